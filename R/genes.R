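#' Read a gene annotation table
#'
#' TSV with columns `chrom, start, end, strand, symbol`; spans are 1-based
#' inclusive.
#'
#' @param path Input path.
#' @return Data frame with those columns.
#' @export
read_gene_annotation <- function(path) {
  df <- read_tsv_lines(path)$df
  req <- c("chrom", "start", "end", "strand", "symbol")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    stop("gene annotation missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$chrom <- as.character(df$chrom)
  df[req]
}

#' Read an eQTL table
#'
#' TSV with columns `marker_id, gene, p` (marker-to-gene expression
#' associations, e.g. whole-blood cis-eQTLs).
#'
#' @param path Input path.
#' @return Data frame with those columns.
#' @export
read_eqtls <- function(path) {
  df <- read_tsv_lines(path)$df
  req <- c("marker_id", "gene", "p")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    stop("eQTL table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(df$p) | df$p <= 0 | df$p > 1)) {
    stop("eQTL p-values must lie in (0, 1]", call. = FALSE)
  }
  df[req]
}

#' Read a drug-target table
#'
#' TSV with columns `drug, gene, indication` (schema-level table; one row
#' per drug-gene-indication triple).
#'
#' @param path Input path.
#' @return Data frame with those columns.
#' @export
read_drug_targets <- function(path) {
  df <- read_tsv_lines(path)$df
  req <- c("drug", "gene", "indication")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    stop("drug-target table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df[req]
}

# Distance (bp) from a 1-based marker position to a 1-based inclusive gene
# span; 0 when the marker lies inside the span.
gene_distance <- function(pos, gstart, gend) {
  ifelse(pos >= gstart & pos <= gend, 0,
         pmin(abs(pos - gstart), abs(pos - gend)))
}

#' Prioritize one candidate gene for a locus
#'
#' eQTL-first prioritization: among eQTL records attached to the locus's
#' enhancer-overlapping markers, the gene with the smallest p wins (ties:
#' smaller marker-to-gene distance, then lexicographic symbol). With no
#' eQTL record, falls back to the gene nearest the lead overlapping marker
#' (distance 0 when the marker lies inside the gene span).
#'
#' @param locus_label Label carried into the result.
#' @param overlapping_markers Data frame with `id, chrom, pos, p` for the
#'   locus members overlapping enriched-cell-type enhancers.
#' @param eqtls eQTL table (`marker_id, gene, p`).
#' @param genes Gene annotation (`chrom, start, end, strand, symbol`).
#' @param window Proximity search window in bp around the lead marker
#'   (default 1 Mb).
#' @return One-row data frame of class `gene_candidate` with columns
#'   `locus_label, gene, evidence, eqtl_p, distance_bp, source_marker`.
#'   Exactly one of `eqtl_p`/`distance_bp` is populated, per the evidence
#'   type; `gene` is `NA` when neither route yields a candidate (logged).
#' @export
prioritize_gene <- function(locus_label, overlapping_markers, eqtls, genes,
                            window = 1e6) {
  if (nrow(overlapping_markers) == 0L) {
    stop("no overlapping markers for locus ", locus_label, call. = FALSE)
  }
  cand <- eqtls[eqtls$marker_id %in% overlapping_markers$id, , drop = FALSE]
  if (nrow(cand) > 0L) {
    mpos <- overlapping_markers$pos[match(cand$marker_id, overlapping_markers$id)]
    gi <- match(cand$gene, genes$symbol)
    gdist <- ifelse(is.na(gi), Inf,
                    gene_distance(mpos, genes$start[gi], genes$end[gi]))
    ord <- order(cand$p, gdist, cand$gene, cand$marker_id)
    best <- ord[1L]
    out <- data.frame(locus_label = locus_label, gene = cand$gene[best],
                      evidence = "eqtl", eqtl_p = cand$p[best],
                      distance_bp = NA_real_,
                      source_marker = cand$marker_id[best],
                      stringsAsFactors = FALSE)
  } else {
    lead <- overlapping_markers[order(overlapping_markers$p,
                                      overlapping_markers$id), ][1L, ]
    g <- genes[norm_chrom(genes$chrom) == norm_chrom(lead$chrom), , drop = FALSE]
    if (nrow(g) > 0L) {
      d <- gene_distance(lead$pos, g$start, g$end)
      g <- g[d <= window, , drop = FALSE]
      d <- d[d <= window]
    }
    if (nrow(g) == 0L) {
      message("prioritize_gene: no eQTL and no gene within ", window,
              " bp for locus ", locus_label)
      out <- data.frame(locus_label = locus_label, gene = NA_character_,
                        evidence = "none", eqtl_p = NA_real_,
                        distance_bp = NA_real_,
                        source_marker = lead$id, stringsAsFactors = FALSE)
    } else {
      ord <- order(d, g$symbol)
      best <- ord[1L]
      out <- data.frame(locus_label = locus_label, gene = g$symbol[best],
                        evidence = "proximity", eqtl_p = NA_real_,
                        distance_bp = d[best],
                        source_marker = lead$id, stringsAsFactors = FALSE)
    }
  }
  class(out) <- c("gene_candidate", "data.frame")
  out
}

#' Annotate a gene with indication-filtered drugs
#'
#' Returns the drugs targeting `gene` whose indication matches the filter,
#' deduplicated case-insensitively (first spelling kept) and sorted.
#'
#' @param gene Gene symbol.
#' @param drug_targets Drug-target table (`drug, gene, indication`).
#' @param indication_filter Character vector of indications to keep
#'   (case-insensitive; default `"arthritis"`).
#' @return A list of class `drug_annotation` with `gene` and sorted
#'   character vector `drugs` (possibly empty).
#' @export
annotate_drugs <- function(gene, drug_targets,
                           indication_filter = "arthritis") {
  stopifnot(length(indication_filter) >= 1L)
  hit <- drug_targets$gene == gene &
    tolower(drug_targets$indication) %in% tolower(indication_filter)
  drugs <- drug_targets$drug[hit]
  drugs <- drugs[!duplicated(tolower(drugs))]
  structure(list(gene = gene, drugs = sort(drugs)),
            class = "drug_annotation")
}

#' Render a candidate's evidence string
#'
#' Report-style rendering: eQTL evidence as
#' `"GENE (eQTL: p = 1.3e-19; rs123)"`, proximity as
#' `"GENE (proximity: 32 kb; rs123)"` (or `"within gene"` at distance 0).
#'
#' @param candidate A `gene_candidate` row.
#' @return Character scalar.
#' @export
format_evidence <- function(candidate) {
  if (is.na(candidate$gene)) return("none")
  if (candidate$evidence == "eqtl") {
    sprintf("%s (eQTL: p = %.3g; %s)", candidate$gene, candidate$eqtl_p,
            candidate$source_marker)
  } else if (candidate$distance_bp == 0) {
    sprintf("%s (proximity: within gene; %s)", candidate$gene,
            candidate$source_marker)
  } else {
    sprintf("%s (proximity: %d kb; %s)", candidate$gene,
            as.integer(round(candidate$distance_bp / 1000)),
            candidate$source_marker)
  }
}
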