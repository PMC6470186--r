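#' Default MHC mask
#'
#' The major histocompatibility complex dominates the association signal in
#' many immune-mediated traits and is masked before suggestive-marker
#' selection. Bounds are 1-based and inclusive on both ends.
#'
#' @param chrom Chromosome label (default `"6"`).
#' @param start,end Mask bounds in bp (default 26,000,000–34,000,000).
#' @return A list with elements `chrom`, `start`, `end`.
#' @export
mhc_mask <- function(chrom = "6", start = 26e6, end = 34e6) {
  list(chrom = as.character(chrom), start = start, end = end)
}

#' Select suggestive significant markers outside a masked region
#'
#' Keeps markers with `p` strictly below `p_thresh` (default 1e-4, the
#' conventional suggestive-significance cutoff) that do not fall inside the
#' mask. The mask test is inclusive on both bounds.
#'
#' @param markers Data frame with at least `chrom`, `pos`, `p`.
#' @param p_thresh Significance threshold in (0, 1); strict `<`.
#' @param mask A region as returned by [mhc_mask()], or `NULL` for no mask.
#' @return The selected subset of `markers` (possibly empty).
#' @export
select_suggestive <- function(markers, p_thresh = 1e-4, mask = mhc_mask()) {
  if (!is.numeric(p_thresh) || length(p_thresh) != 1L ||
      p_thresh <= 0 || p_thresh >= 1) {
    stop("p_thresh must be a single value in (0, 1)", call. = FALSE)
  }
  keep <- markers$p < p_thresh
  if (!is.null(mask)) {
    in_mask <- norm_chrom(markers$chrom) == norm_chrom(mask$chrom) &
      markers$pos >= mask$start & markers$pos <= mask$end
    keep <- keep & !in_mask
  }
  markers[keep, , drop = FALSE]
}

#' Assemble suggestive markers into loci by the genomic-gap rule
#'
#' Groups markers on each chromosome into contiguous loci: sorted by
#' position, a marker joins the current locus iff its gap to the previous
#' member is strictly less than `max_gap` (default 500 kb). This equals the
#' connected components of the graph joining markers less than `max_gap`
#' apart. Single-marker loci are permitted.
#'
#' @param markers Data frame with `chrom`, `pos`, `id`, `p`.
#' @param max_gap Maximum allowed gap between consecutive members in bp
#'   (strict `<`).
#' @return A data frame of class `locus_set`, sorted by `(chrom, start)`,
#'   with columns `locus_label, chrom, start, end, n_markers, lead_id,
#'   min_p` and a list column `marker_ids`. `start`/`end` are the min/max
#'   member positions (1-based inclusive); `lead_id` is the member with the
#'   smallest p (ties broken by smaller id).
#' @details Duplicate `(chrom, pos)` markers are collapsed to the one with
#'   the smaller p (then lexicographically smaller id), with a message.
#' @export
assemble_loci <- function(markers, max_gap = 5e5) {
  stopifnot(max_gap > 0)
  markers <- as.data.frame(markers)
  if (nrow(markers) == 0L) {
    out <- data.frame(locus_label = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_markers = integer(0), lead_id = character(0),
                      min_p = numeric(0), stringsAsFactors = FALSE)
    out$marker_ids <- list()
    class(out) <- c("locus_set", "data.frame")
    return(out)
  }
  markers$chrom <- as.character(markers$chrom)
  key <- paste(markers$chrom, markers$pos, sep = "\r")
  if (anyDuplicated(key)) {
    ord <- order(key, markers$p, markers$id)
    markers <- markers[ord, , drop = FALSE]
    dup <- duplicated(paste(markers$chrom, markers$pos, sep = "\r"))
    message("assemble_loci: collapsed ", sum(dup),
            " duplicate-position marker(s), keeping the smaller p")
    markers <- markers[!dup, , drop = FALSE]
  }
  markers <- markers[order(markers$chrom, markers$pos, markers$id), , drop = FALSE]
  pieces <- lapply(split(markers, markers$chrom), function(mc) {
    gap_break <- c(FALSE, diff(mc$pos) >= max_gap)
    grp <- cumsum(gap_break)
    lapply(split(mc, grp), function(g) {
      lead <- g[order(g$p, g$id), , drop = FALSE][1L, ]
      data.frame(chrom = g$chrom[1L],
                 start = min(g$pos), end = max(g$pos),
                 n_markers = nrow(g),
                 lead_id = lead$id, min_p = lead$p,
                 marker_ids = I(list(g$id)),
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, unlist(pieces, recursive = FALSE))
  rownames(out) <- NULL
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out <- cbind(locus_label = sprintf("%s:%d-%d", out$chrom, out$start, out$end),
               out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("locus_set", "data.frame")
  out
}

#' Marker-to-locus membership table
#'
#' @param loci A `locus_set` from [assemble_loci()].
#' @return A data frame with columns `id`, `locus_label`.
#' @export
locus_membership <- function(loci) {
  if (nrow(loci) == 0L) {
    return(data.frame(id = character(0), locus_label = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(id = unlist(loci$marker_ids),
             locus_label = rep(loci$locus_label, lengths(loci$marker_ids)),
             stringsAsFactors = FALSE)
}

#' Fixed-width locus windows around lead markers
#'
#' Alternative locus report: a symmetric window of `flank` bp either side
#' of each locus's lead marker, offered alongside the marker-span hull of
#' [assemble_loci()] (reported locus windows in the literature are often
#' exactly lead ± 500 kb).
#'
#' @param loci A `locus_set`.
#' @param markers The marker table the loci were assembled from (for lead
#'   positions).
#' @param flank Half-width in bp (default 500 kb).
#' @return `loci` with `start`/`end` replaced by the lead-centered window
#'   (floored at 1) and `locus_label` updated.
#' @export
locus_windows <- function(loci, markers, flank = 5e5) {
  lead_pos <- markers$pos[match(loci$lead_id, markers$id)]
  if (anyNA(lead_pos)) stop("lead marker(s) missing from 'markers'", call. = FALSE)
  loci$start <- pmax(1, lead_pos - flank)
  loci$end <- lead_pos + flank
  loci$locus_label <- sprintf("%s:%d-%d", loci$chrom, loci$start, loci$end)
  loci
}

#' Write a locus table as TSV
#'
#' @param loci A `locus_set`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_loci <- function(loci, path) {
  df <- as.data.frame(loci)
  df$marker_ids <- vapply(df$marker_ids, paste, "", collapse = ",")
  write_tsv(df, path)
}
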