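#' Default pipeline configuration
#'
#' The defaults are the analysis constants the package is built around:
#' suggestive threshold `p_thresh = 1e-4`, MHC mask chr6:26,000,000 to
#' 34,000,000, locus gap `max_gap = 500,000` bp, two-sided Fisher test
#' with the any-cell-type baseline, one-unit `-log10(p)` bins with the
#' last bin open at 4, LD cut at `r2_threshold = 0.9`, 1,000
#' permutations, and `fdr_threshold = 0.05`.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    sumstats_a = NULL, sumstats_b = NULL, tracks = NULL,
    genotypes = NULL, eqtls = NULL, drugs = NULL, genes = NULL,
    expression = NULL, expr_groups = NULL,
    p_thresh = 1e-4,
    mhc = list(chrom = "6", start = 26e6, end = 34e6),
    max_gap = 5e5,
    fisher_alternative = "two.sided",
    baseline = "any",
    max_bin = 4,
    r2_threshold = 0.9,
    n_perm = 1000L,
    fdr_threshold = 0.05,
    indication_filter = "arthritis",
    proximity_window = 1e6,
    run_ldclust = TRUE,
    seed = 1L,
    out_dir = "subloci_out")
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML path or a list; unknown keys are rejected, missing keys
#' filled with defaults, and value types and bounds checked.
#'
#' @param config YAML file path or named list.
#' @return Normalized configuration list of class `pipeline_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  stopifnot(is.list(config))
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, config)
  chk_prob <- function(key) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1) {
      stop("config key '", key, "' must be a single value in (0, 1)",
           call. = FALSE)
    }
  }
  chk_prob("p_thresh"); chk_prob("fdr_threshold"); chk_prob("r2_threshold")
  if (!is.numeric(cfg$max_gap) || cfg$max_gap <= 0) {
    stop("config key 'max_gap' must be > 0", call. = FALSE)
  }
  if (!cfg$fisher_alternative %in% c("two.sided", "greater")) {
    stop("config key 'fisher_alternative' must be 'two.sided' or 'greater'",
         call. = FALSE)
  }
  if (!cfg$baseline %in% c("any", "any_other")) {
    stop("config key 'baseline' must be 'any' or 'any_other'", call. = FALSE)
  }
  if (!is.numeric(cfg$n_perm) || cfg$n_perm < 100) {
    stop("config key 'n_perm' must be >= 100", call. = FALSE)
  }
  if (!is.numeric(cfg$seed) || cfg$seed != floor(cfg$seed)) {
    stop("config key 'seed' must be an integer", call. = FALSE)
  }
  if (!is.null(cfg$mhc)) {
    if (!all(c("chrom", "start", "end") %in% names(cfg$mhc))) {
      stop("config key 'mhc' needs chrom, start, end", call. = FALSE)
    }
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

# One structured log line per stage; the collected log is written with the
# report (no timestamps, so reruns are byte-identical).
log_line <- function(log_env, ...) {
  log_env$lines <- c(log_env$lines, paste0(...))
  invisible(NULL)
}

run_stage <- function(log_env, name, code) {
  tryCatch(force(code), error = function(e) {
    log_line(log_env, "WARNING: pipeline stopped in stage '", name, "'")
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full suggestive-locus pipeline
#'
#' Executes the staged analysis on the configured inputs: indirect
#' meta-analysis of the two summary-statistic sets, suggestive-marker
#' selection outside the MHC, locus assembly, enhancer-overlap incidence,
#' per-cell-type exact-test enrichment with the any-cell-type baseline,
#' significance-binned fold changes, optional LD clustering with a
#' random-loci permutation null, eQTL/proximity candidate-gene
#' prioritization with drug annotation, and the moderated-t
#' differential-expression overlay. All tables plus a run log are written
#' to `out_dir`; with a fixed seed the outputs are byte-identical across
#' runs.
#'
#' @param config YAML path or list accepted by [validate_config()].
#' @return Invisibly, a list with the stage results (`indirect`,
#'   `suggestive`, `loci`, `om`, `enrichment`, `binned_fc`, `ldclust`,
#'   `report`, `degs`, `config`, `log`).
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_env <- new.env()
  log_env$lines <- character(0)
  log_line(log_env, "subloci pipeline")
  log_line(log_env, "seed: ", cfg$seed)
  for (key in c("p_thresh", "max_gap", "fisher_alternative", "baseline",
                "max_bin", "r2_threshold", "n_perm", "fdr_threshold")) {
    log_line(log_env, key, ": ", format(cfg[[key]]))
  }
  log_line(log_env, "mhc: ", cfg$mhc$chrom, ":", format(cfg$mhc$start),
           "-", format(cfg$mhc$end))
  set.seed(cfg$seed)

  ind <- run_stage(log_env, "sumstats", {
    a <- read_sumstats(cfg$sumstats_a)
    b <- read_sumstats(cfg$sumstats_b)
    res <- indirect_meta(a, b)
    log_line(log_env, "stage sumstats: markers_a=", nrow(a),
             " markers_b=", nrow(b), " paired=", nrow(res))
    res
  })

  stage_loci <- run_stage(log_env, "loci", {
    mask <- if (is.null(cfg$mhc)) NULL else
      mhc_mask(cfg$mhc$chrom, cfg$mhc$start, cfg$mhc$end)
    sugg <- select_suggestive(ind, p_thresh = cfg$p_thresh, mask = mask)
    loci <- assemble_loci(sugg, max_gap = cfg$max_gap)
    log_line(log_env, "stage loci: suggestive=", nrow(sugg),
             " loci=", nrow(loci))
    list(suggestive = sugg, loci = loci)
  })
  sugg <- stage_loci$suggestive
  loci <- stage_loci$loci

  om <- run_stage(log_env, "overlap", {
    tracks <- read_tracks(cfg$tracks)
    markers <- data.frame(id = ind$id, chrom = ind$chrom, pos = ind$pos,
                          stringsAsFactors = FALSE)
    om <- suppressMessages(build_overlap_matrix(markers, tracks))
    log_line(log_env, "stage overlap: markers=", length(om$marker_ids),
             " cell_types=", length(om$cell_types),
             " any_overlap=", sum(om$any_overlap))
    om
  })
  is_sugg <- ind$id %in% sugg$id

  enr <- run_stage(log_env, "enrich", {
    res <- celltype_enrichment(om, is_sugg, loci = loci,
                               alternative = cfg$fisher_alternative,
                               baseline = cfg$baseline)
    fc <- binned_fold_change(ind$p, om, max_bin = cfg$max_bin)
    log_line(log_env, "stage enrich: tested=", sum(res$tested),
             " bonferroni_significant=",
             sum(res$tested & res$p_bonf < 0.05, na.rm = TRUE))
    list(enrichment = res, binned_fc = fc)
  })

  ld <- NULL
  if (isTRUE(cfg$run_ldclust) && !is.null(cfg$genotypes)) {
    ld <- run_stage(log_env, "ldclust", {
      panel <- read_genotypes(cfg$genotypes)
      keep <- intersect(sugg$id, panel$marker_ids)
      if (length(keep) < length(sugg$id)) {
        log_line(log_env, "stage ldclust: ", length(sugg$id) - length(keep),
                 " suggestive marker(s) absent from the genotype panel")
      }
      panel <- genotype_panel(panel$dosages[keep, , drop = FALSE],
                              marker_ids = keep,
                              sample_ids = panel$sample_ids)
      r2 <- r2_matrix(panel)
      cl <- ward_cluster(1 - r2, cut_height = 1 - cfg$r2_threshold)
      reps <- cluster_representatives(cl$assignments, sugg)
      pool <- setdiff(om$marker_ids[!is_sugg], reps)
      pn <- cluster_enrichment_null(reps, om, pool,
                                    n_perm = cfg$n_perm,
                                    seed = derive_seed(cfg$seed, 9L))
      log_line(log_env, "stage ldclust: markers=", length(keep),
               " clusters=", length(unique(cl$assignments)),
               " n_perm=", cfg$n_perm)
      list(clusters = cl, representatives = reps, perm = pn)
    })
  }

  dg <- run_stage(log_env, "degx", {
    groups <- cfg$expr_groups
    expr_raw <- read_tsv_lines(cfg$expression)$df
    sample_cols <- c(groups$g1, groups$g2)
    group <- factor(rep(c("g1", "g2"), c(length(groups$g1), length(groups$g2))),
                    levels = c("g1", "g2"))
    has_gene <- identical(tolower(names(expr_raw)[2L]), "gene")
    vals <- as.matrix(expr_raw[, sample_cols, drop = FALSE])
    storage.mode(vals) <- "double"
    rownames(vals) <- as.character(expr_raw[[1L]])
    p2g <- if (has_gene) {
      data.frame(probeset = as.character(expr_raw[[1L]]),
                 gene = as.character(expr_raw[[2L]]), stringsAsFactors = FALSE)
    } else NULL
    expr <- expression_matrix(vals, group, p2g)
    fit <- suppressMessages(fit_moderated_t(expr))
    gene_tab <- suppressMessages(
      collapse_probesets(fit$table, expr$probe_to_gene))
    gene_tab$fdr <- bh_fdr(gene_tab$p)
    degs <- call_degs(gene_tab, fdr_threshold = cfg$fdr_threshold)
    log_line(log_env, "stage degx: probesets=", nrow(fit$table),
             " genes=", nrow(degs), " degs=", sum(degs$is_deg),
             " d0=", format(round(fit$d0, 3)),
             " s0_sq=", format(round(fit$s0_sq, 5)))
    list(fit = fit, degs = degs)
  })

  report <- run_stage(log_env, "genes", {
    eqtls <- read_eqtls(cfg$eqtls)
    drugs <- read_drug_targets(cfg$drugs)
    genes_df <- read_gene_annotation(cfg$genes)
    enriched <- enr$enrichment$cell_type[enr$enrichment$tested &
                                           !is.na(enr$enrichment$p_bonf) &
                                           enr$enrichment$p_bonf < 0.05]
    build_locus_report(loci, sugg, om, enriched, eqtls, drugs, genes_df,
                       dg$degs, indication_filter = cfg$indication_filter,
                       window = cfg$proximity_window, log_env = log_env)
  })

  run_stage(log_env, "write", {
    write_tsv(ind, file.path(cfg$out_dir, "indirect.tsv"))
    write_loci(loci, file.path(cfg$out_dir, "loci.tsv"))
    write_tsv(as.data.frame(enr$enrichment),
              file.path(cfg$out_dir, "enrichment.tsv"))
    write_tsv(as.data.frame(enr$binned_fc),
              file.path(cfg$out_dir, "binned_fc.tsv"))
    write_tsv(report, file.path(cfg$out_dir, "locus_report.tsv"))
    deg_out <- dg$degs[c("gene", "probeset", "fc_ratio", "log_fc", "t_mod",
                         "p", "fdr", "is_deg")]
    write_tsv(deg_out, file.path(cfg$out_dir, "degs.tsv"))
    if (!is.null(ld)) {
      cl_df <- data.frame(marker_id = names(ld$clusters$assignments),
                          cluster_id = unname(ld$clusters$assignments),
                          representative = names(ld$clusters$assignments) %in%
                            ld$representatives,
                          stringsAsFactors = FALSE)
      write_tsv(cl_df, file.path(cfg$out_dir, "clusters.tsv"))
      perm_df <- data.frame(cell_type = names(ld$perm$perm_p),
                            observed = unname(ld$perm$observed),
                            perm_p = unname(ld$perm$perm_p),
                            n_perm = ld$perm$n_perm,
                            stringsAsFactors = FALSE)
      write_tsv(perm_df, file.path(cfg$out_dir, "cluster_perm.tsv"))
    }
    NULL
  })
  log_line(log_env, "pipeline complete")
  writeLines(log_env$lines, file.path(cfg$out_dir, "runlog.txt"))
  invisible(list(indirect = ind, suggestive = sugg, loci = loci, om = om,
                 enrichment = enr$enrichment, binned_fc = enr$binned_fc,
                 ldclust = ld, report = report, degs = dg$degs,
                 modt = dg$fit, config = cfg, log = log_env$lines))
}

# Assemble the per-locus report: for each locus with >= 1 marker
# overlapping an enriched cell type, the per-cell-type minimum marker p,
# the prioritized candidate gene with evidence string, its
# indication-filtered drugs, and the DEG flag.
build_locus_report <- function(loci, sugg, om, enriched_celltypes, eqtls,
                               drugs, genes_df, degs,
                               indication_filter = "arthritis",
                               window = 1e6, log_env = NULL) {
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    member_ids <- loci$marker_ids[[i]]
    idx <- match(member_ids, om$marker_ids)
    if (length(enriched_celltypes) == 0L) next
    inc <- om$incidence[idx, enriched_celltypes, drop = FALSE]
    overlapping <- member_ids[rowSums(inc) > 0]
    if (length(overlapping) == 0L) next
    mk <- sugg[match(overlapping, sugg$id), c("id", "chrom", "pos", "p")]
    cand <- suppressMessages(
      prioritize_gene(loci$locus_label[i], mk, eqtls, genes_df,
                      window = window))
    ann <- if (!is.na(cand$gene)) {
      annotate_drugs(cand$gene, drugs, indication_filter)
    } else list(drugs = character(0))
    min_p <- vapply(enriched_celltypes, function(ct) {
      sel <- inc[, ct] & !is.na(match(member_ids, sugg$id))
      if (!any(sel)) return(NA_real_)
      min(sugg$p[match(member_ids[sel], sugg$id)])
    }, numeric(1))
    row <- data.frame(locus = loci$locus_label[i],
                      chrom = loci$chrom[i], start = loci$start[i],
                      end = loci$end[i], n_markers = loci$n_markers[i],
                      stringsAsFactors = FALSE)
    for (ct in enriched_celltypes) {
      row[[paste0("min_p_", ct)]] <- min_p[[ct]]
    }
    deg_row <- match(cand$gene, degs$gene)
    row$candidate <- format_evidence(cand)
    row$gene <- cand$gene
    row$evidence <- cand$evidence
    row$drugs <- paste(ann$drugs, collapse = ", ")
    row$is_deg <- !is.na(deg_row) && isTRUE(degs$is_deg[deg_row])
    rows[[length(rows) + 1L]] <- row
  }
  if (length(rows) == 0L) {
    if (!is.null(log_env)) {
      log_line(log_env, "stage genes: no locus overlaps an enriched cell type")
    }
    return(data.frame(locus = character(0), stringsAsFactors = FALSE))
  }
  report <- do.call(rbind, rows)
  # rank by the smallest per-enriched-cell-type minimum marker p
  pcols <- grep("^min_p_", names(report), value = TRUE)
  best <- apply(report[pcols], 1L, min, na.rm = TRUE)
  report <- report[order(best), , drop = FALSE]
  rownames(report) <- NULL
  if (!is.null(log_env)) {
    log_line(log_env, "stage genes: report_loci=", nrow(report),
             " with_eqtl=", sum(report$evidence == "eqtl"),
             " with_proximity=", sum(report$evidence == "proximity"),
             " deg_flagged=", sum(report$is_deg))
  }
  report
}
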