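#' Fisher's exact test for a 2x2 table
#'
#' Exact test by hypergeometric enumeration conditional on the table
#' margins. The two-sided p-value is the sum of probabilities of all tables
#' (with the same margins) whose probability does not exceed that of the
#' observed table, compared with relative tolerance 1e-7. The headline odds
#' ratio is the sample cross-product ratio `a*d / (b*c)` (`Inf` when
#' `b*c == 0` and `a*d > 0`, `0` in the opposite case, `NaN` when both
#' products vanish); the conditional maximum-likelihood estimate is
#' available on request.
#'
#' @param a,b,c,d Non-negative integer cell counts, laid out as rows
#'   (group) x columns (feature): `a` = group 1 with feature, `b` = group 1
#'   without, `c` = group 2 with, `d` = group 2 without.
#' @param alternative `"two.sided"` (default) or `"greater"` (enrichment in
#'   group 1).
#' @param conditional_mle If `TRUE`, also return the conditional MLE odds
#'   ratio (via [stats::fisher.test()]) as `or_mle`.
#' @return A list with `odds_ratio`, `p`, and optionally `or_mle`.
#' @export
fisher_exact <- function(a, b, c, d, alternative = c("two.sided", "greater"),
                         conditional_mle = FALSE) {
  alternative <- match.arg(alternative)
  counts <- c(a, b, c, d)
  if (any(!is.finite(counts)) || any(counts < 0) || any(!is_wholenumber(counts))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  m <- a + b; n2 <- c + d; k <- a + c
  if (m == 0 || n2 == 0 || k == 0 || (b + d) == 0) {
    stop("2x2 table has a zero margin", call. = FALSE)
  }
  supp <- max(0, k - n2):min(m, k)
  probs <- stats::dhyper(supp, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  p <- switch(alternative,
              two.sided = sum(probs[probs <= p_obs * (1 + 1e-7)]),
              greater = sum(probs[supp >= a]))
  p <- min(1, p)
  ad <- as.numeric(a) * d
  bc <- as.numeric(b) * c
  or <- if (bc > 0) ad / bc else if (ad > 0) Inf else NaN
  out <- list(odds_ratio = or, p = p)
  if (conditional_mle) {
    ft <- stats::fisher.test(matrix(c(a, c, b, d), nrow = 2L))
    out$or_mle <- unname(ft$estimate)
  }
  out
}

#' Per-cell-type enrichment of suggestive markers among enhancer overlaps
#'
#' Tests, for each cell type, whether suggestive markers overlap that cell
#' type's active enhancers more often than non-suggestive markers do,
#' *among markers that overlap an active enhancer of any cell type* (the
#' baseline reference). For cell type k the 2x2 counts within the baseline
#' are: `a` = suggestive and overlapping k, `b` = suggestive not
#' overlapping k, `c` = non-suggestive overlapping k, `d` = non-suggestive
#' not overlapping k. Bonferroni correction is over the number of cell
#' types with at least one overlapping baseline marker.
#'
#' @param om An `overlap_matrix` covering both suggestive and
#'   non-suggestive markers.
#' @param suggestive Logical vector aligned with `om$marker_ids`.
#' @param loci Optional `locus_set`; when given, `n_loci` counts the loci
#'   contributing at least one marker to cell `a`.
#' @param alternative Passed to [fisher_exact()].
#' @param baseline `"any"` (default; baseline = markers overlapping any
#'   cell type, including the tested one) or `"any_other"` (strict mode:
#'   for each tested cell type the baseline is markers overlapping any
#'   *other* cell type).
#' @return A data frame of class `enrichment_result`, sorted by p, with
#'   columns `cell_type, a, b, c, d, odds_ratio, p, p_bonf,
#'   n_suggestive_markers, n_loci, tested`. Cell types with no overlapping
#'   baseline marker get `tested = FALSE` and `NA` statistics.
#' @export
celltype_enrichment <- function(om, suggestive, loci = NULL,
                                alternative = c("two.sided", "greater"),
                                baseline = c("any", "any_other")) {
  alternative <- match.arg(alternative)
  baseline <- match.arg(baseline)
  stopifnot(inherits(om, "overlap_matrix"),
            length(suggestive) == length(om$marker_ids))
  if (!any(om$any_overlap)) stop("empty baseline", call. = FALSE)
  membership <- if (!is.null(loci)) locus_membership(loci) else NULL
  K <- length(om$cell_types)
  rows <- vector("list", K)
  for (k in seq_len(K)) {
    base <- if (baseline == "any") {
      om$any_overlap
    } else {
      rowSums(om$incidence[, -k, drop = FALSE]) > 0
    }
    ov <- om$incidence[, k]
    a <- sum(base & suggestive & ov)
    b <- sum(base & suggestive & !ov)
    c_ <- sum(base & !suggestive & ov)
    d <- sum(base & !suggestive & !ov)
    tested <- (a + c_) > 0 && (b + d) > 0 && (a + b) > 0 && (c_ + d) > 0
    if (tested) {
      ft <- fisher_exact(a, b, c_, d, alternative = alternative)
      or <- ft$odds_ratio; p <- ft$p
    } else {
      or <- NA_real_; p <- NA_real_
    }
    n_loci <- if (!is.null(membership)) {
      in_a <- om$marker_ids[base & suggestive & ov]
      length(unique(membership$locus_label[membership$id %in% in_a]))
    } else NA_integer_
    rows[[k]] <- data.frame(cell_type = om$cell_types[k],
                            a = a, b = b, c = c_, d = d,
                            odds_ratio = or, p = p,
                            n_suggestive_markers = a, n_loci = n_loci,
                            tested = tested, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  n_tests <- sum((res$a + res$c) > 0)
  res$p_bonf <- pmin(1, res$p * n_tests)
  res <- res[order(res$p, res$cell_type), , drop = FALSE]
  rownames(res) <- NULL
  res <- res[c("cell_type", "a", "b", "c", "d", "odds_ratio", "p", "p_bonf",
               "n_suggestive_markers", "n_loci", "tested")]
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Significance-binned enhancer-overlap fold change
#'
#' Profiles how cell-type-specific enhancer overlap varies with association
#' significance. Markers are binned by `-log10(p)` into `[0,1), [1,2), ...`
#' with the last bin open-ended; for each (bin, cell type) the proportion
#' of the bin's any-overlap markers that overlap the cell type is divided
#' by the same proportion in the `[0,1)` reference bin.
#'
#' @param p Association p-values aligned with `om$marker_ids` (all markers,
#'   not only suggestive ones).
#' @param om An `overlap_matrix`.
#' @param max_bin Lower edge of the open-ended last bin in `-log10` units
#'   (default 4, giving bins `[0,1) ... [4,Inf)`).
#' @param denominator `"any_overlap"` (default; proportions among the
#'   bin's markers overlapping any cell type, consistent with the Fisher
#'   baseline) or `"all"` (among all markers in the bin).
#' @return A data frame of class `binned_fc` with columns `cell_type,
#'   bin_lo, bin_hi, n, proportion, fold_change, defined`. Bins with an
#'   empty denominator get `defined = FALSE` and `NA` proportion.
#' @export
binned_fold_change <- function(p, om, max_bin = 4,
                               denominator = c("any_overlap", "all")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(om, "overlap_matrix"),
            length(p) == length(om$marker_ids))
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  nlp <- -log10(p)
  bin <- pmin(floor(nlp), max_bin)
  in_denom <- if (denominator == "any_overlap") om$any_overlap else
    rep(TRUE, length(p))
  if (!any(in_denom & bin == 0)) stop("reference bin is empty", call. = FALSE)
  bins <- 0:max_bin
  ref_prop <- vapply(seq_along(om$cell_types), function(k) {
    sel <- in_denom & bin == 0
    mean(om$incidence[sel, k])
  }, numeric(1))
  rows <- list()
  for (bi in bins) {
    sel <- in_denom & bin == bi
    n_b <- sum(sel)
    for (k in seq_along(om$cell_types)) {
      if (n_b > 0) {
        prop <- mean(om$incidence[sel, k])
        fc <- if (ref_prop[k] > 0) prop / ref_prop[k] else NA_real_
        defined <- ref_prop[k] > 0
      } else {
        prop <- NA_real_; fc <- NA_real_; defined <- FALSE
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cell_type = om$cell_types[k],
        bin_lo = bi, bin_hi = if (bi == max_bin) Inf else bi + 1,
        n = n_b, proportion = prop, fold_change = fc, defined = defined,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  class(res) <- c("binned_fc", "data.frame")
  res
}
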