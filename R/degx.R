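#' Construct a two-group expression matrix
#'
#' Log2-scale intensities for a two-group comparison (e.g. pre- vs
#' post-differentiation), with an optional probeset-to-gene map.
#'
#' @param values Numeric matrix, probesets x samples, finite log2
#'   intensities.
#' @param group Two-level factor (or coercible) of length `ncol(values)`;
#'   the first level is the reference, so log-fold-changes are
#'   `mean(level 2) - mean(level 1)`.
#' @param probe_to_gene Optional data frame `probeset, gene`.
#' @return Object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, group, probe_to_gene = NULL) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("expression values must be finite", call. = FALSE)
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("exactly two groups required", call. = FALSE)
  if (length(group) != ncol(values)) {
    stop("group length must equal the number of samples", call. = FALSE)
  }
  if (any(table(group) < 2L)) stop(">= 2 samples per group required", call. = FALSE)
  if (is.null(rownames(values))) rownames(values) <- paste0("ps", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("s", seq_len(ncol(values)))
  structure(list(values = values,
                 probeset_ids = rownames(values),
                 sample_ids = colnames(values),
                 group = group,
                 probe_to_gene = probe_to_gene),
            class = "expression_matrix")
}

#' Read an expression TSV
#'
#' First column `probeset`, optional second column `gene`, remaining
#' columns per-sample log2 values.
#'
#' @param path Input path.
#' @param group Group label per sample column (recycled from config);
#'   length must match the sample columns.
#' @return An `expression_matrix`.
#' @export
read_expression <- function(path, group) {
  df <- read_tsv_lines(path)$df
  has_gene <- identical(tolower(names(df)[2L]), "gene")
  first_sample <- if (has_gene) 3L else 2L
  vals <- as.matrix(df[, first_sample:ncol(df), drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- as.character(df[[1L]])
  p2g <- if (has_gene) {
    data.frame(probeset = as.character(df[[1L]]), gene = as.character(df[[2L]]),
               stringsAsFactors = FALSE)
  } else NULL
  expression_matrix(vals, group, p2g)
}

# Invert the trigamma function by monotone bisection on (1e-6, 1e6),
# absolute tolerance 1e-10 on y. trigamma is strictly decreasing, so y
# below trigamma(1e6) maps to +Inf (no finite solution worth reporting).
trigamma_inverse <- function(y) {
  lo <- 1e-6; hi <- 1e6
  if (!is.finite(y) || y <= trigamma(hi)) return(Inf)
  if (y >= trigamma(lo)) return(lo)
  for (i in 1:120) {
    mid <- sqrt(lo * hi)
    if (trigamma(mid) > y) lo <- mid else hi <- mid
    if (hi - lo < 1e-10 * lo) break
  }
  sqrt(lo * hi)
}

#' Empirical-Bayes moderated t-statistics for a two-group design
#'
#' Fits, per probeset, the two-sample linear model and shrinks residual
#' variances toward a common prior via the scaled inverse-chi-square
#' hierarchical model: `s_g^2 | sigma_g^2 ~ sigma_g^2 chi^2_d / d` and
#' `sigma_g^2 ~ s0^2 d0 / chi^2_{d0}`. Hyperparameters are estimated by
#' moment matching on `z_g = log s_g^2`: the prior degrees of freedom
#' solve `trigamma(d0/2) = var(z) - trigamma(d/2)` by monotone bisection,
#' and `s0^2` follows from the mean of `z` with the matching digamma
#' corrections. The posterior variance is the precision-weighted blend
#' `(d0 s0^2 + d s_g^2) / (d0 + d)`, and the moderated t uses `d0 + d`
#' degrees of freedom. A non-positive trigamma estimate yields `d0 = Inf`
#' (complete shrinkage to `s0^2`).
#'
#' @param expr An `expression_matrix`.
#' @param d0 Optional fixed prior degrees of freedom, bypassing
#'   estimation; `d0 = 0` recovers the classical pooled two-sample t.
#' @return A list of class `modt_fit`: data frame `table` with columns
#'   `probeset, log_fc, s_sq, s_tilde_sq, t_mod, df_total, p`, plus
#'   hyperparameters `d0`, `s0_sq` and the residual df `d_resid`.
#' @export
fit_moderated_t <- function(expr, d0 = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (nrow(expr$values) < 2L) {
    stop("hyperparameter estimation needs >= 2 probesets", call. = FALSE)
  }
  g <- expr$group
  lv <- levels(g)
  x1 <- expr$values[, g == lv[1L], drop = FALSE]
  x2 <- expr$values[, g == lv[2L], drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  d <- n1 + n2 - 2L
  if (d < 1L) stop("residual degrees of freedom must be >= 1", call. = FALSE)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  log_fc <- m2 - m1
  rss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  s_sq <- rss / d
  zero_var <- s_sq <= 0
  if (any(zero_var)) {
    message("fit_moderated_t: ", sum(zero_var),
            " probeset(s) with zero residual variance (shrunk to the prior)")
  }
  if (is.null(d0)) {
    z <- log(s_sq[!zero_var])
    if (length(z) < 2L) stop("too few probesets with positive variance", call. = FALSE)
    nz <- length(z)
    evar <- mean((z - mean(z))^2) * nz / (nz - 1) - trigamma(d / 2)
    if (evar > 0) {
      d0_hat <- 2 * trigamma_inverse(evar)
    } else {
      d0_hat <- Inf
    }
    if (is.finite(d0_hat)) {
      s0_sq <- exp(mean(z) - digamma(d / 2) + log(d / 2) +
                     digamma(d0_hat / 2) - log(d0_hat / 2))
    } else {
      s0_sq <- exp(mean(z) - digamma(d / 2) + log(d / 2))
    }
  } else {
    stopifnot(d0 >= 0)
    d0_hat <- d0
    z <- log(s_sq[!zero_var])
    s0_sq <- if (length(z) > 0) exp(mean(z) - digamma(d / 2) + log(d / 2)) else 1
  }
  if (d0_hat == 0) {
    s_tilde_sq <- s_sq
  } else if (is.infinite(d0_hat)) {
    s_tilde_sq <- rep(s0_sq, length(s_sq))
  } else {
    s_tilde_sq <- (d0_hat * s0_sq + d * s_sq) / (d0_hat + d)
  }
  se_fac <- sqrt(1 / n1 + 1 / n2)
  t_mod <- log_fc / (sqrt(s_tilde_sq) * se_fac)
  df_total <- d0_hat + d
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  tab <- data.frame(probeset = expr$probeset_ids,
                    log_fc = log_fc, s_sq = s_sq,
                    s_tilde_sq = s_tilde_sq, t_mod = t_mod,
                    df_total = df_total, p = p,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, d0 = d0_hat, s0_sq = s0_sq, d_resid = d),
            class = "modt_fit")
}

#' Collapse probeset-level results to gene level
#'
#' Per gene, keeps the most significant probeset (smallest p; ties broken
#' by larger `|t_mod|`, then lexicographic probeset id). Probesets absent
#' from the map are dropped with a message.
#'
#' @param results Probeset-level table from `fit_moderated_t()$table`.
#' @param probe_to_gene Data frame `probeset, gene`.
#' @return Gene-level data frame with a leading `gene` column, sorted by
#'   gene.
#' @export
collapse_probesets <- function(results, probe_to_gene) {
  gene <- probe_to_gene$gene[match(results$probeset, probe_to_gene$probeset)]
  unmapped <- is.na(gene)
  if (any(unmapped)) {
    message("collapse_probesets: dropping ", sum(unmapped),
            " unmapped probeset(s)")
  }
  res <- results[!unmapped, , drop = FALSE]
  gene <- gene[!unmapped]
  ord <- order(gene, res$p, -abs(res$t_mod), res$probeset)
  res <- res[ord, , drop = FALSE]
  gene <- gene[ord]
  keep <- !duplicated(gene)
  out <- cbind(gene = gene[keep], res[keep, , drop = FALSE],
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment mapped back to input order: with sorted p-values,
#' `q_(i) = min_{j >= i} p_(j) m / j`, capped at 1.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted values in input order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes at an FDR threshold
#'
#' @param results Gene-level table with `p` (and `log_fc`); an `fdr`
#'   column is computed with [bh_fdr()] if absent.
#' @param fdr_threshold DEG cutoff; strict `fdr < threshold` (default
#'   0.05).
#' @return `results` with `fdr`, `fc_ratio = 2^log_fc` (ratio scale;
#'   values below 1 are down-regulated) and logical `is_deg`.
#' @export
call_degs <- function(results, fdr_threshold = 0.05) {
  if (is.null(results$fdr)) results$fdr <- bh_fdr(results$p)
  results$fc_ratio <- 2^results$log_fc
  results$is_deg <- results$fdr < fdr_threshold
  results
}
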