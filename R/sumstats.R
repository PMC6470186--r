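#' Read a GWAS summary-statistics table
#'
#' Parses a tab-separated summary-statistics file with header columns
#' `chrom, pos, id, ref, alt, beta, se, p` (case-insensitive; extra columns
#' are ignored, lines starting with `#` are skipped). Each row is one
#' marker's association record for a single case-vs-control comparison:
#' `beta` is the log-odds effect estimate, `se` its standard error and `p`
#' the association p-value.
#'
#' @param path Path to a TSV file.
#' @return A `data.frame` of class `marker_assoc` with the eight canonical
#'   columns, in file order.
#' @details Validation enforces `0 < p <= 1`, `se > 0`, `pos >= 1`, and
#'   uniqueness of `(chrom, pos, ref, alt)`; violations raise an error that
#'   names the file line.
#' @export
read_sumstats <- function(path) {
  parsed <- read_tsv_lines(path)
  if (is.null(parsed$df)) stop("empty summary-statistics file: ", path, call. = FALSE)
  df <- parsed$df
  names(df) <- tolower(names(df))
  req <- c("chrom", "pos", "id", "ref", "alt", "beta", "se", "p")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    stop("summary-statistics file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[req]
  for (col in c("pos", "beta", "se", "p")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad) > 0L) {
        stop(sprintf("non-numeric '%s' at line %d of %s",
                     col, parsed$line_no[bad[1L]], path), call. = FALSE)
      }
      df[[col]] <- vn
    }
  }
  bad_row <- function(cond, what) {
    i <- which(cond)
    if (length(i) > 0L) {
      stop(sprintf("%s at line %d of %s", what, parsed$line_no[i[1L]], path),
           call. = FALSE)
    }
  }
  bad_row(!is.finite(df$p) | df$p <= 0 | df$p > 1, "p outside (0, 1]")
  bad_row(!is.finite(df$se) | df$se <= 0, "se must be > 0")
  bad_row(!is.finite(df$beta), "non-finite beta")
  bad_row(!is.finite(df$pos) | df$pos < 1 | !is_wholenumber(df$pos),
          "pos must be a positive integer")
  df$chrom <- as.character(df$chrom)
  df$id <- as.character(df$id)
  df$pos <- as.integer(round(df$pos))
  key <- paste(df$chrom, df$pos, df$ref, df$alt, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (chrom, pos, ref, alt) record(s) in ", path, call. = FALSE)
  }
  class(df) <- c("marker_assoc", "data.frame")
  df
}

#' Write a summary-statistics table
#'
#' Inverse of [read_sumstats()]: round-tripping a valid table is the
#' identity on its canonical columns.
#'
#' @param df A `marker_assoc` data frame (or anything with the canonical columns).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_sumstats <- function(df, path) {
  req <- c("chrom", "pos", "id", "ref", "alt", "beta", "se", "p")
  write_tsv(as.data.frame(df)[req], path)
}

#' Indirect meta-analysis chi-square between two comparisons
#'
#' Given per-marker association results for two case-vs-control comparisons
#' that share controls only implicitly (e.g., disease subtype A vs control
#' and subtype B vs control), computes the Wald difference statistic
#' \deqn{\chi^2 = (\beta_1 - \beta_2)^2 / (se_1^2 + se_2^2 - 2\,cov)}
#' with 1 degree of freedom, the standard indirect comparison of two
#' independent effect estimates. The p-value is the upper chi-square tail.
#'
#' Records are matched on `id`. Alleles are harmonized before differencing:
#' if `b`'s ref/alt are swapped relative to `a`'s, `b`'s beta is negated;
#' any other allele configuration (including strand flips, which are never
#' guessed at) is an error.
#'
#' @param a,b `marker_assoc` data frames (or single records) for the two
#'   comparisons.
#' @param covariance Optional shared-control covariance term subtracted
#'   (twice) from the variance of the difference; default 0, i.e. the two
#'   estimates are treated as independent.
#' @return A data frame with columns `id, chrom, pos, chi2, p`, one row per
#'   marker present in both inputs, in `a`'s order. `chi2 == 0` iff `p == 1`.
#' @export
indirect_meta <- function(a, b, covariance = 0) {
  a <- as.data.frame(a); b <- as.data.frame(b)
  if (anyDuplicated(a$id) || anyDuplicated(b$id)) {
    stop("duplicate marker ids within one summary-statistic set", call. = FALSE)
  }
  if (nrow(a) == 1L && nrow(b) == 1L && a$id != b$id) {
    stop("mismatched marker ids: '", a$id, "' vs '", b$id, "'", call. = FALSE)
  }
  common <- intersect(a$id, b$id)
  if (length(common) == 0L) stop("no shared marker ids between the two sets", call. = FALSE)
  n_drop <- (nrow(a) - length(common)) + (nrow(b) - length(common))
  if (n_drop > 0L) {
    message("indirect_meta: dropping ", n_drop, " record(s) present in only one set")
  }
  a2 <- a[a$id %in% common, , drop = FALSE]
  b2 <- b[match(a2$id, b$id), , drop = FALSE]
  same <- a2$ref == b2$ref & a2$alt == b2$alt
  flip <- a2$ref == b2$alt & a2$alt == b2$ref & !same
  bad <- !(same | flip)
  if (any(bad)) {
    stop("irreconcilable alleles for marker(s): ",
         paste(utils::head(a2$id[bad], 5L), collapse = ", "), call. = FALSE)
  }
  beta_b <- ifelse(flip, -b2$beta, b2$beta)
  v <- a2$se^2 + b2$se^2 - 2 * covariance
  if (any(v <= 0)) stop("non-positive variance of the difference; check 'covariance'", call. = FALSE)
  chi2 <- (a2$beta - beta_b)^2 / v
  data.frame(id = a2$id, chrom = a2$chrom, pos = a2$pos,
             chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}
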