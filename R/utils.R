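# Internal helpers shared across modules.

# Chromosome labels from different sources ("6" vs "chr6") are compared
# after stripping any leading "chr".
norm_chrom <- function(x) sub("^chr", "", as.character(x), ignore.case = TRUE)

# Derive a stage-specific RNG seed from a user seed; kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  as.integer((abs(as.numeric(seed)) * 7919 + as.numeric(stage)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Read a TSV with '#' comment lines, tracking original file line numbers so
# row-level validation errors can name the offending line.
read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(list(df = NULL, line_no = integer(0)))
  }
  df <- utils::read.table(text = lines[idx], header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "", comment.char = "")
  list(df = df, line_no = idx[-1L])
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}
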