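# Small fixtures built in code.

make_sumstats_df <- function(chrom, pos, id, beta, se, p,
                             ref = "A", alt = "G") {
  n <- length(pos)
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   id = id, ref = rep_len(ref, n), alt = rep_len(alt, n),
                   beta = beta, se = se, p = p, stringsAsFactors = FALSE)
  class(df) <- c("marker_assoc", "data.frame")
  df
}

write_tmp_tsv <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "tab.tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_tmp_bed <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "track.bed")
  writeLines(lines, path)
  path
}
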