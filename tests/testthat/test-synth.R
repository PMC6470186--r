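# Small-scale configuration used throughout: keeps generator tests fast
# while preserving the statistical structure of the default scenario.
small_cfg <- function(seed = 1, ...) {
  args <- utils::modifyList(list(seed = seed, n_null_markers = 800,
                                 n_planted_loci = 8, n_genes = 120,
                                 n_samples = 60),
                            list(...))
  do.call(synth_config, args)
}

test_that("generators are pure functions of the configuration", {
  cfg <- small_cfg(seed = 7)
  s1 <- gen_sumstats(cfg)
  s2 <- gen_sumstats(cfg)
  expect_identical(s1, s2)
  mk <- data.frame(id = s1$a$id, chrom = s1$a$chrom, pos = s1$a$pos)
  sugg <- s1$a$id %in% s1$truth$planted_marker_ids
  t1 <- gen_enhancer_tracks(cfg, mk, sugg)
  t2 <- gen_enhancer_tracks(cfg, mk, sugg)
  expect_identical(t1, t2)
  g1 <- gen_genotype_panel(cfg, mk$id[sugg],
                           block = rep(1, sum(sugg)))
  g2 <- gen_genotype_panel(cfg, mk$id[sugg],
                           block = rep(1, sum(sugg)))
  expect_identical(g1, g2)
  e1 <- gen_tables_and_expression(cfg, s1$truth)
  e2 <- gen_tables_and_expression(cfg, s1$truth)
  expect_identical(e1, e2)
})

test_that("null-only summary statistics are calibrated", {
  cfg <- synth_config(seed = 11, n_null_markers = 4000, n_planted_loci = 2)
  ss <- gen_sumstats(cfg)
  ind <- indirect_meta(ss$a, ss$b)
  null_p <- ind$p[!ind$id %in% ss$truth$planted_marker_ids]
  frac <- mean(null_p < 0.05)
  n <- length(null_p)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / n))
})

test_that("planted loci are recovered exactly by locus assembly", {
  cfg <- small_cfg(seed = 13)
  ss <- gen_sumstats(cfg)
  ind <- indirect_meta(ss$a, ss$b)
  sugg <- select_suggestive(ind, p_thresh = cfg$p_thresh)
  loci <- assemble_loci(sugg, max_gap = cfg$max_gap)
  assembled <- canonical_partition(loci$marker_ids)
  for (i in seq_len(nrow(ss$truth$planted_loci))) {
    planted_ids <- sort(ss$truth$planted_loci$marker_ids[[i]])
    hit <- vapply(assembled, identical, logical(1), y = planted_ids)
    expect_true(any(hit))
  }
})

test_that("generated enhancer intervals are valid and cover flagged markers", {
  cfg <- small_cfg(seed = 17)
  ss <- gen_sumstats(cfg)
  mk <- data.frame(id = ss$a$id, chrom = ss$a$chrom, pos = ss$a$pos)
  sugg <- ss$a$id %in% ss$truth$planted_marker_ids
  tr <- gen_enhancer_tracks(cfg, mk, sugg)
  for (t in tr$tracks) {
    expect_true(all(t$intervals$start < t$intervals$end))
  }
  # realized incidence equals the generator's ground truth
  om <- suppressMessages(build_overlap_matrix(mk, tr$tracks))
  expect_identical(unname(om$incidence), unname(tr$incidence_truth))
})

test_that("genotype panel hits its LD targets", {
  cfg <- small_cfg(seed = 19, n_samples = 200)
  ids <- sprintf("m%02d", 1:12)
  block <- rep(1:3, each = 4)
  panel <- gen_genotype_panel(cfg, ids, block)
  r2 <- r2_matrix(panel)
  within <- r2[1:4, 1:4][upper.tri(matrix(0, 4, 4))]
  expect_gt(mean(within), cfg$r2_within - 0.15)
  across <- r2[1:4, 5:8]
  expect_lt(mean(across), 0.05)

  # no flip noise: within-block r2 is exactly 1
  cfg1 <- small_cfg(seed = 19, r2_within = 1)
  p1 <- gen_genotype_panel(cfg1, ids[1:4], rep(1, 4))
  r2_1 <- r2_matrix(p1)
  expect_equal(unname(r2_1), matrix(1, 4, 4))
})

test_that("expression generator plants recoverable structure", {
  cfg <- small_cfg(seed = 23)
  ss <- gen_sumstats(cfg)
  tb <- gen_tables_and_expression(cfg, ss$truth)
  # planted causal genes have the smallest eQTL p at their locus
  fit <- suppressMessages(fit_moderated_t(tb$expr))
  genes <- suppressMessages(collapse_probesets(fit$table,
                                               tb$expr$probe_to_gene))
  degs <- call_degs(transform(genes, fdr = bh_fdr(p)))
  planted <- tb$truth$causal$gene
  recovered <- mean(degs$is_deg[match(planted, degs$gene)])
  expect_gt(recovered, 0.8)

  # pi_de = 0: p-values are uniform (KS)
  cfg0 <- small_cfg(seed = 29, pi_de = 0.001, n_genes = 800)
  cfg0$pi_de <- 0
  tb0 <- gen_tables_and_expression(cfg0, gen_sumstats(cfg0)$truth)
  fit0 <- suppressMessages(fit_moderated_t(tb0$expr))
  keep <- !grepl("^(CAUS|NEAR)", tb0$expr$probe_to_gene$gene)
  expect_gt(suppressWarnings(
    ks.test(fit0$table$p[keep], "punif")$p.value), 0.01)

  # probes_per_gene = 1 makes probeset collapse the identity
  cfg1 <- small_cfg(seed = 31, probes_per_gene = 1)
  tb1 <- gen_tables_and_expression(cfg1, gen_sumstats(cfg1)$truth)
  fit1 <- suppressMessages(fit_moderated_t(tb1$expr))
  out1 <- collapse_probesets(fit1$table, tb1$expr$probe_to_gene)
  expect_equal(nrow(out1), nrow(fit1$table))
})

test_that("the bundle round-trips through the module readers", {
  cfg <- small_cfg(seed = 37)
  dir <- withr::local_tempdir()
  bundle <- gen_bundle(cfg, dir)
  expect_no_warning({
    a <- read_sumstats(file.path(dir, "sumstats_a.tsv"))
    b <- read_sumstats(file.path(dir, "sumstats_b.tsv"))
    tracks <- read_tracks(file.path(dir, "tracks"))
    panel <- read_genotypes(file.path(dir, "genotypes.tsv"))
    eq <- read_eqtls(file.path(dir, "eqtls.tsv"))
    dr <- read_drug_targets(file.path(dir, "drugs.tsv"))
    ga <- read_gene_annotation(file.path(dir, "genes.tsv"))
  })
  expect_equal(nrow(a), nrow(b))
  expect_length(tracks, cfg$n_celltypes)
  expect_true(all(panel$marker_ids %in% a$id))
  expect_true(all(bundle$truth$causal_genes$gene %in% ga$symbol))
})
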