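test_that("fisher_exact matches hand-enumerated tables", {
  # (3,1;1,3): OR = 9, two-sided p = 34/70
  res <- fisher_exact(3, 1, 1, 3)
  expect_equal(res$odds_ratio, 9)
  expect_equal(res$p, 34 / 70, tolerance = 1e-12)

  # symmetric table
  res2 <- fisher_exact(2, 2, 2, 2)
  expect_equal(res2$odds_ratio, 1)
  expect_equal(res2$p, 1)

  # degenerate odds ratios
  expect_identical(fisher_exact(2, 0, 1, 3)$odds_ratio, Inf)
  expect_identical(fisher_exact(0, 2, 3, 1)$odds_ratio, 0)

  expect_error(fisher_exact(-1, 1, 1, 1), "non-negative")
  expect_error(fisher_exact(0, 0, 1, 1), "zero margin")
})

test_that("fisher_exact agrees with enumeration, transposition and fisher.test", {
  set.seed(601)
  for (rep in 1:200) {
    tab <- as.vector(stats::rmultinom(1, size = sample(4:40, 1),
                                      prob = runif(4, 0.1, 1)))
    a <- tab[1]; b <- tab[2]; c_ <- tab[3]; d <- tab[4]
    if ((a + b) * (c_ + d) * (a + c_) * (b + d) == 0) next
    mine <- fisher_exact(a, b, c_, d)
    expect_equal(mine$p, fisher_enum_oracle(a, b, c_, d), tolerance = 1e-12)
    # transposing the table changes neither OR nor p
    tr <- fisher_exact(a, c_, b, d)
    expect_equal(tr$p, mine$p, tolerance = 1e-12)
    expect_equal(tr$odds_ratio, mine$odds_ratio)
    # independent library cross-check
    ft <- stats::fisher.test(matrix(c(a, c_, b, d), 2))
    expect_equal(mine$p, ft$p.value, tolerance = 1e-7)
    gt <- fisher_exact(a, b, c_, d, alternative = "greater")
    ftg <- stats::fisher.test(matrix(c(a, c_, b, d), 2), alternative = "greater")
    expect_equal(gt$p, ftg$p.value, tolerance = 1e-7)
  }
  # conditional MLE available on request
  cm <- fisher_exact(3, 1, 1, 3, conditional_mle = TRUE)
  expect_true(cm$or_mle > 1)
})

test_that("cell-type enrichment counts the 2x2 within the any-overlap baseline", {
  # 53 baseline suggestive markers, 30 overlapping the tested cell type:
  # b must be 53 - 30 = 23
  n_sugg <- 60; n_non <- 500
  inc <- matrix(FALSE, n_sugg + n_non, 2,
                dimnames = list(NULL, c("tested", "other")))
  sugg <- c(rep(TRUE, n_sugg), rep(FALSE, n_non))
  inc[1:30, "tested"] <- TRUE          # suggestive overlapping tested ct
  inc[31:53, "other"] <- TRUE          # suggestive in baseline via other ct
  inc[n_sugg + (1:200), "tested"] <- TRUE
  inc[n_sugg + (201:400), "other"] <- TRUE
  om <- overlap_matrix(inc)
  res <- celltype_enrichment(om, sugg)
  row <- res[res$cell_type == "tested", ]
  expect_equal(row$a, 30)
  expect_equal(row$b, 23)
  expect_equal(row$c, 200)
  expect_equal(row$d, 200)
  expect_equal(row$n_suggestive_markers, 30)

  # Bonferroni over tested cell types; a single tested cell type keeps p
  inc1 <- inc[, "tested", drop = FALSE]
  om1 <- overlap_matrix(inc1)
  res1 <- celltype_enrichment(om1, sugg)
  expect_equal(res1$p_bonf, res1$p)

  expect_error(celltype_enrichment(overlap_matrix(matrix(FALSE, 5, 2)),
                                   rep(TRUE, 5)), "empty baseline")
})

test_that("n_loci counts loci contributing overlapping suggestive markers", {
  mk <- data.frame(chrom = "1", pos = c(1e6, 1.1e6, 5e6, 9e6),
                   id = c("m1", "m2", "m3", "m4"),
                   p = c(1e-6, 1e-6, 1e-6, 0.5))
  loci <- assemble_loci(mk[1:3, ], max_gap = 5e5)
  inc <- matrix(c(TRUE, FALSE, TRUE, TRUE), 4, 1,
                dimnames = list(mk$id, "ct"))
  om <- overlap_matrix(inc)
  res <- celltype_enrichment(om, c(TRUE, TRUE, TRUE, FALSE), loci = loci)
  expect_equal(res$n_loci, 2L)  # m1 and m3 overlap, from two distinct loci
})

test_that("strict any-other baseline excludes the tested cell type", {
  inc <- cbind(ct1 = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
               ct2 = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE))
  om <- overlap_matrix(inc)
  sugg <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  strict <- celltype_enrichment(om, sugg, baseline = "any_other")
  r1 <- strict[strict$cell_type == "ct1", ]
  # baseline for ct1 = markers overlapping ct2 (rows 1,3,4,6)
  expect_equal(r1$a + r1$b, 2)  # suggestive rows 1 and 3
  expect_equal(r1$c + r1$d, 2)  # non-suggestive rows 4 and 6
})

test_that("binned fold change is 1 in the reference bin and ratios elsewhere", {
  set.seed(99)
  n <- 400
  p <- c(runif(300, 0.11, 1),          # bin 0
         10^-runif(100, 4, 6))         # bin >= 4
  inc <- cbind(ct1 = c(runif(300) < 0.3, runif(100) < 0.6),
               ct2 = rep(TRUE, n))     # guarantees any-overlap everywhere
  om <- overlap_matrix(inc)
  fc <- binned_fold_change(p, om, max_bin = 4)
  ref <- fc[fc$bin_lo == 0 & fc$cell_type == "ct1", ]
  expect_equal(ref$fold_change, 1)
  top <- fc[fc$bin_lo == 4 & fc$cell_type == "ct1", ]
  expect_equal(top$fold_change, top$proportion / ref$proportion)
  expect_true(all(fc$proportion >= 0 & fc$proportion <= 1, na.rm = TRUE))
  # empty intermediate bins are flagged undefined
  mid <- fc[fc$bin_lo == 2 & fc$cell_type == "ct1", ]
  expect_false(mid$defined)

  # exact arithmetic: 0.6 vs 0.3 reference is FC 2
  p2 <- c(rep(0.5, 10), rep(1e-5, 10))
  inc2 <- cbind(ct = rep(c(TRUE, FALSE), c(3, 7)), any = rep(TRUE, 10))
  inc2 <- rbind(inc2, cbind(ct = rep(c(TRUE, FALSE), c(6, 4)),
                            any = rep(TRUE, 10)))
  om2 <- overlap_matrix(inc2)
  fc2 <- binned_fold_change(p2, om2, max_bin = 4)
  expect_equal(fc2$fold_change[fc2$cell_type == "ct" & fc2$bin_lo == 4], 2)

  expect_error(binned_fold_change(rep(1e-5, 20), om2), "reference bin")
})

test_that("planted monotone enrichment yields non-decreasing fold changes", {
  set.seed(607)
  wins <- 0L
  for (rep in 1:20) {
    n <- 3000
    p <- 10^-runif(n, 0, 5.5)
    bin <- pmin(floor(-log10(p)), 4)
    rate <- 0.2 * 1.4^bin / (1 + 0.2 * (1.4^bin - 1))  # increasing in bin
    inc <- cbind(planted = runif(n) < pmin(rate, 0.9),
                 flat = runif(n) < 0.4,
                 anyc = TRUE)
    om <- overlap_matrix(inc)
    fc <- binned_fold_change(p, om, max_bin = 4)
    f <- fc$fold_change[fc$cell_type == "planted"]
    if (!is.unsorted(f)) wins <- wins + 1L
  }
  expect_gt(wins, 10L)
})
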