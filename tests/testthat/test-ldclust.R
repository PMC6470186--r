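test_that("r2 matrix matches the direct correlation formula", {
  set.seed(701)
  dos <- matrix(sample(0:2, 8 * 30, replace = TRUE), 8, 30)
  panel <- genotype_panel(dos)
  r2 <- r2_matrix(panel)
  # direct covariance-formula recomputation
  for (i in 1:8) for (j in 1:8) {
    num <- mean(dos[i, ] * dos[j, ]) - mean(dos[i, ]) * mean(dos[j, ])
    den <- sqrt((mean(dos[i, ]^2) - mean(dos[i, ])^2) *
                  (mean(dos[j, ]^2) - mean(dos[j, ])^2))
    expect_equal(r2[i, j], (num / den)^2, tolerance = 1e-12)
  }
  expect_identical(unname(diag(r2)), rep(1, 8))

  # duplicated column and perfect anticorrelation both give r2 = 1
  dup <- genotype_panel(rbind(c(0, 1, 2, 0), c(0, 1, 2, 0)))
  expect_equal(unname(r2_matrix(dup)[1, 2]), 1)
  anti <- genotype_panel(rbind(c(0, 1, 2, 0), c(2, 1, 0, 2)))
  expect_equal(unname(r2_matrix(anti)[1, 2]), 1)

  mono <- genotype_panel(rbind(c(1, 1, 1, 1), c(0, 1, 2, 0)),
                         marker_ids = c("mono1", "m2"))
  expect_error(r2_matrix(mono), "mono1")
  missing_heavy <- genotype_panel(rbind(c(NA, NA, NA, 0, 1, 2),
                                        c(0, 1, 2, 0, 1, 2)))
  expect_error(r2_matrix(missing_heavy), "missing")
  expect_error(genotype_panel(matrix(c(0, 3), 1, 2)), "dosages")
})

test_that("Ward clustering reproduces the hand-computed 3-leaf example", {
  d <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d["A", "B"] <- d["B", "A"] <- 1
  d["A", "C"] <- d["C", "A"] <- 5
  d["B", "C"] <- d["C", "B"] <- 5
  cl <- ward_cluster(d, cut_height = 2)
  expect_equal(cl$merge_heights, c(1, sqrt(33)), tolerance = 1e-12)
  expect_equal(unname(cl$assignments), c(1L, 1L, 2L))

  # two markers at distance zero always share a cluster
  d0 <- matrix(0, 2, 2)
  expect_equal(unname(ward_cluster(d0, cut_height = 1e-6)$assignments),
               c(1L, 1L))
  # a single marker is one singleton cluster
  single <- ward_cluster(matrix(0, 1, 1, dimnames = list("m1", "m1")))
  expect_equal(unname(single$assignments), 1L)
  expect_length(single$merge_heights, 0L)

  ns <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(ward_cluster(ns), "symmetric")
})

test_that("Ward merges equal the Lance-Williams recurrence oracle", {
  set.seed(702)
  for (rep in 1:120) {
    n <- sample(3:6, 1)
    x <- matrix(runif(n * 2), n)
    d <- as.matrix(dist(x))
    cl <- ward_cluster(d, cut_height = 0.1)
    oracle <- lw_ward_oracle(d)
    expect_equal(cl$merge_heights, oracle$heights, tolerance = 1e-8)
    expect_identical(hclust_step_partitions(cl$hclust, n), oracle$partitions)
    # merge heights are non-decreasing
    expect_true(!is.unsorted(cl$merge_heights))
    # cutting at 0 gives singletons; above the max height, one cluster
    expect_equal(length(unique(cutree(cl$hclust, h = 0))), n)
    expect_equal(length(unique(cutree(cl$hclust,
                                      h = max(cl$merge_heights) + 1))), 1L)
  }
})

test_that("complete-linkage mode guarantees within-cluster r2 above threshold", {
  set.seed(703)
  # three LD blocks: markers within a block copy a template with sparse flips
  template <- matrix(sample(0:2, 3 * 80, replace = TRUE), 3, 80)
  dos <- template[rep(1:3, each = 4), ]
  flips <- matrix(runif(length(dos)) < 0.03, nrow(dos))
  dos[flips] <- (dos[flips] + 1) %% 3
  r2 <- r2_matrix(genotype_panel(dos, marker_ids = sprintf("m%02d", 1:12)))
  cl <- ward_cluster(1 - r2, cut_height = 0.3, method = "complete")
  multi <- 0L
  for (k in unique(cl$assignments)) {
    members <- which(cl$assignments == k)
    if (length(members) > 1) {
      multi <- multi + 1L
      expect_true(all(r2[members, members] >= 0.7 - 1e-12))
    }
  }
  expect_gt(multi, 0L)
})

test_that("cluster representatives are the lead markers", {
  assignments <- c(m1 = 1L, m2 = 1L, m3 = 2L)
  mk <- data.frame(id = c("m1", "m2", "m3"), pos = c(10L, 20L, 30L),
                   p = c(0.5, 0.01, 0.9))
  expect_identical(cluster_representatives(assignments, mk), c("m2", "m3"))
  # tie on p: smaller position wins
  mk$p <- c(0.5, 0.5, 0.9)
  expect_identical(cluster_representatives(assignments, mk), c("m1", "m3"))
})

test_that("permutation null is smoothed, bounded and seed-deterministic", {
  set.seed(704)
  inc <- rbind(matrix(TRUE, 5, 2), matrix(FALSE, 300, 2))
  om <- overlap_matrix(inc)
  reps <- om$marker_ids[1:5]
  pool <- om$marker_ids[6:305]
  pn <- cluster_enrichment_null(reps, om, pool, n_perm = 999, seed = 11)
  # observed exceeds every permuted statistic: p attains 1/(n_perm + 1)
  expect_equal(unname(pn$perm_p), c(1 / 1000, 1 / 1000))
  expect_true(all(pn$perm_p > 0))

  # determinism: same seed identical, different seed differs
  inc_r <- matrix(runif(500 * 2) < 0.3, 500, 2)
  om_r <- overlap_matrix(inc_r)
  reps_r <- om_r$marker_ids[1:40]
  pool_r <- om_r$marker_ids[41:500]
  pr1 <- cluster_enrichment_null(reps_r, om_r, pool_r, n_perm = 499, seed = 11)
  pr2 <- cluster_enrichment_null(reps_r, om_r, pool_r, n_perm = 499, seed = 11)
  expect_identical(pr1$perm_p, pr2$perm_p)
  pr3 <- cluster_enrichment_null(reps_r, om_r, pool_r, n_perm = 499, seed = 12)
  expect_false(identical(pr1$perm_p, pr3$perm_p))

  expect_error(cluster_enrichment_null(reps, om, c(reps[1], pool), 999, 1),
               "disjoint")
  expect_error(cluster_enrichment_null(pool[1:10], om, pool[11:15], 999, 1),
               "smaller")
  expect_error(cluster_enrichment_null(reps, om, pool, n_perm = 10), ">= 100")
})

test_that("VCF genotype input is hard-called to dosages", {
  skip_if_not_installed("vcfR")
  dir <- withr::local_tempdir()
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
           "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
           "1\t200\trs2\tA\tG\t.\tPASS\t.\tGT\t1|1\t0|0\t./.")
  writeLines(vcf, file.path(dir, "p.vcf"))
  panel <- read_genotypes(file.path(dir, "p.vcf"))
  expect_equal(unname(panel$dosages["rs1", ]), c(0, 1, 2))
  expect_equal(unname(panel$dosages["rs2", ]), c(2, 0, NA))
})
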