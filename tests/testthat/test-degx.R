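make_expr <- function(vals, n1 = 3, n2 = 3, p2g = NULL) {
  expression_matrix(vals, factor(rep(c("g1", "g2"), c(n1, n2)),
                                 levels = c("g1", "g2")), p2g)
}

test_that("d0 = 0 recovers the classical pooled two-sample t", {
  set.seed(801)
  vals <- matrix(rnorm(50 * 6), 50, 6)
  expr <- make_expr(vals)
  fit <- fit_moderated_t(expr, d0 = 0)
  for (i in c(1, 17, 50)) {
    tt <- t.test(vals[i, 4:6], vals[i, 1:3], var.equal = TRUE)
    expect_equal(fit$table$t_mod[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(fit$table$p[i], tt$p.value, tolerance = 1e-10)
  }
  expect_equal(fit$table$df_total, rep(4, 50))
})

test_that("posterior variance is a convex combination and d0 -> Inf collapses it", {
  set.seed(802)
  vals <- matrix(rnorm(200 * 6, sd = rep(sqrt(0.05 * 4 / rchisq(200, 4)),
                                         each = 1)), 200, 6)
  expr <- make_expr(vals)
  fit <- fit_moderated_t(expr)
  lo <- pmin(fit$s0_sq, fit$table$s_sq)
  hi <- pmax(fit$s0_sq, fit$table$s_sq)
  expect_true(all(fit$table$s_tilde_sq >= lo - 1e-12 &
                    fit$table$s_tilde_sq <= hi + 1e-12))

  fit_inf <- fit_moderated_t(expr, d0 = 1e8)
  s0 <- fit_inf$s0_sq
  expect_equal(fit_inf$table$s_tilde_sq, rep(s0, 200), tolerance = 1e-5)

  # |t| ranking is invariant to global rescaling
  fit2 <- fit_moderated_t(make_expr(vals * 7))
  expect_identical(order(-abs(fit$table$t_mod)), order(-abs(fit2$table$t_mod)))
})

test_that("hyperparameter estimation recovers planted d0 and s0_sq", {
  set.seed(803)
  nG <- 6000; d0 <- 4; s0 <- 0.05
  sigma2 <- s0 * d0 / rchisq(nG, d0)
  vals <- matrix(rnorm(nG * 6, 0, sqrt(sigma2)), nG, 6)
  fit <- fit_moderated_t(make_expr(vals))
  expect_gt(fit$d0, d0 * 0.75); expect_lt(fit$d0, d0 * 1.25)
  expect_gt(fit$s0_sq, s0 * 0.9); expect_lt(fit$s0_sq, s0 * 1.1)
})

test_that("moderated fit agrees with the limma cross-check", {
  skip_if_not_installed("limma")
  set.seed(804)
  nG <- 2000
  sigma2 <- 0.05 * 4 / rchisq(nG, 4)
  lfc <- ifelse(runif(nG) < 0.1, rnorm(nG, 0, 1), 0)
  vals <- matrix(rnorm(nG * 6, 0, sqrt(sigma2)), nG, 6) +
    outer(lfc, c(-0.5, -0.5, -0.5, 0.5, 0.5, 0.5))
  fit <- fit_moderated_t(make_expr(vals))
  design <- cbind(1, rep(0:1, each = 3))
  lf <- limma::eBayes(limma::lmFit(vals, design))
  expect_equal(fit$d0, lf$df.prior, tolerance = 0.05)
  expect_equal(fit$s0_sq, lf$s2.prior, tolerance = 0.01)
  expect_equal(fit$table$t_mod, unname(lf$t[, 2]), tolerance = 1e-6)
  expect_equal(fit$table$p, unname(lf$p.value[, 2]), tolerance = 1e-6)
})

test_that("zero-variance probesets are shrunk and flagged", {
  vals <- rbind(matrix(rnorm(40 * 6), 40, 6),
                matrix(5, 1, 6))
  expect_message(fit <- fit_moderated_t(make_expr(vals)), "zero residual")
  expect_equal(fit$table$s_sq[41], 0)
  expect_gt(fit$table$s_tilde_sq[41], 0)
})

test_that("probeset collapse keeps the most significant probeset per gene", {
  res <- data.frame(probeset = c("p1", "p2", "p3", "p4"),
                    p = c(0.01, 0.2, 0.5, 0.5),
                    t_mod = c(3, 1, -2, 1.5),
                    stringsAsFactors = FALSE)
  map <- data.frame(probeset = c("p1", "p2", "p3", "p4"),
                    gene = c("A", "A", "B", "B"))
  out <- collapse_probesets(res, map)
  expect_equal(out$probeset[out$gene == "A"], "p1")
  # tie on p: larger |t_mod| wins, for either input order
  expect_equal(out$probeset[out$gene == "B"], "p3")
  out_rev <- collapse_probesets(res[4:1, ], map)
  expect_equal(out_rev$probeset[out_rev$gene == "B"], "p3")

  # one probeset per gene: identity
  map1 <- data.frame(probeset = res$probeset, gene = paste0("G", 1:4))
  expect_equal(nrow(collapse_probesets(res, map1)), 4L)

  # unmapped probesets are dropped with a message
  expect_message(dropped <- collapse_probesets(res, map[1:3, ]), "unmapped")
  expect_equal(nrow(dropped), 2L)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_error(bh_fdr(c(0.1, 0)), "\\(0, 1\\]")
  set.seed(805)
  for (rep in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_step_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p & q <= 1))
    expect_true(!is.unsorted(q[order(p)]))
  }
})

test_that("DEG calls are strict and fold changes on the ratio scale", {
  res <- data.frame(gene = c("a", "b", "c"), p = c(0.001, 0.02, 0.9),
                    log_fc = c(1, -0.6, 0))
  res$fdr <- c(0.01, 0.05, 0.9)
  out <- call_degs(res, fdr_threshold = 0.05)
  expect_identical(out$is_deg, c(TRUE, FALSE, FALSE))  # fdr == 0.05 is not a DEG
  expect_equal(out$fc_ratio, c(2, 2^-0.6, 1))
})
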