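# Independent brute-force oracles used to check the implementation paths.
# These deliberately share no code with the package internals.

# Exact 2x2 test by direct enumeration of all tables with the observed
# margins, probabilities from log binomial coefficients.
fisher_enum_oracle <- function(a, b, c, d, alternative = "two.sided") {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(N, c1)
  probs <- exp(logp)
  p_obs <- probs[xs == a]
  if (alternative == "two.sided") {
    min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  } else {
    min(1, sum(probs[xs >= a]))
  }
}

# O(n*m) overlap scan: 1-based marker position pos overlaps BED interval
# [s, e) iff s <= pos - 1 < e.
naive_overlap_oracle <- function(markers, intervals) {
  vapply(seq_len(nrow(markers)), function(i) {
    any(intervals$chrom == markers$chrom[i] &
          intervals$start <= markers$pos[i] - 1 &
          markers$pos[i] - 1 < intervals$end)
  }, logical(1))
}

# Connected components of the graph joining markers on one chromosome
# whose distance is strictly below max_gap; returns a canonical partition
# (list of sorted id vectors, ordered by first id).
cc_loci_oracle <- function(markers, max_gap) {
  comps <- list()
  for (ch in unique(markers$chrom)) {
    mc <- markers[markers$chrom == ch, , drop = FALSE]
    n <- nrow(mc)
    adj <- abs(outer(mc$pos, mc$pos, "-")) < max_gap
    seen <- rep(FALSE, n)
    for (s in seq_len(n)) {
      if (seen[s]) next
      queue <- s; comp <- integer(0)
      while (length(queue) > 0) {
        v <- queue[1]; queue <- queue[-1]
        if (seen[v]) next
        seen[v] <- TRUE
        comp <- c(comp, v)
        queue <- c(queue, which(adj[v, ] & !seen))
      }
      comps[[length(comps) + 1L]] <- sort(mc$id[comp])
    }
  }
  comps[order(vapply(comps, `[[`, "", 1L))]
}

canonical_partition <- function(id_sets) {
  id_sets <- lapply(id_sets, sort)
  id_sets[order(vapply(id_sets, `[[`, "", 1L))]
}

# Direct Lance-Williams recurrence for the squared-distance Ward update:
# d(ij,k) = sqrt(((ni+nk) d(i,k)^2 + (nj+nk) d(j,k)^2 - nk d(i,j)^2) /
#                (ni + nj + nk)).
# Returns merge heights and the partition (over leaf indices) after each
# merge, canonicalized for labeling-independent comparison.
lw_ward_oracle <- function(dmat) {
  n <- nrow(dmat)
  D <- dmat
  sizes <- rep(1L, n)
  members <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  heights <- numeric(0)
  partitions <- list()
  while (sum(active) > 1L) {
    act <- which(active)
    best <- c(NA, NA); best_d <- Inf
    for (ii in seq_along(act)) for (jj in seq_along(act)) {
      if (jj <= ii) next
      i <- act[ii]; j <- act[jj]
      if (D[i, j] < best_d) { best_d <- D[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, best_d)
    ni <- sizes[i]; nj <- sizes[j]
    for (k in act) {
      if (k == i || k == j) next
      nk <- sizes[k]
      dnew <- sqrt(((ni + nk) * D[i, k]^2 + (nj + nk) * D[j, k]^2 -
                      nk * D[i, j]^2) / (ni + nj + nk))
      D[i, k] <- D[k, i] <- dnew
    }
    sizes[i] <- ni + nj
    members[[i]] <- c(members[[i]], members[[j]])
    active[j] <- FALSE
    part <- lapply(members[active], sort)
    partitions[[length(partitions) + 1L]] <-
      part[order(vapply(part, `[[`, 0L, 1L))]
  }
  list(heights = heights, partitions = partitions)
}

# Partitions induced by an hclust merge sequence, canonicalized the same
# way as the oracle's.
hclust_step_partitions <- function(hc, n) {
  out <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    assign <- stats::cutree(hc, k = n - s)
    part <- unname(split(seq_len(n), assign))
    part <- lapply(part, sort)
    out[[s]] <- part[order(vapply(part, `[[`, 0L, 1L))]
  }
  out
}

# Benjamini-Hochberg step-up from the definition.
bh_step_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Upper tail of the 1-df chi-square by numeric integration of the density.
chi2_tail_numint <- function(x) {
  stats::integrate(function(t) exp(-t / 2) / sqrt(2 * pi * t),
                   lower = x, upper = Inf, rel.tol = 1e-10)$value
}

# Random Bernoulli incidence for enrichment simulations.
random_incidence <- function(n, K, rate) {
  matrix(stats::runif(n * K) < rate, n, K)
}
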