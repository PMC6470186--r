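#' Configuration for the synthetic-data generator
#'
#' Defines a complete simulated study: two case-vs-control GWAS
#' summary-statistic sets with planted associated loci, per-cell-type
#' enhancer tracks with a planted overlap odds ratio, a block-LD genotype
#' panel, eQTL/drug/gene tables with planted causal genes, and a two-group
#' expression matrix with planted fold changes. Every generated quantity
#' is a pure function of this configuration (the seed fixes all draws).
#'
#' Defaults describe the study scale the package targets: 49 planted loci
#' of 2-5 suggestive markers (about 170 suggestive markers in total) among
#' 5,000 null markers; 20 cell types of which 2 carry a planted overlap
#' odds ratio of 3 at a per-cell-type base overlap rate of 0.3; a
#' 200-sample genotype panel with within-locus r-squared near 0.95; and a
#' 3 + 3 expression design with prior variance 0.05 on 4 prior degrees of
#' freedom and 10\% background differential expression.
#'
#' @param seed Integer master seed.
#' @param n_null_markers Number of null (unassociated) markers.
#' @param n_planted_loci Number of planted associated loci.
#' @param markers_per_locus Integer vector sampled uniformly for per-locus
#'   marker counts.
#' @param n_celltypes,n_planted_celltypes Number of enhancer tracks and how
#'   many carry the planted odds ratio.
#' @param or_target Planted overlap odds ratio for suggestive markers in
#'   planted cell types.
#' @param base_overlap_rate Per-cell-type Bernoulli overlap rate for all
#'   other marker/cell-type pairs.
#' @param se Per-comparison standard error of beta.
#' @param beta_sd SD of the shared null effect drawn per marker.
#' @param delta Between-comparison beta difference at planted markers.
#' @param p_thresh,max_gap Suggestive threshold and locus gap rule used
#'   when realizing planted structure.
#' @param n_samples Genotype-panel sample count.
#' @param r2_within Target within-locus pairwise r-squared.
#' @param n_genes Total genes in the expression matrix (includes planted
#'   causal genes).
#' @param probes_per_gene Probesets per gene.
#' @param d0,s0_sq Variance-prior degrees of freedom and scale for
#'   expression noise.
#' @param pi_de Background differential-expression rate.
#' @param lfc_sd SD of background log2 fold changes.
#' @param planted_lfc Range of absolute log2 fold change for planted
#'   causal genes (uniform; sign random).
#' @param n_per_group Samples per expression group.
#' @param prob_eqtl Probability a planted locus carries eQTL (rather than
#'   proximity) evidence for its causal gene.
#' @param chrom_length Simulated chromosome length in bp (22 autosomes).
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_null_markers = 5000L,
                         n_planted_loci = 49L,
                         markers_per_locus = 2:5,
                         n_celltypes = 20L,
                         n_planted_celltypes = 2L,
                         or_target = 3,
                         base_overlap_rate = 0.3,
                         se = 0.1,
                         beta_sd = 0.05,
                         delta = 0.9,
                         p_thresh = 1e-4,
                         max_gap = 5e5,
                         n_samples = 200L,
                         r2_within = 0.95,
                         n_genes = 2000L,
                         probes_per_gene = 2L,
                         d0 = 4,
                         s0_sq = 0.05,
                         pi_de = 0.1,
                         lfc_sd = 1,
                         planted_lfc = c(1, 2),
                         n_per_group = 3L,
                         prob_eqtl = 0.8,
                         chrom_length = 1.5e8) {
  cfg <- as.list(environment())
  rates <- c(base_overlap_rate = base_overlap_rate,
             prob_eqtl = prob_eqtl, p_thresh = p_thresh)
  if (any(rates <= 0 | rates >= 1)) {
    stop("rates/probabilities must lie in (0, 1)", call. = FALSE)
  }
  if (pi_de < 0 || pi_de >= 1) {
    stop("pi_de must lie in [0, 1)", call. = FALSE)
  }
  if (r2_within <= 0 || r2_within > 1) {
    stop("r2_within must lie in (0, 1]", call. = FALSE)
  }
  stopifnot(or_target > 0, se > 0, n_celltypes >= n_planted_celltypes,
            n_per_group >= 2, n_samples >= 2, max_gap > 0,
            length(planted_lfc) == 2L, planted_lfc[1] > 0)
  stopifnot(seed == floor(seed), abs(seed) < 2^31)
  class(cfg) <- "synth_config"
  cfg
}

# Run code with a stage-derived seed, restoring the caller's RNG state.
with_stage_seed <- function(cfg, stage, code) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(derive_seed(cfg$seed, stage))
  force(code)
}

#' Generate two case-vs-control summary-statistic sets
#'
#' Null markers share a true beta drawn once per marker; each comparison
#' observes it plus independent `N(0, se^2)` noise, so the indirect
#' chi-square is central. Planted markers carry a between-comparison beta
#' difference of `delta`, spaced so each planted locus satisfies the
#' locus gap rule, on 5 kb grid positions kept clear of other loci and
#' (for planted loci) of the MHC mask.
#'
#' @param cfg A `synth_config`.
#' @return A list with `marker_assoc` data frames `a` and `b` and a
#'   `truth` list (`planted_loci` data frame with spans and member ids,
#'   `planted_marker_ids`).
#' @export
gen_sumstats <- function(cfg) {
  with_stage_seed(cfg, 1L, {
    chroms <- as.character(1:22)
    slot_w <- 5e6
    slots_per_chrom <- floor(cfg$chrom_length / slot_w)
    slot_tab <- expand.grid(chrom = chroms,
                            slot = seq_len(slots_per_chrom) - 1L,
                            stringsAsFactors = FALSE)
    # keep planted loci clear of the MHC mask (chr6 26-34 Mb)
    mhc_hit <- slot_tab$chrom == "6" &
      (slot_tab$slot * slot_w) < 35e6 & ((slot_tab$slot + 1) * slot_w) > 25e6
    slot_tab <- slot_tab[!mhc_hit, , drop = FALSE]
    pick <- slot_tab[sample.int(nrow(slot_tab), cfg$n_planted_loci), ,
                     drop = FALSE]
    planted <- vector("list", cfg$n_planted_loci)
    for (i in seq_len(cfg$n_planted_loci)) {
      n_mk <- if (length(cfg$markers_per_locus) == 1L) cfg$markers_per_locus
              else sample(cfg$markers_per_locus, 1L)
      gaps <- round(stats::runif(n_mk - 1L, 1e4, 0.8 * cfg$max_gap))
      start <- pick$slot[i] * slot_w + round(stats::runif(1L, 5e5, 1e6))
      pos <- start + c(0, cumsum(gaps))
      planted[[i]] <- data.frame(chrom = pick$chrom[i], pos = pos,
                                 locus = i, stringsAsFactors = FALSE)
    }
    planted <- do.call(rbind, planted)
    # null markers on a 5 kb grid, never inside a planted slot (so later
    # enhancer intervals, <= 2 kb, cannot bridge two markers' truth)
    planted_slots <- paste(pick$chrom, pick$slot)
    grid_tab <- expand.grid(chrom = chroms,
                            slot = seq_len(slots_per_chrom) - 1L,
                            stringsAsFactors = FALSE)
    grid_tab <- grid_tab[!paste(grid_tab$chrom, grid_tab$slot) %in%
                           planted_slots, , drop = FALSE]
    offsets_per_slot <- slot_w / 5000L
    cells <- grid_tab[sample.int(nrow(grid_tab), cfg$n_null_markers,
                                 replace = TRUE), , drop = FALSE]
    off <- sample.int(offsets_per_slot, cfg$n_null_markers, replace = TRUE)
    null_pos <- data.frame(chrom = cells$chrom,
                           pos = cells$slot * slot_w + off * 5000L,
                           locus = 0L, stringsAsFactors = FALSE)
    null_pos <- null_pos[!duplicated(paste(null_pos$chrom, null_pos$pos)), ,
                         drop = FALSE]
    mk <- rbind(planted, null_pos)
    mk <- mk[order(match(mk$chrom, chroms), mk$pos), , drop = FALSE]
    n <- nrow(mk)
    mk$id <- sprintf("rs%06d", seq_len(n))
    alleles <- c("A", "C", "G", "T")
    ref <- sample(alleles, n, replace = TRUE)
    alt_shift <- sample.int(3L, n, replace = TRUE)
    alt <- alleles[(match(ref, alleles) + alt_shift - 1L) %% 4L + 1L]
    beta_shared <- stats::rnorm(n, 0, cfg$beta_sd)
    is_planted <- mk$locus > 0L
    mu_a <- beta_shared + ifelse(is_planted, cfg$delta / 2, 0)
    mu_b <- beta_shared - ifelse(is_planted, cfg$delta / 2, 0)
    beta_a <- mu_a + stats::rnorm(n, 0, cfg$se)
    beta_b <- mu_b + stats::rnorm(n, 0, cfg$se)
    mk_assoc <- function(beta) {
      df <- data.frame(chrom = mk$chrom, pos = as.integer(mk$pos), id = mk$id,
                       ref = ref, alt = alt, beta = beta,
                       se = rep(cfg$se, n),
                       p = 2 * stats::pnorm(-abs(beta) / cfg$se),
                       stringsAsFactors = FALSE)
      class(df) <- c("marker_assoc", "data.frame")
      df
    }
    truth_loci <- do.call(rbind, lapply(split(mk[is_planted, ],
                                              mk$locus[is_planted]),
      function(g) data.frame(locus = g$locus[1L], chrom = g$chrom[1L],
                             start = min(g$pos), end = max(g$pos),
                             n_markers = nrow(g),
                             marker_ids = I(list(g$id)),
                             stringsAsFactors = FALSE)))
    truth_loci <- truth_loci[order(truth_loci$locus), , drop = FALSE]
    rownames(truth_loci) <- NULL
    list(a = mk_assoc(beta_a), b = mk_assoc(beta_b),
         truth = list(planted_loci = truth_loci,
                      planted_marker_ids = mk$id[is_planted]))
  })
}

#' Generate per-cell-type enhancer tracks with a planted odds ratio
#'
#' Overlap is generated at the marker level: each marker/cell-type pair is
#' an independent Bernoulli draw at rate `q = base_overlap_rate`, except
#' suggestive markers in planted cell types, which use the rate `q'`
#' solving `q'/(1-q') = OR_target * q/(1-q)`. Each positive draw is
#' realized as a 200-2,000 bp interval covering the marker position.
#'
#' @param cfg A `synth_config`.
#' @param markers Data frame with `id, chrom, pos`.
#' @param suggestive Logical vector aligned with `markers` (typically the
#'   realized suggestive status from the analysis stages).
#' @return A list with `tracks` (named list of `enhancer_track`),
#'   `incidence_truth` (logical matrix markers x cell types), and
#'   `planted_celltypes` (labels of the planted tracks).
#' @export
gen_enhancer_tracks <- function(cfg, markers, suggestive) {
  stopifnot(length(suggestive) == nrow(markers))
  with_stage_seed(cfg, 2L, {
    n <- nrow(markers)
    K <- cfg$n_celltypes
    labels <- sprintf("CT%02d", seq_len(K))
    planted_ct <- labels[seq_len(cfg$n_planted_celltypes)]
    q <- cfg$base_overlap_rate
    odds_hi <- cfg$or_target * q / (1 - q)
    q_hi <- odds_hi / (1 + odds_hi)
    inc <- matrix(FALSE, n, K, dimnames = list(markers$id, labels))
    for (k in seq_len(K)) {
      rate <- rep(q, n)
      if (labels[k] %in% planted_ct) rate[suggestive] <- q_hi
      inc[, k] <- stats::runif(n) < rate
    }
    tracks <- vector("list", K)
    for (k in seq_len(K)) {
      rows <- which(inc[, k])
      if (length(rows) > 0L) {
        len <- sample(200:2000, length(rows), replace = TRUE)
        u <- vapply(len, function(L) sample.int(L, 1L) - 1L, integer(1))
        start0 <- pmax(0L, as.integer(markers$pos[rows]) - 1L - u)
        ints <- data.frame(chrom = markers$chrom[rows],
                           start = start0, end = start0 + len,
                           stringsAsFactors = FALSE)
      } else {
        ints <- data.frame(chrom = character(0), start = integer(0),
                           end = integer(0))
      }
      tracks[[k]] <- enhancer_track(labels[k], ints)
    }
    names(tracks) <- labels
    list(tracks = tracks, incidence_truth = inc,
         planted_celltypes = planted_ct)
  })
}

#' Generate a block-LD genotype panel
#'
#' Within a block (one planted locus), markers copy a latent biallelic
#' haplotype with per-marker flip noise `eps = (1 - r2_within^(1/4)) / 2`,
#' which yields pairwise dosage correlation near `r2_within` in large
#' samples; blocks are independent.
#'
#' @param cfg A `synth_config`.
#' @param marker_ids Marker ids to simulate.
#' @param block Integer/character block label per marker (markers sharing
#'   a label form an LD block; unique labels give independent markers).
#' @return A `genotype_panel`.
#' @export
gen_genotype_panel <- function(cfg, marker_ids, block) {
  stopifnot(length(block) == length(marker_ids))
  with_stage_seed(cfg, 3L, {
    n_mk <- length(marker_ids)
    n_s <- cfg$n_samples
    eps <- (1 - cfg$r2_within^(1 / 4)) / 2
    dos <- matrix(0L, n_mk, n_s, dimnames = list(marker_ids, NULL))
    for (b in unique(block)) {
      rows <- which(block == b)
      h1 <- stats::runif(n_s) < 0.5
      h2 <- stats::runif(n_s) < 0.5
      for (r in rows) {
        a1 <- xor(h1, stats::runif(n_s) < eps)
        a2 <- xor(h2, stats::runif(n_s) < eps)
        dos[r, ] <- as.integer(a1) + as.integer(a2)
      }
    }
    genotype_panel(dos, marker_ids = marker_ids,
                   sample_ids = sprintf("s%03d", seq_len(n_s)))
  })
}

#' Generate eQTL, drug, gene-annotation and expression data
#'
#' Per planted locus, two genes are placed: a "near" gene whose span
#' covers the locus and a "far" gene 30-300 kb away. With probability
#' `prob_eqtl` the locus carries eQTL evidence — every planted marker
#' gets an eQTL for the far (causal) gene with p far smaller than any
#' decoy record — otherwise the near gene is causal by proximity and the
#' locus has no eQTL records. Causal genes are linked to arthritis drugs;
#' decoy drug rows carry other indications. The expression matrix draws
#' per-gene variances from the scaled inverse-chi-square prior
#' `(d0, s0_sq)`, plants `|log2 FC| ~ U(planted_lfc)` on causal genes and
#' Bernoulli(`pi_de`) background differential expression.
#'
#' @param cfg A `synth_config`.
#' @param truth The `truth` list from [gen_sumstats()].
#' @return A list with `eqtls`, `drugs`, `genes` (data frames), `expr`
#'   (an `expression_matrix`) and `truth` (per-locus causal gene table
#'   `causal` and per-gene `deg_truth`).
#' @export
gen_tables_and_expression <- function(cfg, truth) {
  with_stage_seed(cfg, 4L, {
    loci <- truth$planted_loci
    L <- nrow(loci)
    arthritis_drugs <- c("methotrexate", "cyclosporine", "dexamethasone",
                         "indomethacin", "celecoxib", "prednisone",
                         "azathioprine", "diclofenac", "piroxicam")
    other_drugs <- data.frame(drug = c("lisinopril", "metformin", "statinX"),
                              indication = c("hypertension", "diabetes",
                                             "hyperlipidemia"),
                              stringsAsFactors = FALSE)
    gene_rows <- list(); eqtl_rows <- list(); drug_rows <- list()
    causal_rows <- list()
    for (i in seq_len(L)) {
      lc <- loci[i, ]
      g_near <- sprintf("NEAR%02d", i)
      g_far <- sprintf("CAUS%02d", i)
      far_off <- round(stats::runif(1L, 3e4, 3e5))
      far_len <- round(stats::runif(1L, 2e4, 1e5))
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        chrom = lc$chrom,
        start = c(max(1, lc$start - 1e4), lc$end + far_off),
        end = c(lc$end + 1e4, lc$end + far_off + far_len),
        strand = c("+", "-"), symbol = c(g_near, g_far),
        stringsAsFactors = FALSE)
      use_eqtl <- stats::runif(1L) < cfg$prob_eqtl
      if (use_eqtl) {
        mids <- lc$marker_ids[[1L]]
        p_causal <- 10^-stats::runif(length(mids), 8, 20)
        eqtl_rows[[length(eqtl_rows) + 1L]] <- data.frame(
          marker_id = mids, gene = g_far, p = p_causal,
          stringsAsFactors = FALSE)
        causal_gene <- g_far
        evidence <- "eqtl"
      } else {
        causal_gene <- g_near
        evidence <- "proximity"
      }
      nd <- sample.int(3L, 1L)
      drug_rows[[length(drug_rows) + 1L]] <- data.frame(
        drug = sample(arthritis_drugs, nd), gene = causal_gene,
        indication = "arthritis", stringsAsFactors = FALSE)
      causal_rows[[i]] <- data.frame(locus = lc$locus, gene = causal_gene,
                                     evidence = evidence,
                                     stringsAsFactors = FALSE)
    }
    genes_df <- do.call(rbind, gene_rows)
    # background genes on otherwise empty territory: keep them clear of
    # the planted loci so they never tie with a planted candidate
    n_bg <- max(0L, cfg$n_genes - 2L * L)
    if (n_bg > 0L) {
      bg <- data.frame(chrom = sample(as.character(1:22), n_bg, replace = TRUE),
                       start = round(stats::runif(n_bg, 1e6, cfg$chrom_length - 1e6)),
                       stringsAsFactors = FALSE)
      bg$end <- bg$start + round(stats::runif(n_bg, 2e4, 2e5))
      for (it in 1:20) {
        clash <- rep(FALSE, n_bg)
        for (i in seq_len(L)) {
          lc <- loci[i, ]
          clash <- clash | (bg$chrom == lc$chrom &
                              bg$start <= lc$end + 5e5 &
                              bg$end >= lc$start - 5e5)
        }
        if (!any(clash)) break
        k <- sum(clash)
        bg$chrom[clash] <- sample(as.character(1:22), k, replace = TRUE)
        bg$start[clash] <- round(stats::runif(k, 1e6, cfg$chrom_length - 1e6))
        bg$end[clash] <- bg$start[clash] + round(stats::runif(k, 2e4, 2e5))
      }
      bg$strand <- sample(c("+", "-"), n_bg, replace = TRUE)
      bg$symbol <- sprintf("BG%04d", seq_len(n_bg))
      genes_df <- rbind(genes_df, bg[c("chrom", "start", "end", "strand",
                                       "symbol")])
    }
    rownames(genes_df) <- NULL
    eqtls <- if (length(eqtl_rows) > 0L) do.call(rbind, eqtl_rows) else
      data.frame(marker_id = character(0), gene = character(0), p = numeric(0))
    # weak decoy eQTLs for near genes of eQTL loci (never competitive)
    causal <- do.call(rbind, causal_rows)
    eqtl_loci <- causal$locus[causal$evidence == "eqtl"]
    if (length(eqtl_loci) > 0L) {
      decoy <- do.call(rbind, lapply(eqtl_loci, function(li) {
        lc <- loci[loci$locus == li, ]
        data.frame(marker_id = lc$marker_ids[[1L]][1L],
                   gene = sprintf("NEAR%02d", which(loci$locus == li)),
                   p = 10^-stats::runif(1L, 1, 4), stringsAsFactors = FALSE)
      }))
      eqtls <- rbind(eqtls, decoy)
    }
    drugs <- do.call(rbind, drug_rows)
    if (n_bg >= 3L) {
      drugs <- rbind(drugs,
                     data.frame(drug = other_drugs$drug,
                                gene = sprintf("BG%04d", 1:3),
                                indication = other_drugs$indication,
                                stringsAsFactors = FALSE))
    }
    rownames(drugs) <- NULL
    # expression: all annotated genes
    all_genes <- genes_df$symbol
    nG <- length(all_genes)
    is_causal <- all_genes %in% causal$gene
    de_bg <- stats::runif(nG) < cfg$pi_de
    lfc <- ifelse(de_bg, stats::rnorm(nG, 0, cfg$lfc_sd), 0)
    lfc[is_causal] <- sample(c(-1, 1), sum(is_causal), replace = TRUE) *
      stats::runif(sum(is_causal), cfg$planted_lfc[1L], cfg$planted_lfc[2L])
    sigma2 <- cfg$s0_sq * cfg$d0 / stats::rchisq(nG, df = cfg$d0)
    npg <- cfg$probes_per_gene
    n1 <- cfg$n_per_group
    probes <- sprintf("%s_at%d", rep(all_genes, each = npg),
                      rep(seq_len(npg), nG))
    base_expr <- stats::runif(nG, 5, 12)
    mu1 <- rep(base_expr - lfc / 2, each = npg)
    mu2 <- rep(base_expr + lfc / 2, each = npg)
    sdv <- rep(sqrt(sigma2), each = npg)
    nP <- length(probes)
    vals <- cbind(
      matrix(stats::rnorm(nP * n1, mu1, sdv), nP, n1),
      matrix(stats::rnorm(nP * n1, mu2, sdv), nP, n1))
    dimnames(vals) <- list(probes,
                           c(sprintf("pre_%d", seq_len(n1)),
                             sprintf("post_%d", seq_len(n1))))
    p2g <- data.frame(probeset = probes, gene = rep(all_genes, each = npg),
                      stringsAsFactors = FALSE)
    expr <- expression_matrix(vals,
                              group = factor(rep(c("pre", "post"), each = n1),
                                             levels = c("pre", "post")),
                              probe_to_gene = p2g)
    deg_truth <- data.frame(gene = all_genes, is_de = lfc != 0, log_fc = lfc,
                            stringsAsFactors = FALSE)
    list(eqtls = eqtls, drugs = drugs, genes = genes_df, expr = expr,
         truth = list(causal = causal, deg_truth = deg_truth))
  })
}

#' Generate and write a complete synthetic input bundle
#'
#' Runs all generators with one configuration, realizes the suggestive
#' marker set with the package's own analysis stages (so the planted
#' odds ratio is exact in the 2x2 the enrichment stage sees), and writes
#' every input the pipeline needs into `dir`: `sumstats_a.tsv`,
#' `sumstats_b.tsv`, one BED per cell type under `tracks/`,
#' `genotypes.tsv`, `eqtls.tsv`, `drugs.tsv`, `genes.tsv`,
#' `expression.tsv`, a ready-to-run `config.yaml`, and a ground-truth
#' manifest `truth.yaml`.
#'
#' @param cfg A `synth_config`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the written `config` path and the
#'   `truth` manifest.
#' @export
gen_bundle <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ss <- gen_sumstats(cfg)
  write_sumstats(ss$a, file.path(dir, "sumstats_a.tsv"))
  write_sumstats(ss$b, file.path(dir, "sumstats_b.tsv"))
  ind <- indirect_meta(ss$a, ss$b)
  sugg_tab <- select_suggestive(ind, p_thresh = cfg$p_thresh)
  suggestive <- ind$id %in% sugg_tab$id
  markers <- data.frame(id = ind$id, chrom = ind$chrom, pos = ind$pos,
                        stringsAsFactors = FALSE)
  tr <- gen_enhancer_tracks(cfg, markers, suggestive)
  track_dir <- file.path(dir, "tracks")
  dir.create(track_dir, showWarnings = FALSE)
  for (t in tr$tracks) {
    write_tsv_bed <- t$intervals
    utils::write.table(write_tsv_bed, file.path(track_dir,
                                                paste0(t$cell_type, ".bed")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  loci_realized <- assemble_loci(sugg_tab, max_gap = cfg$max_gap)
  memb <- locus_membership(loci_realized)
  block <- memb$locus_label[match(sugg_tab$id, memb$id)]
  panel <- gen_genotype_panel(cfg, sugg_tab$id, block)
  gdf <- data.frame(marker_id = panel$marker_ids, panel$dosages,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(gdf, file.path(dir, "genotypes.tsv"))
  tb <- gen_tables_and_expression(cfg, ss$truth)
  write_tsv(tb$eqtls, file.path(dir, "eqtls.tsv"))
  write_tsv(tb$drugs, file.path(dir, "drugs.tsv"))
  write_tsv(tb$genes, file.path(dir, "genes.tsv"))
  expr_df <- data.frame(probeset = tb$expr$probeset_ids,
                        gene = tb$expr$probe_to_gene$gene,
                        tb$expr$values, check.names = FALSE,
                        stringsAsFactors = FALSE)
  write_tsv(expr_df, file.path(dir, "expression.tsv"))
  config <- list(
    sumstats_a = file.path(dir, "sumstats_a.tsv"),
    sumstats_b = file.path(dir, "sumstats_b.tsv"),
    tracks = track_dir,
    genotypes = file.path(dir, "genotypes.tsv"),
    eqtls = file.path(dir, "eqtls.tsv"),
    drugs = file.path(dir, "drugs.tsv"),
    genes = file.path(dir, "genes.tsv"),
    expression = file.path(dir, "expression.tsv"),
    expr_groups = list(g1 = sprintf("pre_%d", seq_len(cfg$n_per_group)),
                       g2 = sprintf("post_%d", seq_len(cfg$n_per_group))),
    seed = cfg$seed,
    out_dir = file.path(dir, "out"))
  yaml::write_yaml(config, file.path(dir, "config.yaml"))
  truth <- list(
    planted_loci = lapply(seq_len(nrow(ss$truth$planted_loci)), function(i) {
      l <- ss$truth$planted_loci[i, ]
      list(locus = l$locus, chrom = l$chrom, start = l$start, end = l$end,
           marker_ids = l$marker_ids[[1L]])
    }),
    planted_marker_ids = ss$truth$planted_marker_ids,
    planted_celltypes = tr$planted_celltypes,
    causal_genes = tb$truth$causal,
    deg_truth = tb$truth$deg_truth[tb$truth$deg_truth$is_de, ])
  yaml::write_yaml(list(planted_celltypes = truth$planted_celltypes,
                        n_planted_loci = nrow(ss$truth$planted_loci),
                        causal_genes = truth$causal_genes$gene,
                        causal_evidence = truth$causal_genes$evidence),
                   file.path(dir, "truth.yaml"))
  invisible(list(config = file.path(dir, "config.yaml"), truth = truth,
                 incidence_truth = tr$incidence_truth))
}
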