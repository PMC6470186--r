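#' Construct a genotype panel
#'
#' Allele-dosage matrix (markers x samples, values 0/1/2 or `NA`) used as
#' the reference panel for LD estimation.
#'
#' @param dosages Numeric matrix; rows are markers, columns samples.
#' @param marker_ids,sample_ids Optional labels (default: dimnames).
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosages, marker_ids = rownames(dosages),
                           sample_ids = colnames(dosages)) {
  dosages <- as.matrix(dosages)
  if (ncol(dosages) < 2L) stop("genotype panel needs >= 2 samples", call. = FALSE)
  vals <- dosages[!is.na(dosages)]
  if (any(!vals %in% c(0, 1, 2))) {
    stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  }
  if (is.null(marker_ids)) marker_ids <- paste0("m", seq_len(nrow(dosages)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(dosages)))
  dimnames(dosages) <- list(marker_ids, sample_ids)
  structure(list(dosages = dosages,
                 marker_ids = as.character(marker_ids),
                 sample_ids = as.character(sample_ids)),
            class = "genotype_panel")
}

#' Read a genotype panel from TSV or VCF
#'
#' TSV mode: first column marker id, remaining columns per-sample dosages
#' (0/1/2/NA). VCF mode (`.vcf` extension; requires the `vcfR` package):
#' GT fields are hard-called to dosages by counting alternate alleles.
#'
#' @param path Input path.
#' @return A `genotype_panel`.
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stop("VCF input requires the 'vcfR' package", call. = FALSE)
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    dos <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      parts <- suppressWarnings(as.integer(strsplit(g, "[/|]")[[1]]))
      if (anyNA(parts)) return(NA_real_)
      sum(parts > 0)
    })
    ids <- vcfR::getID(v)
    ids[is.na(ids)] <- paste0("m", which(is.na(ids)))
    return(genotype_panel(dos, marker_ids = ids, sample_ids = colnames(gt)))
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  genotype_panel(mat, marker_ids = as.character(df[[1L]]),
                 sample_ids = colnames(mat))
}

#' Pairwise LD (r-squared) matrix from dosages
#'
#' Composite LD: squared Pearson correlation of dosage vectors, computed
#' over samples non-missing for both markers.
#'
#' @param panel A `genotype_panel`.
#' @param max_missing Markers with a missing fraction above this are
#'   rejected (default 0.2).
#' @return Symmetric matrix in `[0, 1]` with unit diagonal, dimnames =
#'   marker ids.
#' @export
r2_matrix <- function(panel, max_missing = 0.2) {
  stopifnot(inherits(panel, "genotype_panel"))
  d <- panel$dosages
  miss <- rowMeans(is.na(d))
  if (any(miss > max_missing)) {
    stop("marker(s) with >", max_missing * 100, "% missing dosages: ",
         paste(utils::head(panel$marker_ids[miss > max_missing], 5L),
               collapse = ", "), call. = FALSE)
  }
  sds <- apply(d, 1L, stats::sd, na.rm = TRUE)
  mono <- !is.finite(sds) | sds == 0
  if (any(mono)) {
    stop("monomorphic marker(s): ",
         paste(utils::head(panel$marker_ids[mono], 5L), collapse = ", "),
         call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(t(d), use = "pairwise.complete.obs"))
  r2 <- r^2
  r2[!is.finite(r2)] <- 0
  diag(r2) <- 1
  r2 <- pmin(pmax(r2, 0), 1)
  dimnames(r2) <- list(panel$marker_ids, panel$marker_ids)
  r2
}

#' Ward hierarchical clustering of markers by LD distance
#'
#' Agglomerative clustering of the distance matrix `d = 1 - r^2` with the
#' squared-distance Ward update (the `ward.D2` criterion), cut at
#' `cut_height = 1 - r2_threshold` so that clusters are maximal subtrees
#' merged at height at most the cut. An alternative `"complete"` mode
#' guarantees every within-cluster pair satisfies `r^2 >= r2_threshold`
#' (complete linkage cut at the same height).
#'
#' @param dist_mat Symmetric distance matrix with zero diagonal
#'   (typically `1 - r2_matrix(panel)`).
#' @param cut_height Dendrogram cut height (default `0.1`, i.e. an r-squared
#'   threshold of 0.9).
#' @param method `"ward"` (default) or `"complete"`.
#' @return A list of class `ld_clusters`: integer `assignments` named by
#'   marker, numeric `merge_heights` (non-decreasing), the `hclust` object
#'   (or `NULL` for a single marker), and `cut_height`.
#' @export
ward_cluster <- function(dist_mat, cut_height = 0.1,
                         method = c("ward", "complete")) {
  method <- match.arg(method)
  dist_mat <- as.matrix(dist_mat)
  if (nrow(dist_mat) != ncol(dist_mat) ||
      !isTRUE(all.equal(dist_mat, t(dist_mat), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(dist_mat)) > 1e-8)) {
    stop("distance matrix must have zero diagonal", call. = FALSE)
  }
  n <- nrow(dist_mat)
  ids <- rownames(dist_mat) %||% paste0("m", seq_len(n))
  if (n == 1L) {
    return(structure(list(assignments = stats::setNames(1L, ids),
                          merge_heights = numeric(0),
                          hclust = NULL, cut_height = cut_height),
                     class = "ld_clusters"))
  }
  hc <- stats::hclust(stats::as.dist(dist_mat),
                      method = if (method == "ward") "ward.D2" else "complete")
  assignments <- stats::cutree(hc, h = cut_height)
  names(assignments) <- ids
  structure(list(assignments = assignments,
                 merge_heights = hc$height,
                 hclust = hc, cut_height = cut_height),
            class = "ld_clusters")
}

#' Pick one representative marker per LD cluster
#'
#' The representative is the member with the smallest association p-value,
#' ties broken by smaller position (the lead-marker convention).
#'
#' @param assignments Named cluster assignments from [ward_cluster()].
#' @param markers Data frame with `id`, `pos`, `p` covering all clustered
#'   markers.
#' @return Character vector of representative marker ids, one per cluster,
#'   ordered by cluster id.
#' @export
cluster_representatives <- function(assignments, markers) {
  idx <- match(names(assignments), markers$id)
  if (anyNA(idx)) stop("clustered marker(s) missing from 'markers'", call. = FALSE)
  df <- data.frame(id = names(assignments), cluster = assignments,
                   p = markers$p[idx], pos = markers$pos[idx],
                   stringsAsFactors = FALSE)
  df <- df[order(df$cluster, df$p, df$pos, df$id), , drop = FALSE]
  df$id[!duplicated(df$cluster)]
}

#' Permutation null for cluster-level enhancer enrichment
#'
#' Sensitivity analysis for the marker-level enrichment: the observed
#' statistic per cell type is the number of cluster representatives
#' overlapping that cell type's enhancers; the null draws equally many
#' markers uniformly without replacement from a candidate pool of
#' non-suggestive markers. Empirical p-values use add-one smoothing,
#' `p = (1 + #{perm >= obs}) / (1 + n_perm)`, so they are never zero and
#' attain their lower bound `1/(n_perm + 1)` when the observed statistic
#' exceeds every permuted one.
#'
#' @param representatives Character vector of representative marker ids
#'   (must be rows of `om`).
#' @param om An `overlap_matrix` covering representatives and pool.
#' @param candidate_pool Character vector of marker ids to draw from;
#'   must be disjoint from `representatives` and at least as large.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed; results are fully reproducible given it.
#' @return A list of class `perm_null` with `perm_p` (named per cell
#'   type), `observed`, `n_perm`, `seed`.
#' @export
cluster_enrichment_null <- function(representatives, om, candidate_pool,
                                    n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(om, "overlap_matrix"))
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  if (length(intersect(representatives, candidate_pool)) > 0L) {
    stop("candidate_pool must be disjoint from representatives", call. = FALSE)
  }
  if (length(candidate_pool) < length(representatives)) {
    stop("candidate pool smaller than the representative set", call. = FALSE)
  }
  rep_idx <- match(representatives, om$marker_ids)
  pool_idx <- match(candidate_pool, om$marker_ids)
  if (anyNA(rep_idx) || anyNA(pool_idx)) {
    stop("marker id(s) missing from the overlap matrix", call. = FALSE)
  }
  observed <- colSums(om$incidence[rep_idx, , drop = FALSE])
  r <- length(rep_idx)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  exceed <- integer(length(observed))
  for (b in seq_len(n_perm)) {
    draw <- pool_idx[sample.int(length(pool_idx), r)]
    stat <- colSums(om$incidence[draw, , drop = FALSE])
    exceed <- exceed + (stat >= observed)
  }
  perm_p <- (1 + exceed) / (1 + n_perm)
  names(perm_p) <- om$cell_types
  names(observed) <- om$cell_types
  structure(list(perm_p = perm_p, observed = observed,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "perm_null")
}
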