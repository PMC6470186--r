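#' Construct an active-enhancer track
#'
#' An enhancer track is a named set of genomic intervals (0-based,
#' half-open, BED convention) marking active enhancers — e.g. H3K27ac
#' peaks — for one cell type. Intervals are sorted and merged per
#' chromosome on construction; abutting half-open intervals merge, since
#' adjacency carries no gap.
#'
#' @param cell_type Track label.
#' @param intervals Data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open; `start < end`).
#' @return An object of class `enhancer_track`.
#' @export
enhancer_track <- function(cell_type, intervals) {
  stopifnot(is.character(cell_type), length(cell_type) == 1L)
  if (nrow(intervals) == 0L) {
    ints <- data.frame(chrom = character(0), start = integer(0),
                       end = integer(0), stringsAsFactors = FALSE)
  } else {
    if (any(intervals$start >= intervals$end)) {
      stop("interval with start >= end", call. = FALSE)
    }
    merged <- lapply(split(intervals, as.character(intervals$chrom)), function(d) {
      # 0-based half-open [s, e) == 1-based closed [s + 1, e]
      ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
      data.frame(chrom = d$chrom[1L],
                 start = IRanges::start(ir) - 1L,
                 end = IRanges::end(ir),
                 stringsAsFactors = FALSE)
    })
    ints <- do.call(rbind, merged)
    rownames(ints) <- NULL
    ints <- ints[order(ints$chrom, ints$start), , drop = FALSE]
    rownames(ints) <- NULL
  }
  structure(list(cell_type = cell_type, intervals = ints),
            class = "enhancer_track")
}

#' Read a BED3+ file as an enhancer track
#'
#' First three columns are `chrom, start, end` (0-based half-open); extra
#' columns are ignored. `track`/`browser`/`#` lines are skipped. Intervals
#' are merged on load.
#'
#' @param path Path to a BED file.
#' @param cell_type Label for the resulting track (default: file name
#'   without extension).
#' @return An `enhancer_track`.
#' @export
read_bed <- function(path, cell_type = sub("\\.bed$", "", basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !grepl("^(#|track\\b|browser\\b)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(enhancer_track(cell_type, data.frame(chrom = character(0),
                                                start = integer(0),
                                                end = integer(0))))
  }
  fields <- strsplit(lines[idx], "[ \t]+")
  n_fields <- lengths(fields)
  if (any(n_fields < 3L)) {
    stop("fewer than 3 BED columns at line ", idx[which(n_fields < 3L)[1L]],
         " of ", path, call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start_c <- vapply(fields, `[[`, "", 2L)
  end_c <- vapply(fields, `[[`, "", 3L)
  suppressWarnings({
    start <- as.numeric(start_c)
    end <- as.numeric(end_c)
  })
  bad <- which(is.na(start) | is.na(end) |
                 !is_wholenumber(start) | !is_wholenumber(end))
  if (length(bad) > 0L) {
    stop("non-integer coordinates at line ", idx[bad[1L]], " of ", path,
         call. = FALSE)
  }
  bad <- which(start >= end)
  if (length(bad) > 0L) {
    stop("start >= end at line ", idx[bad[1L]], " of ", path, call. = FALSE)
  }
  enhancer_track(cell_type, data.frame(chrom = chrom,
                                       start = as.integer(start),
                                       end = as.integer(end),
                                       stringsAsFactors = FALSE))
}

#' Read a directory or combined file of enhancer tracks
#'
#' Two input modes: a directory containing one BED file per cell type
#' (labels from file names), or a single BED file whose fourth column
#' carries the cell-type label.
#'
#' @param path Directory of `*.bed` files, or a single BED3+name file.
#' @return A named list of `enhancer_track` objects, in discovery order.
#' @export
read_tracks <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.bed$", full.names = TRUE))
    if (length(files) == 0L) stop("no .bed files in ", path, call. = FALSE)
    tracks <- lapply(files, read_bed)
  } else {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    df <- utils::read.table(path, header = FALSE, sep = "",
                            stringsAsFactors = FALSE, comment.char = "#")
    if (ncol(df) < 4L) {
      stop("combined track file needs a 4th (cell type) column", call. = FALSE)
    }
    names(df)[1:4] <- c("chrom", "start", "end", "cell_type")
    tracks <- lapply(split(df, df$cell_type), function(d) {
      enhancer_track(d$cell_type[1L], d[c("chrom", "start", "end")])
    })
  }
  labels <- vapply(tracks, `[[`, "", "cell_type")
  if (anyDuplicated(labels)) stop("duplicate cell_type labels", call. = FALSE)
  names(tracks) <- labels
  tracks
}

#' Test markers for enhancer overlap
#'
#' A marker is the single base at its 1-based position `pos`; it overlaps a
#' BED interval `[s, e)` iff `s <= pos - 1 < e` (so `[10, 20)` covers
#' 1-based positions 11..20). Lookup is an interval query against the
#' merged track.
#'
#' @param markers Data frame with `chrom` and 1-based `pos`.
#' @param track An `enhancer_track`.
#' @return Logical vector, one element per marker row. Markers on
#'   chromosomes absent from the track are `FALSE` (logged once per
#'   chromosome).
#' @export
marker_overlaps <- function(markers, track) {
  stopifnot(inherits(track, "enhancer_track"))
  n <- nrow(markers)
  res <- logical(n)
  if (n == 0L || nrow(track$intervals) == 0L) {
    if (n > 0L) {
      message("marker_overlaps: track '", track$cell_type, "' is empty")
    }
    return(res)
  }
  mchrom <- norm_chrom(markers$chrom)
  tints <- track$intervals
  tchrom <- norm_chrom(tints$chrom)
  unknown <- setdiff(unique(mchrom), unique(tchrom))
  for (uc in unknown) {
    message("marker_overlaps: chromosome '", uc, "' absent from track '",
            track$cell_type, "'")
  }
  for (ch in intersect(unique(mchrom), unique(tchrom))) {
    mi <- which(mchrom == ch)
    ti <- tchrom == ch
    subj <- IRanges::IRanges(start = tints$start[ti] + 1L, end = tints$end[ti])
    qry <- IRanges::IRanges(start = markers$pos[mi], width = 1L)
    hits <- IRanges::findOverlaps(qry, subj)
    res[mi[unique(S4Vectors::queryHits(hits))]] <- TRUE
  }
  res
}

#' Construct an overlap incidence matrix directly
#'
#' Wraps a precomputed logical incidence matrix (markers x cell types) in
#' the container used by the enrichment stage; `any_overlap` is derived
#' as the row-wise OR.
#'
#' @param incidence Logical matrix, markers in rows, cell types in columns.
#' @param marker_ids,cell_types Optional labels (default: dimnames).
#' @return An object of class `overlap_matrix`.
#' @export
overlap_matrix <- function(incidence, marker_ids = rownames(incidence),
                           cell_types = colnames(incidence)) {
  incidence <- as.matrix(incidence)
  storage.mode(incidence) <- "logical"
  if (is.null(marker_ids)) marker_ids <- paste0("m", seq_len(nrow(incidence)))
  if (is.null(cell_types)) cell_types <- paste0("ct", seq_len(ncol(incidence)))
  if (anyDuplicated(cell_types)) stop("duplicate cell_type labels", call. = FALSE)
  dimnames(incidence) <- list(marker_ids, cell_types)
  structure(list(marker_ids = as.character(marker_ids),
                 cell_types = as.character(cell_types),
                 incidence = incidence,
                 any_overlap = unname(rowSums(incidence) > 0)),
            class = "overlap_matrix")
}

#' Build the marker-by-cell-type overlap incidence matrix
#'
#' Columns follow the input track order; `any_overlap` is the row-wise OR
#' over cell types and defines the any-cell-type baseline used by the
#' enrichment stage.
#'
#' @param markers Data frame with `id`, `chrom`, `pos`.
#' @param tracks List of `enhancer_track` objects with unique labels.
#' @return An object of class `overlap_matrix`: list with `marker_ids`,
#'   `cell_types`, logical matrix `incidence`, and logical `any_overlap`.
#' @export
build_overlap_matrix <- function(markers, tracks) {
  stopifnot(length(tracks) >= 1L)
  labels <- vapply(tracks, `[[`, "", "cell_type")
  if (anyDuplicated(labels)) stop("duplicate cell_type labels", call. = FALSE)
  inc <- vapply(tracks, function(tr) marker_overlaps(markers, tr),
                logical(nrow(markers)))
  inc <- matrix(inc, nrow = nrow(markers), ncol = length(tracks))
  overlap_matrix(inc, marker_ids = as.character(markers$id),
                 cell_types = unname(labels))
}

#' Write an overlap incidence matrix as TSV
#'
#' @param om An `overlap_matrix`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_overlap_matrix <- function(om, path) {
  df <- data.frame(id = om$marker_ids,
                   om$incidence * 1L,
                   any_overlap = om$any_overlap * 1L,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}
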