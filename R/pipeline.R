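# End-to-end secretion time-series pipeline: ingestion, spatial aggregation,
# temporal averaging, baselining, noise cutoff, metric series, comparison and
# secretio-type clustering.

#' Construct a signal time series
#'
#' A signal series is an ordered list of same-shaped non-negative signal
#' frames with strictly increasing time stamps (minutes from the start of the
#' recording).
#'
#' @param frames list of numeric matrices of identical dimensions.
#' @param times numeric vector of time stamps in minutes, one per frame
#'   (default `0, 1, 2, ...`).
#' @param sample_id label for the cell or sample (default `"sample"`).
#' @return an object of class `signal_series`.
#' @export
signal_series <- function(frames, times = NULL, sample_id = "sample") {
  if (!is.list(frames) || length(frames) < 1L) {
    stop("`frames` must be a non-empty list of matrices", call. = FALSE)
  }
  for (f in frames) validate_signal_matrix(f, "frames")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames must share the same dimensions", call. = FALSE)
  }
  if (is.null(times)) {
    times <- seq_along(frames) - 1
  }
  if (!is.numeric(times) || length(times) != length(frames) || anyNA(times)) {
    stop("`times` must be numeric with one entry per frame", call. = FALSE)
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  structure(
    list(frames = frames, times = as.numeric(times),
         sample_id = as.character(sample_id)[1]),
    class = "signal_series"
  )
}

validate_signal_series <- function(s) {
  if (!inherits(s, "signal_series")) {
    stop("`s` must be a `signal_series` (see `signal_series()`)", call. = FALSE)
  }
  s
}

#' @export
print.signal_series <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("Signal series '%s': %d frame(s) of %d x %d, t = %s min\n",
              x$sample_id, length(x$frames), d[1], d[2],
              paste(signif(x$times, 4), collapse = ", ")))
  invisible(x)
}

#' Read a signal series from a plain-text matrix file
#'
#' Parses a whitespace- or comma-delimited numeric matrix. A file with as many
#' rows as columns is read as a single frame; a stacked file with `x * n` rows
#' and `n` columns is split into `x` frames of `n` x `n` in file order.
#'
#' @param path path to the text file.
#' @param times optional time stamps in minutes (default `0, 1, ...`).
#' @param sample_id sample label (default the file name without extension).
#' @return a [signal_series()].
#' @export
read_series <- function(path, times = NULL, sample_id = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) {
    stop(sprintf("no data in %s", path), call. = FALSE)
  }
  sep_comma <- grepl(",", lines[keep[1]], fixed = TRUE)
  rows <- vector("list", length(keep))
  width <- NULL
  for (j in seq_along(keep)) {
    ln <- keep[j]
    fields <- if (sep_comma) {
      trimws(strsplit(lines[ln], ",", fixed = TRUE)[[1]])
    } else {
      strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) {
      stop(sprintf("parse error at line %d of %s: non-numeric cell '%s'",
                   ln, path, fields[which(is.na(vals))[1]]), call. = FALSE)
    }
    if (is.null(width)) {
      width <- length(vals)
    } else if (length(vals) != width) {
      stop(sprintf("parse error at line %d of %s: %d cells, expected %d",
                   ln, path, length(vals), width), call. = FALSE)
    }
    rows[[j]] <- vals
  }
  m_all <- do.call(rbind, rows)
  n_rows <- nrow(m_all)
  n_cols <- ncol(m_all)
  if (n_rows %% n_cols != 0L) {
    stop(sprintf(
      "%s has %d rows, not a multiple of its %d columns: cannot split into square frames",
      path, n_rows, n_cols), call. = FALSE)
  }
  x <- n_rows %/% n_cols
  frames <- lapply(seq_len(x), function(i) {
    m_all[((i - 1) * n_cols + 1):(i * n_cols), , drop = FALSE]
  })
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  signal_series(frames, times = times, sample_id = sample_id)
}

#' Write a signal series as a stacked plain-text matrix
#'
#' The inverse of [read_series()]: frames are stacked vertically and written
#' whitespace-delimited without headers.
#'
#' @param s a [signal_series()] or a single matrix.
#' @param path output path.
#' @export
write_series <- function(s, path) {
  m <- if (inherits(s, "signal_series")) {
    do.call(rbind, s$frames)
  } else {
    validate_signal_matrix(s)
    s
  }
  utils::write.table(m, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the tunable parameters of [analyze_series()]. Defaults mirror the
#' IL-6 case-study settings: a 1-minute averaging window, 5 x 5 block
#' aggregation of a centered 250 x 250 crop, per-pixel baselining against the
#' 0-minute frame, and delta-mode metrics.
#'
#' @param window_minutes temporal averaging window in minutes (> 0).
#' @param cutoff_mode `"absolute"` (threshold in intensity units) or
#'   `"fraction_of_peak"` (threshold as a fraction of the peak delta signal).
#' @param cutoff_value the threshold (default 0; the case study uses
#'   fraction 0.10).
#' @param block block side for sum pooling (default 5; 1 disables pooling).
#' @param crop_size side of the centered crop (default 250; `NULL` disables
#'   cropping). Must be divisible by `block`.
#' @param mode `"delta"` or `"cumulative"` metric evaluation.
#' @param baseline whether to baseline-correct against the first frame
#'   (default TRUE).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(window_minutes = 1,
                            cutoff_mode = c("absolute", "fraction_of_peak"),
                            cutoff_value = 0,
                            block = 5L,
                            crop_size = 250L,
                            mode = c("delta", "cumulative"),
                            baseline = TRUE) {
  cutoff_mode <- match.arg(cutoff_mode)
  mode <- match.arg(mode)
  if (!is.numeric(window_minutes) || window_minutes <= 0) {
    stop("`window_minutes` must be positive", call. = FALSE)
  }
  if (!is.numeric(cutoff_value) || cutoff_value < 0) {
    stop("`cutoff_value` must be non-negative", call. = FALSE)
  }
  if (cutoff_mode == "fraction_of_peak" && cutoff_value >= 1) {
    stop("a fractional cutoff must lie in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(block) || block < 1 || block != floor(block)) {
    stop("`block` must be a positive integer", call. = FALSE)
  }
  if (!is.null(crop_size)) {
    if (!is.numeric(crop_size) || crop_size < 1 || crop_size != floor(crop_size)) {
      stop("`crop_size` must be a positive integer or NULL", call. = FALSE)
    }
    if (crop_size %% block != 0) {
      stop("`block` must divide `crop_size`", call. = FALSE)
    }
  }
  structure(
    list(window_minutes = window_minutes, cutoff_mode = cutoff_mode,
         cutoff_value = cutoff_value, block = as.integer(block),
         crop_size = if (is.null(crop_size)) NULL else as.integer(crop_size),
         mode = mode, baseline = isTRUE(baseline)),
    class = "pipeline_config"
  )
}

#' Centered crop and block-sum aggregation of a frame
#'
#' Crops a `crop_size` x `crop_size` region from the frame center (the
#' captured cell is centered by construction) and pools it into
#' non-overlapping `block` x `block` sums, e.g. 250 x 250 with block 5 gives
#' a 50 x 50 grid. Sum pooling conserves the signal mass within the crop;
#' the downstream metrics are scale-invariant, so sums and means are
#' equivalent up to that invariance.
#'
#' @param frame numeric matrix.
#' @param crop_size side of the centered crop (`NULL` keeps the full frame;
#'   must not exceed the frame dimensions).
#' @param block pooling block side (must divide the cropped size).
#' @return aggregated matrix of side `crop_size / block`.
#' @export
crop_and_aggregate <- function(frame, crop_size = 250L, block = 5L) {
  validate_signal_matrix(frame, "frame")
  if (!is.null(crop_size)) {
    if (crop_size > nrow(frame) || crop_size > ncol(frame)) {
      stop(sprintf("crop size %d exceeds frame dimensions %d x %d",
                   crop_size, nrow(frame), ncol(frame)), call. = FALSE)
    }
    r0 <- floor((nrow(frame) - crop_size) / 2)
    c0 <- floor((ncol(frame) - crop_size) / 2)
    frame <- frame[r0 + seq_len(crop_size), c0 + seq_len(crop_size), drop = FALSE]
  }
  if (block == 1L) {
    return(frame)
  }
  if (nrow(frame) %% block != 0 || ncol(frame) %% block != 0) {
    stop("`block` must divide the cropped frame size", call. = FALSE)
  }
  row_groups <- rep(seq_len(nrow(frame) %/% block), each = block)
  col_groups <- rep(seq_len(ncol(frame) %/% block), each = block)
  pooled <- rowsum(frame, row_groups)
  t(rowsum(t(pooled), col_groups))
}

#' Temporal window averaging of a signal series
#'
#' For each requested time point `t`, averages all frames whose time stamp
#' lies in the half-open window `(t - window, t]` -- the window precedes the
#' time point and includes it. With frames every 10 seconds and a 1-minute
#' window, six frames enter each average.
#'
#' @param s a [signal_series()].
#' @param at_minutes time points (minutes) at which to produce averaged
#'   frames; strictly increasing.
#' @param window window length in minutes (default 1).
#' @return a [signal_series()] with one frame per requested time point.
#' @export
window_average <- function(s, at_minutes, window = 1) {
  s <- validate_signal_series(s)
  if (!is.numeric(at_minutes) || length(at_minutes) < 1L || anyNA(at_minutes)) {
    stop("`at_minutes` must be a numeric vector of time points", call. = FALSE)
  }
  if (!is.numeric(window) || window <= 0) {
    stop("`window` must be positive", call. = FALSE)
  }
  frames <- lapply(at_minutes, function(t) {
    idx <- which(s$times > t - window & s$times <= t)
    if (length(idx) == 0L) {
      stop(sprintf("no frames in the window (%s, %s] minutes",
                   format(t - window), format(t)), call. = FALSE)
    }
    Reduce(`+`, s$frames[idx]) / length(idx)
  })
  signal_series(frames, times = at_minutes, sample_id = s$sample_id)
}

#' Per-pixel baseline correction against the 0-minute frame
#'
#' Each pixel's baseline is the smaller of its 0-minute value and its current
#' value; the baseline is subtracted, so outputs are non-negative everywhere
#' and pixels that dropped below their starting level are neutralised to 0.
#' The first frame maps to an all-zero frame.
#'
#' @param s a [signal_series()] whose first frame is the 0-minute frame.
#' @return baseline-corrected [signal_series()].
#' @export
baseline_correct <- function(s) {
  s <- validate_signal_series(s)
  b0 <- s$frames[[1]]
  frames <- lapply(s$frames, function(f) f - pmin(f, b0))
  signal_series(frames, times = s$times, sample_id = s$sample_id)
}

#' Zero out sub-threshold signal
#'
#' Sets every entry at or below the resolved cutoff to 0. In
#' `"fraction_of_peak"` mode the threshold is `cutoff_value * max(m)` (e.g. a
#' peak delta of 4440 with fraction 0.10 gives a cutoff of 444).
#'
#' @param m numeric matrix.
#' @param cutoff_value threshold (absolute intensity, or fraction in \[0, 1)).
#' @param cutoff_mode `"absolute"` or `"fraction_of_peak"`.
#' @return thresholded matrix.
#' @export
apply_cutoff <- function(m, cutoff_value,
                         cutoff_mode = c("absolute", "fraction_of_peak")) {
  validate_signal_matrix(m)
  cutoff_mode <- match.arg(cutoff_mode)
  if (!is.numeric(cutoff_value) || length(cutoff_value) != 1L ||
      is.na(cutoff_value) || cutoff_value < 0) {
    stop("`cutoff_value` must be a single non-negative number", call. = FALSE)
  }
  thr <- if (cutoff_mode == "fraction_of_peak") {
    if (cutoff_value >= 1) {
      stop("a fractional cutoff must lie in [0, 1)", call. = FALSE)
    }
    cutoff_value * max(m)
  } else {
    cutoff_value
  }
  m[m <= thr] <- 0
  m
}

#' Run the full secretion-signal pipeline on a series
#'
#' Applies the fixed stage order crop/aggregate, window-average, baseline,
#' cutoff, metrics. Stages are individually skippable through the
#' configuration (`crop_size = NULL`, `block = 1`, `at_minutes = NULL`,
#' `baseline = FALSE`); with everything disabled and cutoff 0 the result
#' equals calling [metric_series()] directly.
#'
#' In `"fraction_of_peak"` mode the absolute threshold is resolved as the
#' configured fraction of the peak delta signal across the whole series, then
#' applied per frame inside [metric_series()].
#'
#' @param s a [signal_series()].
#' @param config a [pipeline_config()].
#' @param at_minutes optional time points for window averaging (`NULL` skips
#'   the averaging stage).
#' @return a `metric_series` data frame (see [metric_series()]).
#' @export
analyze_series <- function(s, config = pipeline_config(), at_minutes = NULL) {
  s <- validate_signal_series(s)
  if (!inherits(config, "pipeline_config")) {
    stop("`config` must be a `pipeline_config()`", call. = FALSE)
  }
  if (!is.null(config$crop_size) || config$block > 1L) {
    frames <- lapply(s$frames, crop_and_aggregate,
                     crop_size = config$crop_size, block = config$block)
    s <- signal_series(frames, times = s$times, sample_id = s$sample_id)
  }
  if (!is.null(at_minutes)) {
    s <- window_average(s, at_minutes, window = config$window_minutes)
  }
  if (config$baseline) {
    s <- baseline_correct(s)
  }
  cutoff <- config$cutoff_value
  if (config$cutoff_mode == "fraction_of_peak") {
    deltas <- if (config$mode == "delta") {
      prev <- c(list(array(0, dim(s$frames[[1]]))), s$frames[-length(s$frames)])
      Map(function(cur, pre) pmax(cur - pre, 0), s$frames, prev)
    } else {
      s$frames
    }
    peak <- max(vapply(deltas, max, numeric(1)))
    cutoff <- config$cutoff_value * peak
  }
  metric_series(s, mode = config$mode, cutoff = cutoff)
}

#' Compare two metric series by Pearson correlation
#'
#' Correlates the chosen metric across aligned time points of two samples and
#' reports the two-sided p-value from the t distribution with `n - 2` degrees
#' of freedom (via [stats::cor.test()]).
#'
#' @param a,b `metric_series` data frames (see [metric_series()]) with aligned
#'   time points (length >= 3).
#' @param metric `"sii"` or `"sci"`.
#' @return list of class `series_comparison` with `metric`, `r`, `p`, `n` and
#'   `sample_pair`.
#' @export
compare_series <- function(a, b, metric = c("sii", "sci")) {
  metric <- match.arg(metric)
  for (ms in list(a, b)) {
    if (!is.data.frame(ms) || !all(c("time_min", "sii", "sci") %in% names(ms))) {
      stop("`a` and `b` must be metric-series data frames", call. = FALSE)
    }
  }
  if (nrow(a) != nrow(b)) {
    stop("the two series must have the same number of time points", call. = FALSE)
  }
  if (nrow(a) < 3L) {
    stop("at least 3 aligned time points are required", call. = FALSE)
  }
  if (!isTRUE(all.equal(a$time_min, b$time_min))) {
    stop("the two series must share aligned time points", call. = FALSE)
  }
  va <- a[[metric]]
  vb <- b[[metric]]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("correlation undefined: a series has zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(va, vb, method = "pearson", alternative = "two.sided")
  structure(
    list(metric = metric, r = unname(ct$estimate), p = ct$p.value,
         n = nrow(a),
         sample_pair = c(a$sample_id[1], b$sample_id[1])),
    class = "series_comparison"
  )
}

#' @export
print.series_comparison <- function(x, ...) {
  cat(sprintf("Pearson correlation of %s between '%s' and '%s' (n = %d): r = %.3f, p = %.4g\n",
              toupper(x$metric), x$sample_pair[1], x$sample_pair[2], x$n, x$r, x$p))
  invisible(x)
}

#' Secretio-type clustering of metric series
#'
#' Agglomerative hierarchical clustering of samples by the Euclidean distance
#' between their temporal metric vectors. The linkage defaults to average
#' (UPGMA) and is configurable; the distance is fixed to Euclidean.
#'
#' @param series list of `metric_series` data frames with aligned lengths.
#' @param metric `"sii"` or `"sci"`.
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @return an [stats::hclust] merge tree labelled by sample ids.
#' @seealso [cluster_newick()]
#' @export
cluster_series <- function(series, metric = c("sii", "sci"),
                           linkage = "average") {
  metric <- match.arg(metric)
  if (!is.list(series) || length(series) < 2L) {
    stop("at least two metric series are required", call. = FALSE)
  }
  lens <- vapply(series, nrow, integer(1))
  if (any(lens != lens[1])) {
    stop("all metric series must have the same number of time points", call. = FALSE)
  }
  mat <- do.call(rbind, lapply(series, function(ms) ms[[metric]]))
  rownames(mat) <- vapply(series, function(ms) ms$sample_id[1], character(1))
  stats::hclust(stats::dist(mat, method = "euclidean"), method = linkage)
}

#' Export a cluster tree in newick format
#'
#' @param hc an [stats::hclust] tree, e.g. from [cluster_series()].
#' @param path optional file path; when `NULL` the newick string is returned.
#' @return the newick string, invisibly when written to a file.
#' @export
cluster_newick <- function(hc, path = NULL) {
  if (!inherits(hc, "hclust")) {
    stop("`hc` must be an hclust tree", call. = FALSE)
  }
  phy <- ape::as.phylo(hc)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}
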