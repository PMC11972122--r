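# 2D composites: axis projections, SII, SCI, and per-frame metric series.

validate_signal_matrix <- function(m, arg = "m") {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (nrow(m) < 1L || ncol(m) < 1L) {
    stop(sprintf("`%s` must have at least one row and one column", arg), call. = FALSE)
  }
  # a single range() pass (no logical temporaries) keeps validation cheap on
  # large maps: NA/NaN propagate into the range, Inf and negatives show there
  rng <- range(m)
  if (anyNA(rng) || !all(is.finite(rng))) {
    stop(sprintf("`%s` contains missing or non-finite values", arg), call. = FALSE)
  }
  if (rng[1] < 0) {
    stop(sprintf("`%s` contains negative intensities", arg), call. = FALSE)
  }
  invisible(m)
}

# marginal profiles without re-validation (internal hot path)
projections_of <- function(m) {
  list(x = unname(colSums(m)), y = unname(rowSums(m)))
}

#' Project a 2D signal map onto one axis
#'
#' The x-projection is the profile of column sums (a signal intensity per x
#' position); the y-projection is the profile of row sums. Total signal mass
#' is conserved: the projection sums to the grid total.
#'
#' @param m numeric matrix of non-negative intensities.
#' @param axis `"x"` (columns) or `"y"` (rows).
#' @return numeric vector of length `ncol(m)` (x) or `nrow(m)` (y).
#' @examples
#' project(matrix(1, 4, 4), "x") # 4 4 4 4
#' @export
project <- function(m, axis = c("x", "y")) {
  validate_signal_matrix(m)
  axis <- match.arg(axis)
  if (axis == "x") unname(colSums(m)) else unname(rowSums(m))
}

#' Signal inequality index (SII) of a 2D map
#'
#' Euclidean norm of the degrees of inequality of the two axis projections:
#' \deqn{SII = \sqrt{DI_x^2 + DI_y^2}.}
#' SII measures the dissymmetry of the map: it is 0 for centrally symmetric
#' maps and grows as signal mass moves off-center, reaching
#' \eqn{\sqrt{2}\,(n-1)/n} for all mass in one corner of an n-by-n grid.
#' Because each DI depends only on the intensity centroid of its projection,
#' SII is exactly invariant under rotations of the pattern about the grid
#' center (up to resampling error) and under transposition.
#'
#' @inheritParams project
#' @return a single non-negative value (at most `sqrt(2)`).
#' @seealso [sci()], [map_metrics()]
#' @export
sii <- function(m) {
  validate_signal_matrix(m)
  pr <- projections_of(m)
  sqrt(degree_of_inequality(pr$x)^2 + degree_of_inequality(pr$y)^2)
}

#' Signal coverage index (SCI) of a 2D map
#'
#' Euclidean norm of the center-weighted signal-to-noise ratios of the two
#' axis projections:
#' \deqn{SCI = \sqrt{CWSNR_x^2 + CWSNR_y^2}.}
#' SCI measures how much above-uniform ("asymmetric") signal sits near the map
#' center: it is 0 for uniform or all-zero maps and high when concentrated
#' signal hugs the central point.
#'
#' @inheritParams project
#' @return a single non-negative value.
#' @seealso [sii()], [cwsnr()]
#' @export
sci <- function(m) {
  validate_signal_matrix(m)
  pr <- projections_of(m)
  sqrt(cwsnr(pr$x)$cwsnr^2 + cwsnr(pr$y)$cwsnr^2)
}

#' Full metric decomposition of a 2D map
#'
#' Computes both composites together with the per-axis decompositions, so that
#' intermediate quantities (DI, SNR, CWSNR per axis) can be inspected.
#'
#' @inheritParams project
#' @return an object of class `map_metrics`: list with `sii`, `sci`,
#'   `axis_x` and `axis_y` (each an [cwsnr()] decomposition).
#' @export
map_metrics <- function(m) {
  validate_signal_matrix(m)
  pr <- projections_of(m)
  ax <- cwsnr(pr$x)
  ay <- cwsnr(pr$y)
  structure(
    list(
      sii = sqrt(ax$di^2 + ay$di^2),
      sci = sqrt(ax$cwsnr^2 + ay$cwsnr^2),
      axis_x = ax,
      axis_y = ay
    ),
    class = "map_metrics"
  )
}

#' @export
print.map_metrics <- function(x, ...) {
  cat(sprintf(
    "SII = %.4f (DIx = %.4f, DIy = %.4f); SCI = %.4f (CWSNRx = %.4f, CWSNRy = %.4f)\n",
    x$sii, x$axis_x$di, x$axis_y$di, x$sci, x$axis_x$cwsnr, x$axis_y$cwsnr
  ))
  invisible(x)
}

#' SII and SCI over a time series of maps
#'
#' Evaluates the two composites at every time point of a [signal_series()].
#' In `"delta"` mode each frame is first differenced against the previous one
#' (the first frame against zero), negative increments are clipped to 0
#' (secretion increments are non-negative by construction), and entries at or
#' below `cutoff` are zeroed as noise before the metrics are computed. In
#' `"cumulative"` mode the frames are evaluated as-is.
#'
#' @param s a [signal_series()].
#' @param mode `"delta"` or `"cumulative"`.
#' @param cutoff non-negative noise threshold applied to the evaluated frame.
#' @return a data frame of class `metric_series` with columns `sample_id`,
#'   `time_min`, `sii` and `sci`, one row per time point.
#' @export
metric_series <- function(s, mode = c("delta", "cumulative"), cutoff = 0) {
  s <- validate_signal_series(s)
  mode <- match.arg(mode)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 0) {
    stop("`cutoff` must be a single non-negative value", call. = FALSE)
  }
  frames <- s$frames
  if (mode == "delta") {
    prev <- c(list(array(0, dim(frames[[1]]))), frames[-length(frames)])
    frames <- Map(function(cur, pre) pmax(cur - pre, 0), frames, prev)
  }
  vals <- vapply(frames, function(f) {
    f[f <= cutoff] <- 0
    mm <- map_metrics(f)
    c(mm$sii, mm$sci)
  }, numeric(2))
  structure(
    data.frame(
      sample_id = s$sample_id,
      time_min = s$times,
      sii = vals[1, ],
      sci = vals[2, ],
      stringsAsFactors = FALSE
    ),
    class = c("metric_series", "data.frame")
  )
}
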