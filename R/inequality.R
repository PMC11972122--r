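#' @keywords internal
"_PACKAGE"

# ---- input validation -------------------------------------------------------

validate_signal_vector <- function(x, arg = "x") {
  if (!is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric vector", arg), call. = FALSE)
  }
  if (length(x) < 1L) {
    stop(sprintf("`%s` must have length >= 1", arg), call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("`%s` contains missing or non-finite values", arg), call. = FALSE)
  }
  if (any(x < 0)) {
    stop(sprintf("`%s` contains negative intensities", arg), call. = FALSE)
  }
  invisible(as.numeric(x))
}

#' Degree of inequality of a 1D signal profile
#'
#' The degree of inequality (DI) is an unsorted, position-aware Lorenz-curve
#' statistic. The cumulative signal share at pixel `k` is compared with the
#' 45-degree perfect-equality diagonal `k/n`, and the signed deviations are
#' averaged:
#' \deqn{DI = \frac{1}{n}\sum_{k=1}^{n} 2\left(\frac{\sum_{i \le k} x_i}
#'   {\sum_{i} x_i} - \frac{k}{n}\right).}
#' Unlike the classic Gini coefficient the profile is *not* sorted, so DI keeps
#' the sign information of where the signal mass sits: positive when mass is
#' concentrated at low pixel indices, negative at high indices, 0 for any
#' symmetric or uniform profile.
#'
#' DI is invariant under positive rescaling of the intensities and under pixel
#' duplication (resolution doubling), and is negated when the profile is
#' reversed. It equals \eqn{(n+1-2\bar{k})/n} where \eqn{\bar{k}} is the
#' intensity-weighted mean pixel index.
#'
#' @param x numeric vector of non-negative intensities (a signal profile,
#'   typically an axis projection of a 2D map).
#' @return a single value in \[-1, 1\]. An all-zero profile returns 0.
#' @examples
#' degree_of_inequality(c(0, 0, 0, 0, 0, 0, 0, 1, 0, 0)) # -0.5
#' degree_of_inequality(c(1, 1, 1, 1, 1))                # 0
#' @seealso [di_derivative()], [cwsnr()], [sii()]
#' @export
degree_of_inequality <- function(x) {
  x <- validate_signal_vector(x)
  n <- length(x)
  total <- sum(x)
  if (total == 0) {
    return(0)
  }
  lorenz <- cumsum(x) / total
  2 * sum(lorenz - seq_len(n) / n) / n
}

#' Pixelwise derivative of the degree of inequality
#'
#' Discrete derivative of the prefix DI curve, with the convention
#' \eqn{DI(0) = 0}. Because pixels are unit-spaced the difference collapses to
#' \deqn{\partial DI(k) = \frac{x_k}{\sum_i x_i} - \frac{1}{n},}
#' the excess signal share of pixel `k` over the uniform share. Entries sum to
#' zero whenever the profile carries any signal; an all-zero profile yields an
#' all-zero derivative.
#'
#' @inheritParams degree_of_inequality
#' @return numeric vector of length `length(x)`.
#' @examples
#' di_derivative(c(0, 0, 3, 2, 1))
#' @export
di_derivative <- function(x) {
  x <- validate_signal_vector(x)
  n <- length(x)
  total <- sum(x)
  if (total == 0) {
    return(numeric(n))
  }
  x / total - 1 / n
}

#' Signal-to-noise ratio of a DI derivative vector
#'
#' Pixels with a strictly positive DI derivative carry more than the uniform
#' signal share and are counted as signal units; the rest are counted as noise
#' units. The ratio guards the center-weighted sum in [cwsnr()] against
#' universally noisy profiles.
#'
#' When no noise units exist (never the case for a profile with at least one
#' zero-derivative pixel) the ratio is capped at `c_signal` with a warning
#' rather than returning `Inf`.
#'
#' @param d_di numeric vector, a DI derivative as returned by [di_derivative()].
#' @return list with elements `c_signal`, `c_noise` (non-negative integer
#'   counts, `c_signal + c_noise = length(d_di)`) and `snr`.
#' @examples
#' signal_noise_ratio(di_derivative(c(0, 0, 3, 2, 1)))$snr # 2/3
#' @export
signal_noise_ratio <- function(d_di) {
  if (!is.numeric(d_di) || length(d_di) < 1L || anyNA(d_di)) {
    stop("`d_di` must be a numeric vector without missing values", call. = FALSE)
  }
  c_signal <- sum(d_di > 0)
  c_noise <- length(d_di) - c_signal
  if (c_noise == 0L) {
    warning("no noise units: SNR capped at the signal-unit count", call. = FALSE)
    snr <- c_signal
  } else {
    snr <- c_signal / c_noise
  }
  list(c_signal = c_signal, c_noise = c_noise, snr = snr)
}

#' Semicircular center weights for an axis
#'
#' Weight profile used by [cwsnr()] to emphasise signal near the axis center:
#' the center pixel gets weight 1, both endpoints get 0, and intermediate
#' pixels follow a semicircle (Pythagorean construction)
#' \deqn{W(i) = \sqrt{1 - (o_i / h)^2},}
#' with \eqn{o_i = |i - (n+1)/2|} the offset from the axis center and
#' \eqn{h = (n-1)/2} the half-span. For even `n` the two central pixels sit at
#' offset 1/2 and share the largest weight; the profile stays symmetric with
#' zero endpoints.
#'
#' @param n axis length in pixels (>= 1).
#' @return numeric vector of length `n` with values in \[0, 1\].
#' @examples
#' center_weights(5) # 0, 0.866..., 1, 0.866..., 0
#' @export
center_weights <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != floor(n)) {
    stop("`n` must be a single integer >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  if (n == 1L) {
    return(1)
  }
  offset <- abs(seq_len(n) - (n + 1) / 2)
  half_span <- (n - 1) / 2
  sqrt(pmax(0, 1 - (offset / half_span)^2))
}

#' Center-weighted signal-to-noise ratio of a 1D profile
#'
#' Composes the full per-axis decomposition behind the signal coverage index:
#' the DI derivative is rectified to its positive part (the signal vector `v`),
#' weighted by the semicircular center weights `w`, summed, and scaled by the
#' signal-to-noise ratio:
#' \deqn{CWSNR = SNR \cdot \sum_i V(i) W(i).}
#' CWSNR is always non-negative; it is 0 for uniform and all-zero profiles and
#' grows when above-uniform signal sits near the axis center.
#'
#' @inheritParams degree_of_inequality
#' @return an object of class `axis_decomposition`: a list with fields `di`,
#'   `d_di`, `c_signal`, `c_noise`, `snr`, `v`, `w` and `cwsnr`.
#' @examples
#' cwsnr(c(0, 0, 3, 2, 1))$cwsnr # about 0.277
#' @export
cwsnr <- function(x) {
  x <- validate_signal_vector(x)
  d <- di_derivative(x)
  ratio <- signal_noise_ratio(d)
  v <- pmax(d, 0)
  w <- center_weights(length(x))
  structure(
    list(
      di = degree_of_inequality(x),
      d_di = d,
      c_signal = ratio$c_signal,
      c_noise = ratio$c_noise,
      snr = ratio$snr,
      v = v,
      w = w,
      cwsnr = ratio$snr * sum(v * w)
    ),
    class = "axis_decomposition"
  )
}

#' @export
print.axis_decomposition <- function(x, ...) {
  cat(sprintf(
    "Axis decomposition (n = %d): DI = %.4f, SNR = %d/%d = %.4f, CWSNR = %.4f\n",
    length(x$d_di), x$di, x$c_signal, x$c_noise, x$snr, x$cwsnr
  ))
  invisible(x)
}

#' Comparator inequality and concentration indices
#'
#' Five standard indices used as baselines for the position-aware DI/CWSNR
#' pair. All treat the profile as an unordered distribution and therefore
#' cannot see signal position:
#'
#' * `shannon`: entropy \eqn{H = -\sum_i p_i \log_2 p_i} of the signal shares
#'   (bits, range \[0, log2(n)\]);
#' * `theil`: \eqn{T = \frac{1}{n}\sum_i \frac{x_i+\varepsilon}{\mu}
#'   \log\frac{x_i+\varepsilon}{\mu}} with \eqn{\mu} the mean of the shifted
#'   values \eqn{x_i+\varepsilon}, natural log (range \[0, Inf));
#' * `hhi`: Herfindahl-Hirschman concentration \eqn{\sum_i p_i^2};
#' * `simpson`: diversity \eqn{1 - \sum_i p_i^2};
#' * `atkinson`: \eqn{1 - \left[\frac{1}{n}\sum_i (x_i/\mu)^{1-\epsilon}
#'   \right]^{1/(1-\epsilon)}} with inequality-aversion \eqn{\epsilon}.
#'
#' The small shift `theil_epsilon` keeps the Theil log finite on zero pixels;
#' using the shifted values inside the mean as well makes perfect equality
#' score exactly 0.
#'
#' @inheritParams degree_of_inequality
#' @param method one of `"shannon"`, `"theil"`, `"hhi"`, `"simpson"`,
#'   `"atkinson"`.
#' @param theil_epsilon small positive shift for the Theil index (default 0.01).
#' @param atkinson_aversion inequality-aversion parameter in (0, 1)
#'   (default 0.5).
#' @return a single numeric value. An all-zero profile returns 0 with a
#'   degenerate-input warning.
#' @examples
#' alternative_metric(c(1, 1, 1, 1), "shannon") # 2 bits
#' @export
alternative_metric <- function(x,
                               method = c("shannon", "theil", "hhi", "simpson", "atkinson"),
                               theil_epsilon = 0.01,
                               atkinson_aversion = 0.5) {
  x <- validate_signal_vector(x)
  method <- match.arg(method)
  if (method == "theil") {
    if (!is.numeric(theil_epsilon) || theil_epsilon <= 0) {
      stop("`theil_epsilon` must be a small positive value", call. = FALSE)
    }
    shifted <- x + theil_epsilon
    ratio <- shifted / mean(shifted)
    return(mean(ratio * log(ratio)))
  }
  total <- sum(x)
  if (total == 0) {
    warning("all-zero profile: returning 0", call. = FALSE)
    return(0)
  }
  if (method == "atkinson") {
    if (!is.numeric(atkinson_aversion) || atkinson_aversion <= 0 ||
        atkinson_aversion >= 1) {
      stop("`atkinson_aversion` must lie in (0, 1)", call. = FALSE)
    }
    e <- atkinson_aversion
    return(1 - mean((x / mean(x))^(1 - e))^(1 / (1 - e)))
  }
  p <- x / total
  switch(method,
    shannon = {
      p <- p[p > 0] # 0 * log(0) = 0 convention
      -sum(p * log2(p))
    },
    hhi = sum(p^2),
    simpson = 1 - sum(p^2)
  )
}
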