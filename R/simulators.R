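# Reference signal simulators: 1D scenario profiles, the four 2D diffusion
# models, pattern rotation, and reproducible random matrices for scaling runs.

#' Simulate a one-dimensional signal scenario
#'
#' Generates the 5-pixel reference profiles of the four 1D models used to
#' characterise DI and CWSNR:
#'
#' * `shifting` (a): a unit signal stepping rightward from the center
#'   (stages 1-3: center, center+1, center+2);
#' * `shaping` (b): signal densities 3, 2 and 1 arranged over the right three
#'   pixels (stage 1 `2,3,1`; stage 2 `3,2,1`; stage 3 `1,2,3` -- ordered so
#'   CWSNR ranks stage 2 > stage 1 > stage 3);
#' * `spreading` (c): signal widening from the center pixel (stage 1) to the
#'   central three pixels (stage 2) to the full uniform profile (stage 3);
#' * `propagating` (d): signal moving symmetrically outward from the center
#'   (stage 1) through the two mid pixels (stage 2) to both endpoints
#'   (stage 3).
#'
#' @param model one of `"shifting"`, `"shaping"`, `"spreading"`,
#'   `"propagating"`.
#' @param stage stage index within the model (1-3).
#' @return numeric vector of length 5.
#' @examples
#' simulate_1d("shaping", 2) # 0 0 3 2 1
#' @export
simulate_1d <- function(model = c("shifting", "shaping", "spreading", "propagating"),
                        stage = 1L) {
  model <- match.arg(model)
  if (!is.numeric(stage) || length(stage) != 1L || is.na(stage) ||
      !stage %in% 1:3) {
    stop(sprintf("unknown stage %s for model '%s'", format(stage), model),
         call. = FALSE)
  }
  stage <- as.integer(stage)
  profiles <- switch(model,
    shifting = list(c(0, 0, 1, 0, 0), c(0, 0, 0, 1, 0), c(0, 0, 0, 0, 1)),
    shaping = list(c(0, 0, 2, 3, 1), c(0, 0, 3, 2, 1), c(0, 0, 1, 2, 3)),
    spreading = list(c(0, 0, 1, 0, 0), c(0, 1, 1, 1, 0), c(1, 1, 1, 1, 1)),
    propagating = list(c(0, 0, 1, 0, 0), c(0, 1, 0, 1, 0), c(1, 0, 0, 0, 1))
  )
  profiles[[stage]]
}

#' The ten distinct one-dimensional scenario profiles
#'
#' The four 1D models comprise twelve stages, but the shifting, spreading and
#' propagating models share the same centered starting profile, leaving ten
#' distinct scenarios. Names follow the model letter and stage (a1-a3, b1-b3,
#' c2-c3, d2-d3).
#'
#' @return named list of ten numeric vectors of length 5.
#' @seealso [metric_separation()]
#' @export
scenario_profiles_1d <- function() {
  list(
    a1 = simulate_1d("shifting", 1), a2 = simulate_1d("shifting", 2),
    a3 = simulate_1d("shifting", 3),
    b1 = simulate_1d("shaping", 1), b2 = simulate_1d("shaping", 2),
    b3 = simulate_1d("shaping", 3),
    c2 = simulate_1d("spreading", 2), c3 = simulate_1d("spreading", 3),
    d2 = simulate_1d("propagating", 2), d3 = simulate_1d("propagating", 3)
  )
}

#' How well a metric pair separates the 1D scenarios
#'
#' Computes (DI, CWSNR) for each scenario profile and reports the separation
#' accuracy: the number of distinct metric pairs divided by the number of
#' scenarios. A scenario whose pair coincides with another's collapses onto
#' it and reduces the count of distinct values by one.
#'
#' @param profiles named list of signal profiles
#'   (default [scenario_profiles_1d()]).
#' @param tol equality tolerance when comparing metric pairs.
#' @return list with `table` (data frame of scenario, di, cwsnr), `n_distinct`
#'   and `accuracy`.
#' @export
metric_separation <- function(profiles = scenario_profiles_1d(), tol = 1e-9) {
  if (!is.list(profiles) || length(profiles) < 1L) {
    stop("`profiles` must be a non-empty list of signal profiles", call. = FALSE)
  }
  tab <- data.frame(
    scenario = if (is.null(names(profiles))) {
      as.character(seq_along(profiles))
    } else {
      names(profiles)
    },
    di = vapply(profiles, degree_of_inequality, numeric(1)),
    cwsnr = vapply(profiles, function(p) cwsnr(p)$cwsnr, numeric(1)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  key <- paste(round(tab$di / tol), round(tab$cwsnr / tol))
  n_distinct <- length(unique(key))
  list(table = tab, n_distinct = n_distinct,
       accuracy = n_distinct / nrow(tab))
}

# 1-based center index of an axis of length n (0-based floor(n/2), so a
# 51-pixel axis is centered at 0-based 25).
grid_center <- function(n) floor(n / 2) + 1L

#' Simulate a frame of a two-dimensional diffusion model
#'
#' Generates the signal map of one of the four 2D models at time point `t` on
#' a square grid (default 51 with center at 0-based (25, 25)):
#'
#' * `circular_propagation` (a): at `t` = 1 a point signal of height
#'   `amplitude` at the center; afterwards an annulus of cells at Euclidean
#'   distance between `step*(t-1)` and `outer_step*(t-1)` from the center,
#'   each carrying `amplitude / (outer_step*(t-1))` (signal decays with the
#'   outer distance);
#' * `circular_with_direction` (b): the same annulus additionally shifted
#'   right by `step*(t-1)` grid units;
#' * `circular_sector` (c): the annulus masked to the right-pointing sector
#'   `dx >= dy` and `dx >= -(dy+1)`;
#' * `translation` (d): the signal translated right along the center row,
#'   occupying the cells at distance `step*(t-1)` through `outer_step*(t-1)`
#'   (the same inner/outer span as the annulus models) with the same decayed
#'   amplitude.
#'
#' Cells falling off the grid are dropped.
#'
#' @param model one of `"circular_propagation"`, `"circular_with_direction"`,
#'   `"circular_sector"`, `"translation"`.
#' @param t time point, 1 to `timepoints`.
#' @param grid_size side length of the square grid (default 51; an odd size
#'   admits an exact center pixel).
#' @param amplitude initial signal height (default 5000).
#' @param step inner-edge displacement per time step in grid units (default 4).
#' @param outer_step outer-edge displacement per time step (default 5).
#' @param timepoints number of time points in the model (default 4).
#' @param rotation_deg optional rotation of the pattern about the grid center,
#'   in degrees (default 0); see [rotate_map()].
#' @return a `grid_size` x `grid_size` numeric matrix.
#' @examples
#' f <- simulate_2d("translation", t = 2)
#' sii(f)
#' @export
simulate_2d <- function(model = c("circular_propagation", "circular_with_direction",
                                  "circular_sector", "translation"),
                        t,
                        grid_size = 51L,
                        amplitude = 5000,
                        step = 4L,
                        outer_step = 5L,
                        timepoints = 4L,
                        rotation_deg = 0) {
  model <- match.arg(model)
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t != floor(t) ||
      t < 1 || t > timepoints) {
    stop(sprintf("`t` must be an integer in 1..%d", timepoints), call. = FALSE)
  }
  if (grid_size < 2L) stop("`grid_size` must be >= 2", call. = FALSE)
  if (amplitude <= 0) stop("`amplitude` must be positive", call. = FALSE)
  t <- as.integer(t)
  n <- as.integer(grid_size)
  cen <- grid_center(n)
  m <- matrix(0, n, n)

  if (t == 1L) {
    m[cen, cen] <- amplitude
  } else {
    inner <- step * (t - 1)
    outer <- outer_step * (t - 1)
    value <- amplitude / outer
    if (model == "translation") {
      cols <- cen + inner:outer
      cols <- cols[cols >= 1 & cols <= n]
      m[cen, cols] <- value
    } else {
      dx <- matrix(rep(seq_len(n) - cen, each = n), n, n) # column offsets
      dy <- matrix(rep(seq_len(n) - cen, times = n), n, n) # row offsets
      d <- sqrt(dx^2 + dy^2)
      mask <- d >= inner & d <= outer
      if (model == "circular_sector") {
        mask <- mask & (dx >= dy) & (dx >= -(dy + 1))
      }
      m[mask] <- value
      if (model == "circular_with_direction") {
        shift <- inner
        out <- matrix(0, n, n)
        keep <- seq_len(n - shift)
        out[, keep + shift] <- m[, keep]
        m <- out
      }
    }
  }
  if (rotation_deg != 0) {
    m <- rotate_map(m, rotation_deg)
  }
  m
}

#' Rotate a signal map about its center
#'
#' Rotates the pattern counterclockwise about the grid center. Multiples of
#' 90 degrees are exact index permutations. Other angles use forward bilinear
#' mass splatting: each source cell's intensity is distributed over the four
#' cells surrounding its rotated position. This conserves total mass exactly
#' (apart from cells rotated off the grid) and preserves the intensity
#' centroid, so centroid-based statistics such as [sii()] are invariant under
#' rotation up to machine precision.
#'
#' @param m square numeric matrix of non-negative intensities.
#' @param angle_deg rotation angle in degrees (counterclockwise).
#' @return rotated matrix of the same dimensions.
#' @export
rotate_map <- function(m, angle_deg) {
  validate_signal_matrix(m)
  if (nrow(m) != ncol(m)) {
    stop("`m` must be a square grid", call. = FALSE)
  }
  if (!is.numeric(angle_deg) || length(angle_deg) != 1L || !is.finite(angle_deg)) {
    stop("`angle_deg` must be a single finite number", call. = FALSE)
  }
  n <- nrow(m)
  cen <- grid_center(n)
  angle <- angle_deg %% 360
  if (angle == 0) {
    return(m)
  }
  # exact trigonometry at quarter turns avoids needless resampling error
  if (angle %% 90 == 0) {
    k <- as.integer(angle / 90) %% 4L
    cs <- c(1, 0, -1, 0)[k + 1L]
    sn <- c(0, 1, 0, -1)[k + 1L]
  } else {
    theta <- angle * pi / 180
    cs <- cos(theta)
    sn <- sin(theta)
  }
  nz <- which(m != 0, arr.ind = TRUE)
  out <- matrix(0, n, n)
  if (nrow(nz) == 0L) {
    return(out)
  }
  dx <- nz[, 2] - cen
  dy <- cen - nz[, 1] # y axis points up
  rx <- dx * cs - dy * sn
  ry <- dx * sn + dy * cs
  col_f <- cen + rx
  row_f <- cen - ry
  vals <- m[nz]
  c0 <- floor(col_f); r0 <- floor(row_f)
  fc <- col_f - c0; fr <- row_f - r0
  for (i in seq_along(vals)) {
    for (dcol in 0:1) {
      for (drow in 0:1) {
        w <- (if (dcol == 0) 1 - fc[i] else fc[i]) *
             (if (drow == 0) 1 - fr[i] else fr[i])
        if (w == 0) next
        rr <- r0[i] + drow
        cc <- c0[i] + dcol
        if (rr >= 1 && rr <= n && cc >= 1 && cc <= n) {
          out[rr, cc] <- out[rr, cc] + w * vals[i]
        }
      }
    }
  }
  out
}

#' Rotation sweep of a 2D model frame
#'
#' Simulates one frame of a 2D model at every rotation angle (default 0 to
#' 330 degrees in 30-degree steps) and tabulates the one-dimensional metrics
#' of the x-projection (DIx, CWSNRx) against the rotation-robust composites
#' (SII, SCI), together with the mean and sample variance of each metric
#' across the angles.
#'
#' @inheritParams simulate_2d
#' @param angles rotation angles in degrees.
#' @param ... further arguments passed to [simulate_2d()].
#' @return list of class `rotation_sweep` with `per_angle` (data frame:
#'   angle, di_x, cwsnr_x, sii, sci) and `summary` (data frame: metric, mean,
#'   variance).
#' @examples
#' sw <- rotation_sweep("translation", t = 2)
#' sw$summary
#' @export
rotation_sweep <- function(model, t, angles = seq(0, 330, by = 30), ...) {
  rows <- lapply(angles, function(a) {
    mm <- map_metrics(simulate_2d(model, t = t, rotation_deg = a, ...))
    data.frame(angle = a, di_x = mm$axis_x$di, cwsnr_x = mm$axis_x$cwsnr,
               sii = mm$sii, sci = mm$sci)
  })
  per_angle <- do.call(rbind, rows)
  metrics <- c("di_x", "cwsnr_x", "sii", "sci")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(mc) mean(per_angle[[mc]]), numeric(1)),
    variance = vapply(metrics, function(mc) stats::var(per_angle[[mc]]), numeric(1)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  structure(list(per_angle = per_angle, summary = summary),
            class = "rotation_sweep")
}

#' @export
print.rotation_sweep <- function(x, ...) {
  print(x$per_angle)
  cat("\n")
  print(x$summary)
  invisible(x)
}

#' Reproducible random signal matrix
#'
#' Generates a square matrix of uniform random intensities for scalability
#' and stress testing. The same seed always yields the same matrix, and the
#' caller's random-number state is left untouched.
#'
#' @param dim side length (>= 1).
#' @param seed integer seed.
#' @param max_value upper bound of the uniform intensities (default 5000).
#' @return `dim` x `dim` non-negative numeric matrix.
#' @export
random_matrix <- function(dim, seed, max_value = 5000) {
  if (!is.numeric(dim) || length(dim) != 1L || dim < 1 || dim != floor(dim)) {
    stop("`dim` must be a single integer >= 1", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  matrix(stats::runif(dim * dim, 0, max_value), dim, dim)
}

#' Time the metric evaluation across matrix sizes
#'
#' Runs [map_metrics()] on reproducible random matrices of increasing size
#' and records the elapsed evaluation time (matrix generation is excluded).
#' Timings are hardware-dependent and are reported, never asserted.
#'
#' @param dims vector of side lengths.
#' @param reps repetitions per size (seeds `seed`, `seed + 1`, ...).
#' @param seed base seed.
#' @return data frame with columns `dim`, `rep`, `seed`, `seconds`.
#' @export
benchmark_metrics <- function(dims = c(400L, 800L, 1600L, 3200L), reps = 5L,
                              seed = 0L) {
  grid <- expand.grid(rep = seq_len(reps), dim = as.integer(dims))
  res <- lapply(seq_len(nrow(grid)), function(i) {
    d <- grid$dim[i]
    s <- seed + grid$rep[i] - 1L
    m <- random_matrix(d, s)
    el <- system.time(map_metrics(m))[["elapsed"]]
    data.frame(dim = d, rep = grid$rep[i], seed = s, seconds = el)
  })
  do.call(rbind, res)
}
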