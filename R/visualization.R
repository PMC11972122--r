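# Multi-layer secretion-signal map rendering: RBF surface interpolation,
# heatmap + contour + velocity layers, and the paired 3D cumulative/delta
# panels.

rbf_kernels <- c("gaussian", "multiquadric", "inverse", "linear", "cubic",
                 "quintic", "thin_plate")

rbf_eval <- function(r, kernel, eps) {
  switch(kernel,
    gaussian = exp(-(r / eps)^2),
    multiquadric = sqrt((r / eps)^2 + 1),
    inverse = 1 / sqrt((r / eps)^2 + 1),
    linear = r,
    cubic = r^3,
    quintic = r^5,
    thin_plate = ifelse(r == 0, 0, r^2 * log(r))
  )
}

#' Radial-basis-function surface interpolation of a signal map
#'
#' Fits an RBF interpolant through every grid cell (cell centers as nodes,
#' intensities as values) and samples it on a finer regular grid. The default
#' kernel is a 2D Gaussian; multiquadric, inverse, linear, cubic, quintic and
#' thin-plate kernels are available. With `smooth = 0` the surface passes
#' through the input samples (up to the linear-solve tolerance); positive
#' `smooth` relaxes the fit. The system is augmented with a constant term so
#' that a flat map yields an exactly flat surface under every kernel.
#'
#' The dense kernel system is solved directly, so the cost grows cubically
#' with the number of cells; maps beyond ~60 x 60 should be block-aggregated
#' first (see [crop_and_aggregate()]).
#'
#' @param m numeric matrix of non-negative intensities.
#' @param kernel one of `"gaussian"`, `"multiquadric"`, `"inverse"`,
#'   `"linear"`, `"cubic"`, `"quintic"`, `"thin_plate"`.
#' @param factor refinement factor of the output grid (default 2).
#' @param epsilon kernel length scale in grid units (default: mean node
#'   spacing, i.e. 1).
#' @param smooth non-negative smoothing parameter (default 0, interpolating).
#' @return list of class `rbf_surface` with `x`, `y` (output grid coordinates
#'   in input-cell units) and `z` (interpolated matrix, rows = y, cols = x).
#' @export
interpolate_surface <- function(m, kernel = "gaussian", factor = 2L,
                                epsilon = NULL, smooth = 0) {
  validate_signal_matrix(m)
  if (!is.character(kernel) || length(kernel) != 1L || !kernel %in% rbf_kernels) {
    stop(sprintf("unknown kernel '%s'; use one of: %s",
                 paste(kernel, collapse = ","),
                 paste(rbf_kernels, collapse = ", ")), call. = FALSE)
  }
  if (!is.numeric(factor) || factor < 1) {
    stop("`factor` must be >= 1", call. = FALSE)
  }
  nr <- nrow(m)
  nc <- ncol(m)
  if (nr * nc > 4096L) {
    stop("too many interpolation nodes; block-aggregate the map first",
         call. = FALSE)
  }
  if (is.null(epsilon)) epsilon <- 1
  nodes <- cbind(
    x = rep(seq_len(nc), each = nr),
    y = rep(seq_len(nr), times = nc)
  )
  vals <- as.vector(m)
  dmat <- as.matrix(stats::dist(nodes))
  A <- rbf_eval(dmat, kernel, epsilon)
  if (smooth > 0) diag(A) <- diag(A) - smooth
  # augment with a constant term (weights constrained to sum to zero) so a
  # flat map interpolates to an exactly flat surface for every kernel
  N <- length(vals)
  K <- rbind(cbind(A, 1), c(rep(1, N), 0))
  sol <- solve(K, c(vals, 0))
  w <- sol[seq_len(N)]
  c0 <- sol[N + 1L]

  xs <- seq(1, nc, length.out = max(2L, round((nc - 1) * factor) + 1L))
  ys <- seq(1, nr, length.out = max(2L, round((nr - 1) * factor) + 1L))
  grid <- cbind(x = rep(xs, each = length(ys)), y = rep(ys, times = length(xs)))
  # evaluate in row blocks to bound the cross-distance matrix size
  z <- numeric(nrow(grid))
  block <- 20000L
  for (start in seq(1L, nrow(grid), by = block)) {
    idx <- start:min(start + block - 1L, nrow(grid))
    cross <- sqrt(outer(grid[idx, "x"], nodes[, "x"], "-")^2 +
                    outer(grid[idx, "y"], nodes[, "y"], "-")^2)
    z[idx] <- rbf_eval(cross, kernel, epsilon) %*% w + c0
  }
  structure(
    list(x = xs, y = ys, z = matrix(z, nrow = length(ys), ncol = length(xs))),
    class = "rbf_surface"
  )
}

#' Rendering configuration for the secretion-signal map
#'
#' @param kernel RBF kernel for the interpolated layers
#'   (see [interpolate_surface()]).
#' @param n_hotspots number of peak hotspots seeding velocity arrows
#'   (default 3; 0 disables the velocity layer).
#' @param show_arrows draw the velocity arrows (default TRUE).
#' @param arrow_density step length of the gradient paths in surface-grid
#'   units (default 1).
#' @param contour_layers which contour layers to draw: `"delta"`,
#'   `"cumulative"`, `"both"` or `"none"`.
#' @param cumulative_cutoff contour levels below this value are suppressed in
#'   the cumulative layer (default 0).
#' @param color_range optional `c(min, max)` intensity range for the heatmap
#'   colors (default: data range).
#' @param width,height output size in pixels (default 900 x 900).
#' @param dpi nominal resolution (default 96).
#' @param label_cex axis/label magnification (default 1).
#' @param formats output formats, subset of `c("png", "svg")`.
#' @return list of class `render_config`.
#' @export
render_config <- function(kernel = "gaussian",
                          n_hotspots = 3L,
                          show_arrows = TRUE,
                          arrow_density = 1,
                          contour_layers = c("both", "delta", "cumulative", "none"),
                          cumulative_cutoff = 0,
                          color_range = NULL,
                          width = 900L, height = 900L, dpi = 96L,
                          label_cex = 1,
                          formats = "png") {
  contour_layers <- match.arg(contour_layers)
  if (!kernel %in% rbf_kernels) {
    stop(sprintf("unknown kernel '%s'", kernel), call. = FALSE)
  }
  if (!is.numeric(n_hotspots) || n_hotspots < 0) {
    stop("`n_hotspots` must be a non-negative integer", call. = FALSE)
  }
  if (!is.numeric(arrow_density) || arrow_density <= 0) {
    stop("`arrow_density` must be positive", call. = FALSE)
  }
  if (!all(formats %in% c("png", "svg"))) {
    stop("`formats` must be a subset of c('png', 'svg')", call. = FALSE)
  }
  structure(
    list(kernel = kernel, n_hotspots = as.integer(n_hotspots),
         show_arrows = isTRUE(show_arrows), arrow_density = arrow_density,
         contour_layers = contour_layers,
         cumulative_cutoff = cumulative_cutoff, color_range = color_range,
         width = as.integer(width), height = as.integer(height),
         dpi = as.integer(dpi), label_cex = label_cex, formats = formats),
    class = "render_config"
  )
}

# largest-n surface maxima with 3x3 non-maximum suppression
find_hotspots <- function(surface, n_hotspots) {
  z <- surface$z
  if (n_hotspots == 0L) {
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0)))
  }
  ord <- order(z, decreasing = TRUE)
  picked <- matrix(numeric(0), 0, 2)
  vals <- numeric(0)
  for (idx in ord) {
    rr <- (idx - 1) %% nrow(z) + 1
    cc <- (idx - 1) %/% nrow(z) + 1
    if (nrow(picked) == 0 ||
        all(abs(picked[, 1] - rr) > 1 | abs(picked[, 2] - cc) > 1)) {
      picked <- rbind(picked, c(rr, cc))
      vals <- c(vals, z[rr, cc])
      if (nrow(picked) >= n_hotspots) break
    }
  }
  data.frame(x = surface$x[picked[, 2]], y = surface$y[picked[, 1]], z = vals)
}

# follow the negative gradient of the surface from a seed; returns the path
gradient_path <- function(surface, x0, y0, step = 1, max_steps = 60L) {
  z <- surface$z
  gx <- z
  gy <- z
  dx <- mean(diff(surface$x))
  dy <- mean(diff(surface$y))
  nc <- ncol(z); nr <- nrow(z)
  gx[, 2:(nc - 1)] <- (z[, 3:nc] - z[, 1:(nc - 2)]) / (2 * dx)
  gx[, 1] <- (z[, 2] - z[, 1]) / dx
  gx[, nc] <- (z[, nc] - z[, nc - 1]) / dx
  gy[2:(nr - 1), ] <- (z[3:nr, ] - z[1:(nr - 2), ]) / (2 * dy)
  gy[1, ] <- (z[2, ] - z[1, ]) / dy
  gy[nr, ] <- (z[nr, ] - z[nr - 1, ]) / dy
  px <- x0; py <- y0
  path <- matrix(c(px, py), 1, 2)
  for (i in seq_len(max_steps)) {
    ci <- which.min(abs(surface$x - px))
    ri <- which.min(abs(surface$y - py))
    g <- c(gx[ri, ci], gy[ri, ci])
    gn <- sqrt(sum(g^2))
    if (gn < 1e-12) break
    px <- px - step * dx * g[1] / gn
    py <- py - step * dy * g[2] / gn
    px <- min(max(px, min(surface$x)), max(surface$x))
    py <- min(max(py, min(surface$y)), max(surface$y))
    path <- rbind(path, c(px, py))
    if (i > 1 && sqrt(sum((path[nrow(path), ] - path[nrow(path) - 1, ])^2)) <
          1e-6) {
      break
    }
  }
  path
}

heat_palette <- function(n = 64L) {
  grDevices::colorRampPalette(
    c("#1a1334", "#26294a", "#01545a", "#017351", "#03c383",
      "#aad962", "#fbbf45", "#ef6a32", "#ed0345", "#a12a5e")
  )(n)
}

draw_map_panel <- function(m_delta, m_cumulative, cfg) {
  surf_d <- interpolate_surface(m_delta, kernel = cfg$kernel)
  zr <- if (is.null(cfg$color_range)) range(surf_d$z) else cfg$color_range
  graphics::image(surf_d$x, surf_d$y, t(surf_d$z), zlim = zr,
                  col = heat_palette(), xlab = "x (grid units)",
                  ylab = "y (grid units)", cex.lab = cfg$label_cex,
                  cex.axis = cfg$label_cex, useRaster = TRUE)
  graphics::title("Secretion-signal map (delta layer)", cex.main = cfg$label_cex)
  if (cfg$contour_layers %in% c("delta", "both")) {
    graphics::contour(surf_d$x, surf_d$y, t(surf_d$z), add = TRUE,
                      col = "grey20", lwd = 0.6, labcex = 0.6 * cfg$label_cex)
  }
  if (cfg$contour_layers %in% c("cumulative", "both")) {
    surf_c <- interpolate_surface(m_cumulative, kernel = cfg$kernel)
    levels <- pretty(range(surf_c$z), 8)
    levels <- levels[levels > cfg$cumulative_cutoff]
    if (length(levels) > 0) {
      graphics::contour(surf_c$x, surf_c$y, t(surf_c$z), add = TRUE,
                        levels = levels, col = "grey60", lty = 2, lwd = 0.6,
                        labcex = 0.6 * cfg$label_cex)
    }
  }
  if (cfg$show_arrows && cfg$n_hotspots > 0L) {
    hot <- find_hotspots(surf_d, cfg$n_hotspots)
    for (i in seq_len(nrow(hot))) {
      path <- gradient_path(surf_d, hot$x[i], hot$y[i],
                            step = cfg$arrow_density)
      if (nrow(path) >= 2) {
        graphics::lines(path[, 1], path[, 2], col = "white", lwd = 1.4)
        k <- nrow(path)
        graphics::arrows(path[k - 1, 1], path[k - 1, 2], path[k, 1],
                         path[k, 2], length = 0.08, col = "white", lwd = 1.4)
      }
    }
    graphics::points(hot$x, hot$y, pch = 21, bg = "white", col = "black",
                     cex = 0.9 * cfg$label_cex)
  }
}

draw_3d_panel <- function(m, title, base_col, delta = NULL, cfg) {
  nr <- nrow(m); nc <- ncol(m)
  cols <- if (is.null(delta)) {
    matrix(base_col, nr - 1, nc - 1)
  } else {
    # facets where the delta change dominates shade from grey to red
    facet <- (delta[-1, -1] + delta[-1, -nc] + delta[-nr, -1] + delta[-nr, -nc]) / 4
    ramp <- grDevices::colorRampPalette(c(base_col, "#d62728"))(32)
    idx <- 1L + floor(31 * (facet - min(facet)) /
                        max(max(facet) - min(facet), .Machine$double.eps))
    matrix(ramp[idx], nr - 1, nc - 1)
  }
  graphics::persp(seq_len(nr), seq_len(nc), m, theta = 35, phi = 28,
                  expand = 0.55, col = cols, border = NA, shade = 0.45,
                  xlab = "y", ylab = "x", zlab = "signal",
                  main = title, cex.main = cfg$label_cex)
}

#' Render the stacked multi-layer secretion-signal map
#'
#' Writes the three-layer 2D map (RBF-interpolated heatmap of the delta
#' signal, contour layers for delta and/or cumulative signal, and a velocity
#' layer of arrows flowing from the top peaks down the surface gradient)
#' together with two 3D panels: the cumulative signal with the delta change
#' highlighted in red over a grey baseline, and the delta change alone.
#' Each panel is a separate file; inputs are never modified.
#'
#' @param m_delta delta-change signal matrix.
#' @param m_cumulative cumulative signal matrix of the same shape.
#' @param cfg a [render_config()].
#' @param out output path prefix; files `<out>_map.<fmt>`,
#'   `<out>_cumulative3d.<fmt>` and `<out>_delta3d.<fmt>` are written for
#'   each configured format.
#' @return character vector of the files written, invisibly.
#' @export
render_map <- function(m_delta, m_cumulative, cfg = render_config(), out) {
  validate_signal_matrix(m_delta, "m_delta")
  validate_signal_matrix(m_cumulative, "m_cumulative")
  if (!all(dim(m_delta) == dim(m_cumulative))) {
    stop("`m_delta` and `m_cumulative` must have the same shape", call. = FALSE)
  }
  if (!inherits(cfg, "render_config")) {
    stop("`cfg` must be a `render_config()`", call. = FALSE)
  }
  if (cfg$width < 1L || cfg$height < 1L) {
    stop("zero-size figure requested", call. = FALSE)
  }
  dir <- dirname(out)
  if (!dir.exists(dir)) {
    stop(sprintf("output directory does not exist: %s", dir), call. = FALSE)
  }
  panels <- list(
    map = function() draw_map_panel(m_delta, m_cumulative, cfg),
    cumulative3d = function() {
      draw_3d_panel(m_cumulative, "Cumulative signal (red = delta change)",
                    "#bdbdbd", delta = m_delta, cfg = cfg)
    },
    delta3d = function() {
      draw_3d_panel(m_delta, "Signal delta change", "#f4a582", cfg = cfg)
    }
  )
  written <- character(0)
  for (fmt in cfg$formats) {
    for (name in names(panels)) {
      file <- sprintf("%s_%s.%s", out, name, fmt)
      if (fmt == "png") {
        grDevices::png(file, width = cfg$width, height = cfg$height,
                       res = cfg$dpi, type = "cairo")
      } else {
        grDevices::svg(file, width = cfg$width / cfg$dpi,
                       height = cfg$height / cfg$dpi)
      }
      ok <- try(panels[[name]](), silent = TRUE)
      grDevices::dev.off()
      if (inherits(ok, "try-error")) {
        stop(sprintf("failed to render panel '%s': %s", name,
                     attr(ok, "condition")$message), call. = FALSE)
      }
      written <- c(written, file)
    }
  }
  invisible(written)
}
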