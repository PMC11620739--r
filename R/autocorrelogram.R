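# Spatial autocorrelograms of rate maps.
#
# The autocorrelogram holds, for every integer pixel displacement, the
# Pearson correlation between the map and a shifted copy of itself computed
# over the overlapping region.  The per-lag sums needed for the correlation
# (overlap size, sums, sums of squares, cross products) are obtained with
# zero-padded FFT cross-correlations, which makes a 41 x 41 map cost a few
# milliseconds instead of seconds.

xcorr2 <- function(a, b) {
  # full cross-correlation sum_{x} a(x) * b(x + lag), lags -(n-1)..(n-1)
  n <- nrow(a)
  m <- 2L^ceiling(log2(2L * n))
  pa <- matrix(0, m, m); pa[1:n, 1:n] <- a
  pb <- matrix(0, m, m); pb[1:n, 1:n] <- b
  r <- Re(fft(Conj(fft(pa)) * fft(pb), inverse = TRUE)) / m^2
  idx <- c((m - n + 2):m, 1:n)
  r[idx, idx]
}

#' Spatial autocorrelogram of a rate map
#'
#' Correlates two copies of the map displaced relative to one another in
#' all directions and magnitudes (Pearson correlation over the overlap at
#' each displacement), then multiplies by a circular Hamming taper of the
#' arena's spatial extent centred at zero lag, which suppresses the
#' poorly-sampled extreme displacements.
#'
#' @param map matrix (a single cell's rate map).
#' @param pixel_size pixel side in metres (for the window and lag scale).
#' @param window apply the circular Hamming taper (default `TRUE`).
#' @param window_radius taper radius in metres (reaches its minimum at this
#'   lag distance); defaults to the arena side, i.e. the full lag range of
#'   a square map.
#' @param min_overlap smallest overlap (pixels) for which a correlation is
#'   computed; smaller overlaps are set to zero.
#' @return object of class `autocorrelogram`: list with `values`
#'   ((2n-1) x (2n-1) matrix, zero lag at the centre), `lag_step`,
#'   `window_applied`, and `degenerate` (`TRUE` for a constant map, whose
#'   correlation is undefined).
#' @export
compute_autocorrelogram <- function(map, pixel_size = 0.024, window = TRUE,
                                    window_radius = NULL,
                                    min_overlap = 16) {
  stopifnot(is.matrix(map), nrow(map) == ncol(map))
  n <- nrow(map)
  degenerate <- sd(map) == 0
  one <- matrix(1, n, n)
  cnt <- xcorr2(one, one)
  sab <- xcorr2(map, map)
  sa <- xcorr2(map, one)
  sb <- xcorr2(one, map)
  sa2 <- xcorr2(map^2, one)
  sb2 <- xcorr2(one, map^2)
  cnt_r <- pmax(round(cnt), 1)
  num <- cnt_r * sab - sa * sb
  den <- sqrt(pmax(cnt_r * sa2 - sa^2, 0) * pmax(cnt_r * sb2 - sb^2, 0))
  ac <- ifelse(den > 1e-9 & cnt_r >= min_overlap, num / den, 0)
  lag <- (-(n - 1)):(n - 1) * pixel_size
  raw <- ac
  if (window) {
    if (is.null(window_radius)) window_radius <- n * pixel_size
    rho <- sqrt(outer(lag^2, lag^2, `+`))
    w <- ifelse(rho <= window_radius,
                0.54 + 0.46 * cos(pi * rho / window_radius), 0)
    ac <- ac * w
  }
  structure(list(values = ac, raw = raw, lag_step = pixel_size, lags = lag,
                 window_applied = window, degenerate = degenerate),
            class = "autocorrelogram")
}

#' Mean population autocorrelogram
#'
#' Element-wise average of the per-cell autocorrelograms of a map stack.
#'
#' @param maps array `[n_cells, n_px, n_px]`.
#' @param pixel_size pixel side (m).
#' @param ... passed to [compute_autocorrelogram()].
#' @return an `autocorrelogram` object.
#' @export
population_autocorrelogram <- function(maps, pixel_size = 0.024, ...) {
  n_cells <- dim(maps)[1]
  acc <- NULL
  out <- NULL
  for (i in seq_len(n_cells)) {
    a <- compute_autocorrelogram(maps[i, , ], pixel_size, ...)
    if (is.null(acc)) {
      acc <- a$values
      raw <- a$raw
      out <- a
    } else {
      acc <- acc + a$values
      raw <- raw + a$raw
    }
  }
  out$values <- acc / n_cells
  out$raw <- raw / n_cells
  out$degenerate <- FALSE
  out
}

#' @export
print.autocorrelogram <- function(x, ...) {
  cat(sprintf("autocorrelogram: %d x %d lags, step %.1f cm%s%s\n",
              nrow(x$values), ncol(x$values), 100 * x$lag_step,
              if (x$window_applied) ", Hamming-windowed" else "",
              if (x$degenerate) ", DEGENERATE (constant map)" else ""))
  invisible(x)
}

#' @export
plot.autocorrelogram <- function(x, ...) {
  graphics::image(x$lags, x$lags, x$values, asp = 1,
                  xlab = "lag x (m)", ylab = "lag y (m)",
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE), ...)
  invisible(x)
}

# bilinear interpolation of the autocorrelogram on a polar grid
# radii in metres, angles in radians; returns radius x angle matrix.
# use = "values" samples the windowed correlogram, "raw" the unwindowed
# one (magnitude comparisons across radii must not see the radial taper).
polar_interp <- function(ac, radii, angles, use = "values") {
  vals <- ac[[use]]
  n <- nrow(vals)
  c0 <- (n + 1) / 2  # centre index of zero lag
  px <- ac$lag_step
  out <- matrix(0, length(radii), length(angles))
  ca <- cos(angles); sa <- sin(angles)
  for (ri in seq_along(radii)) {
    x <- c0 + radii[ri] * ca / px
    y <- c0 + radii[ri] * sa / px
    x0 <- floor(x); y0 <- floor(y)
    fx <- x - x0; fy <- y - y0
    ok <- x0 >= 1 & y0 >= 1 & x0 < n & y0 < n
    v <- numeric(length(angles))
    if (any(ok)) {
      i00 <- cbind(x0[ok], y0[ok]); i10 <- cbind(x0[ok] + 1, y0[ok])
      i01 <- cbind(x0[ok], y0[ok] + 1); i11 <- cbind(x0[ok] + 1, y0[ok] + 1)
      v[ok] <- vals[i00] * (1 - fx[ok]) * (1 - fy[ok]) +
        vals[i10] * fx[ok] * (1 - fy[ok]) +
        vals[i01] * (1 - fx[ok]) * fy[ok] +
        vals[i11] * fx[ok] * fy[ok]
    }
    out[ri, ] <- v
  }
  out
}
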