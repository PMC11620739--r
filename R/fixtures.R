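# Synthetic fixtures: ideal grid populations with controlled phase layouts
# and samples of known manifolds.  They emulate the end-state structure of
# trained networks (not the learning transients) so the analysis stack can
# be exercised in seconds.

#' Ideal grid map from the three-cosine kernel
#'
#' Rasterizes `f(x - phase)` with
#' `f(x) = 1 + (2/3) sum_i cos(k_i . x)` (three wave vectors 120 degrees
#' apart, modulus set by `spacing`) on the standard rate-map pixel grid.
#' `f` ranges over `[0, 3]`, so the map is a valid nonnegative rate map.
#'
#' @param spacing grid spacing (m).
#' @param orientation grid orientation (radians).
#' @param phase length-2 spatial phase offset (m).
#' @param n_px,pixel_size,arena_side pixel grid geometry.
#' @return `n_px x n_px` matrix.
#' @export
grid_kernel_map <- function(spacing = 0.6, orientation = 0, phase = c(0, 0),
                            n_px = 41, pixel_size = 0.024, arena_side = 1) {
  off <- (arena_side - n_px * pixel_size) / 2
  cs <- off + (seq_len(n_px) - 0.5) * pixel_size
  dx <- outer(cs - phase[1], rep(1, n_px))
  dy <- outer(rep(1, n_px), cs - phase[2])
  grid_kernel(dx, dy, spacing, orientation)
}

#' Synthetic population of aligned grid cells
#'
#' Generates `n_cells` rate maps sharing spacing and orientation and
#' differing only in spatial phase, emulating a trained, aligned
#' population.  Phase layouts:
#'
#' * `"uniform"` — phases i.i.d. uniform over the unit cell of the grid
#'   lattice.  The population activity over the central crop is then a
#'   sample of a torus.
#' * `"ring"` — phases traverse a closed cycle of the unit cell with an
#'   integer winding vector, emulating the configurations found with ring
#'   attractors; the neuron cloud then has the homology of a circle.
#'
#' Additive Gaussian noise (s.d. `noise_sd`, in rate units; the kernel peak
#' is 3) is clipped at zero.
#'
#' @param n_cells number of cells.
#' @param spacing,orientation lattice geometry (m, radians).
#' @param phase_layout `"uniform"` or `"ring"`.
#' @param winding integer winding vector (w1, w2) in lattice coordinates
#'   for the ring layout; `(1, 0)` is the first-order configuration.
#' @param wiggle transverse modulation amplitude (unit-cell fraction) of
#'   the ring layout, used to break the bump-degeneracy of windings whose
#'   coordinates share a common factor.
#' @param noise_sd additive noise s.d.
#' @param seed optional RNG seed.
#' @param n_px,pixel_size,arena_side pixel grid geometry.
#' @return array `[n_cells, n_px, n_px]` with attributes `phases` (n x 2),
#'   `spacing`, `orientation`, `pixel_size`, `arena_side`.
#' @export
ideal_grid_population <- function(n_cells = 100, spacing = 0.6,
                                  orientation = 0,
                                  phase_layout = c("uniform", "ring"),
                                  winding = c(1, 0), wiggle = 0,
                                  noise_sd = 0, seed = NULL,
                                  n_px = 41, pixel_size = 0.024,
                                  arena_side = 1) {
  phase_layout <- match.arg(phase_layout)
  if (!is.null(seed)) set.seed(seed)
  # translation lattice of the three-cosine kernel: the maxima sit on a
  # hexagonal lattice rotated 30 degrees from the wave vectors
  th <- orientation + pi / 6
  a1 <- spacing * c(cos(th), sin(th))
  a2 <- spacing * c(cos(th + pi / 3), sin(th + pi / 3))
  uv <- switch(phase_layout,
    uniform = cbind(runif(n_cells), runif(n_cells)),
    ring = {
      s <- (seq_len(n_cells) - 1) / n_cells
      perp <- c(-winding[2], winding[1])
      base <- cbind(s * winding[1], s * winding[2])
      base + wiggle * sin(2 * pi * s) %o% perp
    })
  phases <- cbind(uv[, 1] * a1[1] + uv[, 2] * a2[1],
                  uv[, 1] * a1[2] + uv[, 2] * a2[2])
  maps <- array(0, c(n_cells, n_px, n_px))
  for (c in seq_len(n_cells)) {
    m <- grid_kernel_map(spacing, orientation, phases[c, ], n_px,
                         pixel_size, arena_side)
    if (noise_sd > 0) m <- pmax(m + rnorm(length(m), 0, noise_sd), 0)
    maps[c, , ] <- m
  }
  structure(maps, phases = phases, spacing = spacing,
            orientation = orientation, pixel_size = pixel_size,
            arena_side = arena_side)
}

#' Samples of reference manifolds
#'
#' Seeded samples of spaces with known topology, used as ground truth for
#' the analysis stack:
#'
#' * `"torus"` — flat torus, standard double-angle embedding in R^4;
#' * `"circle"` — unit circle in R^2;
#' * `"sheet"` — unit square in R^3 (a bounded 2-manifold with boundary);
#' * `"sphere_patch"` — geodesic cap of the unit d-sphere in R^(d+1)
#'   (default `dim = 2`; `dim = 3` gives a locally 3-dimensional sample);
#' * `"klein"` — Klein bottle, half-twisted tube embedding in R^4;
#' * `"two_planes"` — two 2-planes in R^4 glued at a single point (a cone
#'   singularity: an annulus around the origin has beta1 = 2).
#'
#' The closed surfaces (`torus`, `klein`) are sampled on a stratified grid
#' with uniform jitter, which keeps their Rips homology detectable at
#' moderate sample sizes; the other spaces are sampled uniformly at random.
#' Ambient Gaussian noise of s.d. `noise_sd` is added to all coordinates.
#'
#' @param kind manifold name.
#' @param n number of points (stratified kinds round to a near-square
#'   grid).
#' @param noise_sd ambient noise s.d.
#' @param seed optional RNG seed.
#' @param dim sphere dimension for `"sphere_patch"`.
#' @param cap_angle geodesic radius (radians) of the sphere patch.
#' @param tube_radius minor radius of the Klein tube embedding.
#' @return a [point_cloud()] with Euclidean metric (re-metrize as needed).
#' @export
manifold_sample <- function(kind = c("torus", "circle", "sheet",
                                     "sphere_patch", "klein", "two_planes"),
                            n = 625, noise_sd = 0, seed = NULL,
                            dim = 2, cap_angle = pi / 3, tube_radius = 0.5) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  pts <- switch(kind,
    torus = {
      uv <- stratified_angles(n)
      cbind(cos(uv[, 1]), sin(uv[, 1]), cos(uv[, 2]), sin(uv[, 2]))
    },
    circle = {
      th <- runif(n, 0, 2 * pi)
      cbind(cos(th), sin(th))
    },
    sheet = cbind(runif(n), runif(n), 0),
    sphere_patch = {
      x <- matrix(rnorm(n * (dim + 1)), n)
      x <- x / sqrt(rowSums(x^2))
      x[, dim + 1] <- abs(x[, dim + 1])
      keep <- x[, dim + 1] >= cos(cap_angle)
      while (sum(keep) < n) {  # top up the cap
        y <- matrix(rnorm(n * (dim + 1)), n)
        y <- y / sqrt(rowSums(y^2))
        y[, dim + 1] <- abs(y[, dim + 1])
        x <- rbind(x[keep, , drop = FALSE], y)
        keep <- x[, dim + 1] >= cos(cap_angle)
      }
      x[keep, , drop = FALSE][seq_len(n), ]
    },
    klein = {
      uv <- stratified_angles(n)
      u <- uv[, 1]; v <- uv[, 2]; r <- tube_radius
      cbind((1 + r * cos(u)) * cos(v), (1 + r * cos(u)) * sin(v),
            r * sin(u) * cos(v / 2), r * sin(u) * sin(v / 2))
    },
    two_planes = {
      half <- n %/% 2
      a <- cbind(runif(half, -0.5, 0.5), runif(half, -0.5, 0.5), 0, 0)
      b <- cbind(0, 0, runif(n - half, -0.5, 0.5), runif(n - half, -0.5, 0.5))
      rbind(a, b)
    })
  if (noise_sd > 0) pts <- pts + rnorm(length(pts), 0, noise_sd)
  point_cloud(pts, metric = "euclidean",
              provenance = paste0("fixture:", kind))
}

# near-square stratified grid of angle pairs with full-cell jitter
# (jittered-grid sampling): variance-reduced coverage without the comb
# artifacts of a nearly exact grid
stratified_angles <- function(n) {
  ns <- ceiling(sqrt(n))
  ms <- ceiling(n / ns)
  g <- expand.grid(u = (seq_len(ns) - 1) / ns, v = (seq_len(ms) - 1) / ms)
  g <- g[seq_len(min(n, nrow(g))), ]
  ju <- runif(nrow(g), 0, 1 / ns)
  jv <- runif(nrow(g), 0, 1 / ms)
  cbind(2 * pi * (g$u + ju), 2 * pi * (g$v + jv))
}
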