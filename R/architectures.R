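# Fixed recurrent-collateral architectures.  Each builder returns the raw
# nonnegative kernel; build_architecture() zeroes the diagonal, normalizes
# every row to unit L1 norm and applies the recurrent gain and scale, which
# is the form consumed by the simulation.

#' Recurrent weight matrix for the configured architecture
#'
#' Builds the raw architecture kernel, zeroes self-connections, normalizes
#' each row to unit L1 norm, multiplies by `recurrent_gain * recurrent_scale`
#' and optionally shuffles, per row, the identities of the presynaptic
#' partners (preserving each row's weight multiset).
#'
#' @param config a [sim_config()].
#' @return `n_grid x n_grid` nonnegative matrix (all zeros for
#'   `architecture = "none"`).
#' @export
build_architecture <- function(config) {
  W <- switch(config$architecture,
              torus2d = build_torus_architecture(config),
              ring1d = build_ring_architecture(config),
              stripe1dl = build_stripe_architecture(config),
              fragmented = build_fragmented_architecture(config),
              none = matrix(0, config$n_grid, config$n_grid))
  diag(W) <- 0
  rs <- rowSums(W)
  pos <- rs > 0
  W[pos, ] <- W[pos, , drop = FALSE] / rs[pos]
  W <- W * config$recurrent_gain * config$recurrent_scale
  if (config$shuffle_recurrent) {
    n <- nrow(W)
    for (i in seq_len(n)) W[i, -i] <- sample(W[i, -i])
  }
  W
}

#' Toroidal (2D) architecture kernel
#'
#' Neurons are assigned positions on a uniform sqrt(n) x sqrt(n) lattice
#' covering an arena-sized sheet with periodic boundaries.  The connection
#' between two neurons is `f(x_k - x_l)` where
#' `f(x) = 1 + (2/3) * sum_i cos(k_i . x)` with three wave vectors 120
#' degrees apart whose modulus `4*pi / (sqrt(3) * spacing)` makes `f` an
#' ideal grid map of the configured `kernel_spacing`.  `f` ranges over
#' `[0, 3]`, so the kernel is nonnegative by construction.
#'
#' @param config a [sim_config()]; `n_grid` must be a perfect square.
#' @return raw `n_grid x n_grid` kernel (no normalization).
#' @export
build_torus_architecture <- function(config) {
  n <- config$n_grid
  ns <- as.integer(round(sqrt(n)))
  if (ns^2 != n)
    stop("torus2d architecture needs n_grid to be a perfect square")
  L <- config$arena_side
  xy <- cbind(rep(seq_len(ns) - 1, times = ns),
              rep(seq_len(ns) - 1, each = ns)) * (L / ns)
  dx <- outer(xy[, 1], xy[, 1], `-`)
  dy <- outer(xy[, 2], xy[, 2], `-`)
  # periodic wrap of relative positions into [-L/2, L/2)
  dx <- dx - L * round(dx / L)
  dy <- dy - L * round(dy / L)
  grid_kernel(dx, dy, config$kernel_spacing)
}

# the three-cosine ideal grid function, f in [0, 3]
grid_kernel <- function(dx, dy, spacing, orientation = 0) {
  kmod <- 4 * pi / (sqrt(3) * spacing)
  ang <- orientation + c(0, 2 * pi / 3, 4 * pi / 3)
  v <- 1
  for (a in ang) v <- v + (2 / 3) * cos(kmod * (cos(a) * dx + sin(a) * dy))
  v
}

#' Ring (1D) architecture kernel
#'
#' Neurons sit uniformly on an imaginary ring (3.6 degrees apart for 100
#' cells); the connection strength is a Gaussian of the minimum angular
#' distance with s.d. `ring_sigma_deg` (7.2 degrees by default).
#'
#' @param config a [sim_config()].
#' @return raw kernel matrix.
#' @export
build_ring_architecture <- function(config) {
  n <- config$n_grid
  th <- (seq_len(n) - 1) * 360 / n
  d <- abs(outer(th, th, `-`))
  d <- pmin(d, 360 - d)
  exp(-(d / config$ring_sigma_deg)^2 / 2)
}

#' Stripe (1D, non-periodic) architecture kernel
#'
#' Neurons sit uniformly on an imaginary line; the connection strength is a
#' Gaussian of the distance with s.d. equal to `stripe_sigma_units` times
#' the distance between consecutive neurons.  Rows near the extremes have a
#' smaller total input because the line does not wrap.
#'
#' @param config a [sim_config()].
#' @return raw kernel matrix.
#' @export
build_stripe_architecture <- function(config) {
  n <- config$n_grid
  d <- abs(outer(seq_len(n), seq_len(n), `-`))
  exp(-(d / config$stripe_sigma_units)^2 / 2)
}

#' Fragmented architecture kernel
#'
#' `fragment_reps` times, `fragment_size` cells are drawn at random and the
#' mutual weights of a short stripe attractor connecting them (in the order
#' drawn) are added to the matrix.  The result is the overlap of many short
#' one-dimensional attractors.  Uses R's RNG.
#'
#' @param config a [sim_config()].
#' @return raw kernel matrix.
#' @export
build_fragmented_architecture <- function(config) {
  n <- config$n_grid
  W <- matrix(0, n, n)
  ks <- exp(-(abs(outer(seq_len(config$fragment_size),
                        seq_len(config$fragment_size), `-`)) /
                config$stripe_sigma_units)^2 / 2)
  for (rep in seq_len(config$fragment_reps)) {
    sel <- sample(n, config$fragment_size)
    W[sel, sel] <- W[sel, sel] + ks
  }
  W
}
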