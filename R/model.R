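# Reference implementations of the network-model operations.  These are the
# exact (dense) versions of each step of the update loop; the fused C++
# stepper used by run_grid_sim() is cross-checked against them in the tests.

#' Centres of the input tuning curves
#'
#' Input cells sit on a uniform sqrt(n_input) x sqrt(n_input) lattice over
#' the arena, at the centres of equal square tiles.
#'
#' @param config a [sim_config()].
#' @return n_input x 2 matrix of (x, y) centres in metres.
#' @export
input_centers <- function(config) {
  ns <- as.integer(round(sqrt(config$n_input)))
  cs <- (seq_len(ns) - 0.5) * config$arena_side / ns
  cbind(x = rep(cs, times = ns), y = rep(cs, each = ns))
}

#' Input-layer firing rates at a position
#'
#' Each input cell responds with a Gaussian tuning curve of width
#' `input_sigma` and peak `input_peak_rate` centred on its preferred
#' position: r_j = peak * exp(-d_j^2 / (2 sigma^2)).
#'
#' @param position numeric (x, y) inside the arena.
#' @param config a [sim_config()].
#' @return numeric vector of length `n_input`.
#' @export
input_rates <- function(position, config) {
  stopifnot(length(position) == 2,
            all(position >= 0), all(position <= config$arena_side))
  ctr <- input_centers(config)
  d2 <- (ctr[, 1] - position[1])^2 + (ctr[, 2] - position[2])^2
  config$input_peak_rate * exp(-d2 / (2 * config$input_sigma^2))
}

#' Initialise the network state
#'
#' Feedforward weights start as i.i.d. uniform(0,1) rows scaled to unit
#' Euclidean norm; internal variables, rates and running averages start at
#' zero.  The recurrent matrix is built from the configured architecture.
#'
#' @param config a [sim_config()].
#' @param W_rec optional pre-built recurrent matrix (otherwise
#'   [build_architecture()] is called).
#' @return A list of class `network_state` with elements `W_in`, `W_rec`,
#'   `h_act`, `h_inact`, `r_grid`, `r_bar_grid`, `r_bar_in`.
#' @export
network_state <- function(config, W_rec = NULL) {
  W <- matrix(runif(config$n_grid * config$n_input), config$n_grid)
  W <- W / sqrt(rowSums(W^2))
  if (is.null(W_rec)) W_rec <- build_architecture(config)
  st <- list(W_in = W, W_rec = W_rec,
             h_act = numeric(config$n_grid),
             h_inact = numeric(config$n_grid),
             r_grid = numeric(config$n_grid),
             r_bar_grid = numeric(config$n_grid),
             r_bar_in = numeric(config$n_input))
  class(st) <- "network_state"
  st
}

#' Total field received by each grid cell
#'
#' The field is the sum of the feedforward drive `W_in %*% r_in` and the
#' recurrent drive computed from the previous step's grid-cell rates.  The
#' recurrent term is divided by the current mean grid rate so that, with
#' row-normalized recurrent weights, its magnitude stays comparable to the
#' feedforward term irrespective of the overall activity scale.
#'
#' @param state a `network_state`.
#' @param r_in input rates (previous/current step).
#' @param config a [sim_config()].
#' @return numeric vector `h` of length `n_grid`.
#' @export
compute_fields <- function(state, r_in, config) {
  if (length(r_in) != ncol(state$W_in)) stop("r_in has the wrong length")
  h <- drop(state$W_in %*% r_in)
  mr <- mean(state$r_grid)
  if (!is.null(state$W_rec) && mr > 1e-12)
    h <- h + drop(state$W_rec %*% state$r_grid) / mr
  h
}

#' One adaptation step
#'
#' Two internal variables mimic neural fatigue:
#' `h_act(t+1) = h(t) - h_inact(t)` and
#' `h_inact(t+1) = h_inact(t) + beta * h_act(t)`.
#' Under a sustained constant field the activating component relaxes toward
#' zero, forcing cells to take turns.
#'
#' @param state a `network_state`.
#' @param h total field from [compute_fields()].
#' @param config a [sim_config()].
#' @return the state with `h_act`, `h_inact` advanced by one step.
#' @export
adaptation_step <- function(state, h, config) {
  h_act_old <- state$h_act
  state$h_act <- h - state$h_inact
  state$h_inact <- state$h_inact + config$beta_adapt * h_act_old
  state
}

#' Threshold-linear transfer with an exact active fraction
#'
#' A threshold T (global inhibition) is set at the
#' `(1 - active_fraction)` quantile of `h_act` so that exactly
#' `ceiling(active_fraction * n_grid)` cells exceed it (ties broken by cell
#' index).  Rates are `G * (h_act - T)_+ / mean((h_act - T)_+)`, the mean
#' running over all cells, so the population mean rate equals `G` whenever
#' any cell is active.
#'
#' @param h_act activation variable, length `n_grid`.
#' @param config a [sim_config()].
#' @return nonnegative rate vector; all zeros when the drive is degenerate
#'   (normalisation denominator below 1e-12).
#' @export
apply_transfer <- function(h_act, config) {
  n <- length(h_act)
  m <- ceiling(config$active_fraction * n)
  if (m >= n) {
    T <- min(h_act) - 1  # everyone active
  } else {
    o <- order(-h_act, seq_len(n))
    T <- h_act[o[m + 1]]
  }
  v <- pmax(h_act - T, 0)
  if (m < n) v[order(-h_act, seq_len(n))[(m + 1):n]] <- 0
  den <- mean(v)
  if (den < 1e-12) return(numeric(n))
  config$gain_G * v / den
}

#' Hebbian update of the feedforward weights
#'
#' `dW_ij = eps * (r_in_j * r_grid_i - rbar_in_j * rbar_grid_i)`; negative
#' weights are clipped to zero and each row is divided by its Euclidean
#' norm, pinning the presynaptic weight vector of every cell to the unit
#' sphere (synapses of a cell compete for a fixed total strength).
#' The running averages are then advanced:
#' `rbar(t+1) = rbar(t) * (1 - delta) + r(t) * delta`.
#'
#' @param state a `network_state`.
#' @param r_in input rates used for this step.
#' @param r_grid grid-cell rates produced this step.
#' @param config a [sim_config()].
#' @return the state with `W_in`, `r_bar_grid`, `r_bar_in`, `r_grid` updated.
#' @export
hebbian_update <- function(state, r_in, r_grid, config) {
  dW <- config$epsilon_learn *
    (outer(r_grid, r_in) - outer(state$r_bar_grid, state$r_bar_in))
  W <- pmax(state$W_in + dW, 0)
  nrm <- sqrt(rowSums(W^2))
  scl <- ifelse(nrm > 0, 1 / nrm, 1)
  state$W_in <- W * scl
  state$r_bar_grid <- state$r_bar_grid * (1 - config$delta_avg) +
    r_grid * config$delta_avg
  state$r_bar_in <- state$r_bar_in * (1 - config$delta_avg) +
    r_in * config$delta_avg
  state$r_grid <- r_grid
  state
}

#' Update the rate-map accumulator for one visited pixel
#'
#' Only the pixel currently traversed is touched:
#' `m <- m * (1 - tau) + r * tau`; every other pixel is left unchanged.
#'
#' @param maps array `[n_grid, n_px, n_px]` of running mean rates.
#' @param position (x, y) in metres.
#' @param r_grid instantaneous rates.
#' @param config a [sim_config()].
#' @return the updated array.
#' @export
update_rate_maps <- function(maps, position, r_grid, config) {
  off <- (config$arena_side - config$n_px * config$pixel_size) / 2
  px <- min(config$n_px, max(1, 1 + floor((position[1] - off) / config$pixel_size)))
  py <- min(config$n_px, max(1, 1 + floor((position[2] - off) / config$pixel_size)))
  maps[, px, py] <- maps[, px, py] * (1 - config$tau_map) +
    r_grid * config$tau_map
  maps
}

#' Random-walk trajectory through the arena
#'
#' The virtual animal moves a fixed distance each step; the running
#' direction changes by independent normal increments (s.d. `turn_sd`
#' degrees).  Steps that would leave the arena trigger a redraw of the turn
#' until the step stays inside.  Uses R's RNG, so the result is
#' reproducible under [set.seed()].
#'
#' @param config a [sim_config()]; `n_steps` may be overridden.
#' @param n_steps optional number of steps.
#' @return A list of class `trajectory` with `positions` (n x 2, metres)
#'   and `headings` (radians).
#' @export
generate_trajectory <- function(config, n_steps = config$n_steps) {
  if (n_steps < 1) stop("n_steps must be positive")
  tr <- cpp_generate_trajectory(as.integer(n_steps), config$step_length,
                                config$turn_sd * pi / 180, config$arena_side)
  colnames(tr$positions) <- c("x", "y")
  class(tr) <- "trajectory"
  tr
}
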