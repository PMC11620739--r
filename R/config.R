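#' Simulation configuration
#'
#' Bundles every model, trajectory, architecture and discretisation
#' parameter of the self-organizing grid-cell network.  Defaults are the
#' reference parameter set used throughout the package: a 1 m square arena,
#' 225 place-cell-like inputs with 5.4 cm Gaussian fields and peak rate 20,
#' 100 grid cells of which 60% may fire at any time, adaptation strength
#' 0.04, feedforward gain 0.1, recurrent gain 2 and a 60 cm design spacing
#' for the toroidal architecture kernel.  All lengths are in metres.
#'
#' @param n_input number of input cells (must be a perfect square; the
#'   tuning-curve centres sit on a uniform lattice over the arena).
#' @param n_grid number of grid cells.
#' @param arena_side side of the square arena (m).
#' @param input_sigma standard deviation of the input Gaussian fields (m).
#' @param input_peak_rate firing rate of an input cell at its field centre.
#' @param step_length distance travelled in one simulation step (m).
#' @param turn_sd s.d. of the per-step change in running direction (degrees).
#' @param n_steps number of simulation steps.
#' @param beta_adapt adaptation (neural fatigue) parameter.
#' @param gain_G gain of the threshold-linear transfer function.
#' @param recurrent_gain gain applied to the normalized recurrent input.
#' @param active_fraction fraction of grid cells allowed to be active.
#' @param epsilon_learn Hebbian learning rate.
#' @param delta_avg rate of the running-average estimator used by the
#'   Hebbian rule.
#' @param tau_map update rate of the exponential rate-map accumulator.
#' @param architecture recurrent-collateral architecture, one of
#'   `"torus2d"`, `"ring1d"`, `"stripe1dl"`, `"fragmented"`, `"none"`.
#' @param recurrent_scale multiplier on the recurrent weights (1 for the
#'   standard conditions; use e.g. 5 or 0.2 for the too-strong/too-weak
#'   controls).
#' @param shuffle_recurrent if `TRUE`, the presynaptic identities of each
#'   row of the recurrent matrix are permuted (weight multiset preserved).
#' @param kernel_spacing design spacing of the imaginary grid map that
#'   defines the toroidal kernel (m).
#' @param ring_sigma_deg s.d. (degrees) of the Gaussian ring kernel.
#' @param stripe_sigma_units s.d. of the stripe kernel in units of the
#'   inter-neuron distance.
#' @param fragment_reps,fragment_size number of fragments and cells per
#'   fragment for the fragmented architecture.
#' @param n_px number of rate-map pixels per side.
#' @param pixel_size rate-map pixel side (m).
#' @param rec_off_at fraction of the run after which the recurrent
#'   collaterals are silenced (`NULL` to keep them throughout); used for the
#'   attractor-off control.
#' @param seed integer seed making the whole run reproducible.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(architecture = "ring1d", n_steps = 1000, seed = 1)
#' cfg
#' @export
sim_config <- function(n_input = 225L,
                       n_grid = 100L,
                       arena_side = 1,
                       input_sigma = 0.054,
                       input_peak_rate = 20,
                       step_length = 0.006,
                       turn_sd = 17,
                       n_steps = 2e7,
                       beta_adapt = 0.04,
                       gain_G = 0.1,
                       recurrent_gain = 2,
                       active_fraction = 0.6,
                       epsilon_learn = 0.005,
                       delta_avg = 0.5,
                       tau_map = 0.03,
                       architecture = c("torus2d", "ring1d", "stripe1dl",
                                        "fragmented", "none"),
                       recurrent_scale = 1,
                       shuffle_recurrent = FALSE,
                       kernel_spacing = 0.6,
                       ring_sigma_deg = 7.2,
                       stripe_sigma_units = 2,
                       fragment_reps = 20L,
                       fragment_size = 10L,
                       n_px = 41L,
                       pixel_size = 0.024,
                       rec_off_at = NULL,
                       seed = NULL) {
  architecture <- match.arg(architecture)
  cfg <- list(
    n_input = as.integer(n_input), n_grid = as.integer(n_grid),
    arena_side = arena_side, input_sigma = input_sigma,
    input_peak_rate = input_peak_rate, step_length = step_length,
    turn_sd = turn_sd, n_steps = as.double(n_steps),
    beta_adapt = beta_adapt, gain_G = gain_G,
    recurrent_gain = recurrent_gain, active_fraction = active_fraction,
    epsilon_learn = epsilon_learn, delta_avg = delta_avg, tau_map = tau_map,
    architecture = architecture, recurrent_scale = recurrent_scale,
    shuffle_recurrent = isTRUE(shuffle_recurrent),
    kernel_spacing = kernel_spacing, ring_sigma_deg = ring_sigma_deg,
    stripe_sigma_units = stripe_sigma_units,
    fragment_reps = as.integer(fragment_reps),
    fragment_size = as.integer(fragment_size),
    n_px = as.integer(n_px), pixel_size = pixel_size,
    rec_off_at = rec_off_at,
    seed = if (is.null(seed)) NULL else as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(cfg$n_input >= 1, cfg$n_grid >= 2, cfg$arena_side > 0,
            cfg$input_sigma > 0, cfg$input_peak_rate > 0,
            cfg$step_length > 0, cfg$turn_sd >= 0,
            cfg$beta_adapt >= 0, cfg$beta_adapt < 1,
            cfg$gain_G > 0, cfg$recurrent_gain >= 0,
            cfg$epsilon_learn >= 0, cfg$delta_avg > 0, cfg$delta_avg <= 1,
            cfg$tau_map > 0, cfg$tau_map <= 1,
            cfg$kernel_spacing > 0, cfg$n_px >= 3, cfg$pixel_size > 0)
  if (cfg$n_steps < 1) stop("n_steps must be positive")
  if (cfg$active_fraction <= 0 || cfg$active_fraction > 1)
    stop("active_fraction must be in (0, 1]")
  if (round(sqrt(cfg$n_input))^2 != cfg$n_input)
    stop("n_input must be a perfect square (inputs sit on a uniform lattice)")
  if (cfg$arena_side <= cfg$step_length)
    stop("arena_side must exceed step_length")
  if (!is.null(cfg$rec_off_at) &&
      (cfg$rec_off_at <= 0 || cfg$rec_off_at > 1))
    stop("rec_off_at must be a fraction in (0, 1]")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Grid-cell network configuration\n")
  cat(sprintf("  architecture: %s (gain %g, scale %g%s)\n", x$architecture,
              x$recurrent_gain, x$recurrent_scale,
              if (x$shuffle_recurrent) ", shuffled" else ""))
  cat(sprintf("  cells: %d grid <- %d input | arena %g m | steps %g\n",
              x$n_grid, x$n_input, x$arena_side, x$n_steps))
  cat(sprintf("  beta %g, G %g, active %g%%, eps %g, delta %g, tau %g\n",
              x$beta_adapt, x$gain_G, 100 * x$active_fraction,
              x$epsilon_learn, x$delta_avg, x$tau_map))
  if (!is.null(x$seed)) cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Read a simulation configuration from a YAML file
#'
#' Unknown keys are rejected; keys that are absent keep their default
#' values, so an empty file yields the reference configuration.
#'
#' @param path path to a YAML file.
#' @return A [sim_config()] object.
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) stop("configuration file must contain a YAML mapping")
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(sim_config, vals)
}

#' Write a configuration to YAML
#' @param cfg a [sim_config()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
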