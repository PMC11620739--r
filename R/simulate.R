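#' Run a self-organizing grid-cell simulation
#'
#' Simulates the full training loop: random-walk trajectory, Gaussian
#' place-cell inputs, total field with normalized recurrent drive,
#' adaptation, threshold-linear transfer with an exact active fraction,
#' Hebbian feedforward learning with weight clipping and unit-ball
#' projection, and the exponential rate-map accumulator.  Transient rate
#' maps are checkpointed periodically for learning-curve analyses.
#'
#' @param config a [sim_config()].
#' @param checkpoint_every checkpoint cadence as a fraction of `n_steps`
#'   (default every 5%).
#' @param trajectory optional pre-generated [generate_trajectory()] result.
#' @return An object of class `grid_sim`: list with `config`, `W_in`,
#'   `W_rec`, `maps` (array `[n_grid, n_px, n_px]` of mean rates),
#'   `occupancy`, `checkpoints` (list of map arrays), `checkpoint_steps`
#'   and the final internal `state`.
#' @examples
#' cfg <- sim_config(architecture = "none", n_steps = 2000, seed = 1)
#' sim <- run_grid_sim(cfg)
#' sim
#' @export
run_grid_sim <- function(config, checkpoint_every = 0.05, trajectory = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  W_rec <- build_architecture(config)
  W_in <- matrix(runif(config$n_grid * config$n_input), config$n_grid)
  W_in <- W_in / sqrt(rowSums(W_in^2))
  if (is.null(trajectory)) trajectory <- generate_trajectory(config)
  n_steps <- nrow(trajectory$positions)

  cps <- unique(pmax(1, round(seq(checkpoint_every, 1, by = checkpoint_every) *
                                n_steps)))
  rec_off <- if (is.null(config$rec_off_at)) -1L else
    as.integer(round(config$rec_off_at * n_steps))
  par <- list(arena_side = config$arena_side, input_sigma = config$input_sigma,
              input_peak_rate = config$input_peak_rate,
              beta_adapt = config$beta_adapt, gain_G = config$gain_G,
              active_fraction = config$active_fraction,
              epsilon_learn = config$epsilon_learn,
              delta_avg = config$delta_avg, tau_map = config$tau_map,
              n_px = config$n_px, pixel_size = config$pixel_size,
              rec_off_step = rec_off)
  res <- cpp_simulate(W_in, W_rec, trajectory$positions, par,
                      as.integer(cps))
  out <- list(config = config, W_in = res$W_in, W_rec = W_rec,
              maps = res$maps, occupancy = res$occupancy,
              checkpoints = res$checkpoints,
              checkpoint_steps = res$checkpoint_steps,
              state = list(h_act = res$h_act, h_inact = res$h_inact,
                           r_grid = res$r_grid, r_bar_grid = res$r_bar_grid,
                           r_bar_in = res$r_bar_in))
  class(out) <- "grid_sim"
  out
}

#' @export
print.grid_sim <- function(x, ...) {
  cat(sprintf("grid_sim: %d cells, %s architecture, %g steps, %d checkpoints\n",
              x$config$n_grid, x$config$architecture, x$config$n_steps,
              length(x$checkpoints)))
  cat(sprintf("  mean map rate %.3f, max %.3f\n", mean(x$maps), max(x$maps)))
  invisible(x)
}

#' @export
summary.grid_sim <- function(object, ...) {
  sc <- population_grid_scores(object$maps, object$config$pixel_size)
  cat(sprintf("grid_sim summary (%s):\n", object$config$architecture))
  cat(sprintf("  mean individual gridness %.2f, spacing %.1f cm (n = %d scored)\n",
              mean(sc$gridness, na.rm = TRUE),
              100 * mean(sc$spacing, na.rm = TRUE),
              sum(!is.na(sc$gridness))))
  invisible(sc)
}

#' @export
plot.grid_sim <- function(x, cells = 1:4, ...) {
  op <- graphics::par(mfrow = c(2, ceiling(length(cells) / 2)),
                      mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  for (i in cells) {
    graphics::image(x$maps[i, , ], axes = FALSE, main = paste("cell", i),
                    col = grDevices::hcl.colors(64, "viridis"), ...)
  }
  invisible(x)
}
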