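# Scaled learning-trend runs for the architecture-comparison checks.
# One condition x seed: train 1e6 steps, score a subset of cells at an
# early checkpoint and at the end.  Kept deliberately small so five seeds
# of four conditions stay within a routine test run; the reference
# protocol (2e7 steps) sharpens all contrasts.
trend_run <- function(arch, seed, n_steps = 1e6, cells = 1:40) {
  cfg <- sim_config(architecture = arch, n_steps = n_steps, seed = seed)
  sim <- run_grid_sim(cfg)
  score <- function(maps) {
    sc <- population_grid_scores(maps, cells = cells)
    ok <- !sc$flagged & !is.na(sc$gridness)
    list(gridness = mean(sc$gridness[ok]),
         spacing = mean(sc$spacing[ok]),
         n_ok = sum(ok))
  }
  early <- score(sim$checkpoints[[4]])   # 20% of the run
  final <- score(sim$maps)
  spread <- compute_angular_spread(sim$maps[cells, , , drop = FALSE])
  list(arch = arch, seed = seed, early = early, final = final,
       spread = as.numeric(spread))
}

fx_trend <- function() {
  fx("trend_runs", {
    archs <- c("torus2d", "ring1d", "stripe1dl", "none")
    out <- list()
    for (arch in archs) {
      for (seed in 1:5) {
        out[[paste(arch, seed)]] <- trend_run(arch, 400 + seed)
      }
    }
    out
  })
}

trend_mean <- function(runs, arch, what) {
  vals <- vapply(runs, function(r) {
    if (r$arch != arch) return(NA_real_)
    switch(what,
           gridness = r$final$gridness,
           spread = r$spread,
           spacing = r$final$spacing,
           spacing_early = r$early$spacing,
           gridness_early = r$early$gridness)
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}
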