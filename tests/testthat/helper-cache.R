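# Shared fixtures for the test session.  The heavy objects (625-point
# population clouds and their persistence diagrams) are computed once and
# reused across test files.
.fx_env <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (!exists(name, envir = .fx_env)) {
    assign(name, force(expr), envir = .fx_env)
  }
  get(name, envir = .fx_env)
}

# the reference aligned-population fixture (2% of the kernel peak of 3)
fx_population <- function() {
  fx("population", ideal_grid_population(
    100, spacing = 0.6, phase_layout = "uniform", noise_sd = 0.06,
    seed = 101))
}

fx_population_cloud <- function() {
  fx("population_cloud", build_population_cloud(fx_population(), k = 10))
}

fx_population5_persistence <- function() {
  # the aligned population at the upper end of the tolerated noise (5% of
  # the kernel peak of 3)
  fx("population5_ps", {
    pop5 <- ideal_grid_population(100, spacing = 0.6,
                                  phase_layout = "uniform",
                                  noise_sd = 0.15, seed = 201)
    rips_persistence(build_population_cloud(pop5, k = 10),
                     max_degree = 2, field = 2)
  })
}

fx_ring_population <- function() {
  fx("ring_population", ideal_grid_population(
    100, spacing = 0.6, phase_layout = "ring", winding = c(1, 0),
    noise_sd = 0.03, seed = 102))
}

fx_torus_manifold_report <- function() {
  fx("torus_manifold_report", {
    tor <- manifold_sample("torus", 625, noise_sd = 0.02, seed = 74)
    gtor <- point_cloud(tor$points, metric = "knn_geodesic", k = 10)
    classify_surface(gtor, k_dim = 70, k1 = 50, k2 = 100)
  })
}

fx_sheet_report <- function() {
  fx("sheet_report", {
    sh <- manifold_sample("sheet", 625, noise_sd = 0.01, seed = 75)
    list(cloud = sh,
         report = classify_surface(sh, k_dim = 20, k1 = 10, k2 = 30,
                                   check_orientability = FALSE))
  })
}

fx_klein_orientability <- function() {
  # ambient Euclidean metric: the fatter tube keeps the two sheets apart
  # and its Rips diagrams separate signal from noise more cleanly than
  # the geodesic metric of the thin tube
  fx("klein_orientability", {
    kl <- manifold_sample("klein", 720, noise_sd = 0.01, seed = 72,
                          tube_radius = 0.6)
    # full enclosing radius: the default ceiling would cap the long Z3
    # 1-cycles whose deaths sit in the top fifth of the filtration
    orientability_check(kl, threshold = min(apply(kl$dist, 1, max)))
  })
}
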