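test_that("autocorrelogram of an ideal map shows the hexagonal ring", {
  km <- grid_kernel_map(spacing = 0.6)
  ac <- compute_autocorrelogram(km)
  expect_false(ac$degenerate)
  n <- nrow(ac$values)
  ctr <- (n + 1) / 2
  # zero lag attains the maximum (lattice-vector lags tie for a perfectly
  # periodic map)
  expect_equal(ac$raw[ctr, ctr], max(ac$raw), tolerance = 1e-9)
  # point symmetry about the origin
  expect_equal(ac$raw, ac$raw[n:1, n:1], tolerance = 1e-10)
  mx <- autocorr_maxima(ac)
  expect_equal(nrow(mx), 6)
  expect_equal(sort(diff(sort(mx$angle))), rep(60, 5), tolerance = 3)
})

test_that("autocorrelogram is invariant under affine rate changes", {
  set.seed(31)
  m <- pmax(grid_kernel_map(spacing = 0.45) +
              matrix(rnorm(41^2, 0, 0.2), 41), 0)
  a1 <- compute_autocorrelogram(m)
  a2 <- compute_autocorrelogram(3 * m + 2)
  expect_equal(a1$values, a2$values, tolerance = 1e-9)
})

test_that("white-noise maps give a central peak and near-zero gridness", {
  set.seed(32)
  g <- fl <- numeric(60)
  for (i in 1:60) {
    a <- compute_autocorrelogram(matrix(runif(41 * 41), 41))
    sp <- estimate_spacing(a)
    fl[i] <- attr(sp, "flagged")
    g[i] <- compute_gridness(a, sp)
    if (i == 1) {
      n <- nrow(a$raw); ctr <- (n + 1) / 2
      expect_equal(a$raw[ctr, ctr], max(a$raw))
      # well-sampled off-centre lags stay near zero
      nearby <- abs(row(a$raw) - ctr) <= 10 & abs(col(a$raw) - ctr) <= 10
      off <- a$raw[nearby & (abs(row(a$raw) - ctr) > 2 |
                               abs(col(a$raw) - ctr) > 2)]
      expect_lt(max(abs(off)), 0.3)
    }
  }
  expect_gte(mean(fl), 0.9)       # ring-free noise is flagged
  expect_lt(max(abs(g)), 0.25)    # and carries no hexagonal contrast
})

test_that("constant maps are reported as degenerate", {
  a <- compute_autocorrelogram(matrix(1, 41, 41))
  expect_true(a$degenerate)
  expect_true(attr(estimate_spacing(a), "flagged"))
  expect_true(is.na(compute_gridness(a)))
})

test_that("spacing estimator recovers design spacings and scales with them", {
  for (s in c(0.3, 0.45, 0.6)) {
    ac <- compute_autocorrelogram(grid_kernel_map(spacing = s))
    est <- as.numeric(estimate_spacing(ac))
    expect_equal(est, s, tolerance = 0.05)
  }
})

test_that("gridness separates hexagonal, square and rotated maps", {
  ac <- compute_autocorrelogram(grid_kernel_map(spacing = 0.6))
  g_hex <- compute_gridness(ac)
  expect_gt(g_hex, 1)
  # a 60-degree rotation maps the lattice onto itself: gridness invariant
  ac_rot <- compute_autocorrelogram(
    grid_kernel_map(spacing = 0.6, orientation = pi / 3))
  expect_equal(compute_gridness(ac_rot), g_hex, tolerance = 0.05)
  # a square lattice map scores low or negative
  cs <- 0.008 + (1:41 - 0.5) * 0.024
  sq <- outer(cs, cs, function(x, y) cos(2 * pi * x / 0.45) +
                                      cos(2 * pi * y / 0.45)) + 2
  g_sq <- compute_gridness(compute_autocorrelogram(sq), 0.45)
  expect_lt(g_sq, 0.3)
})

test_that("angular spread detects alignment and misalignment", {
  # identical aligned cells: spread close to zero
  pop <- ideal_grid_population(12, spacing = 0.5, phase_layout = "uniform",
                               noise_sd = 0, seed = 33)
  sp0 <- compute_angular_spread(pop)
  expect_lt(sp0, 5)
  # orientation jitter increases the spread monotonically
  jitter_pop <- function(sd_deg, seed) {
    set.seed(seed)
    maps <- array(0, c(20, 41, 41))
    for (c in 1:20) {
      maps[c, , ] <- grid_kernel_map(
        spacing = 0.5, orientation = rnorm(1, 0, sd_deg * pi / 180),
        phase = runif(2, 0, 0.4))
    }
    maps
  }
  s1 <- compute_angular_spread(jitter_pop(2, 34))
  s2 <- compute_angular_spread(jitter_pop(15, 34))
  expect_gt(s2, s1)
  # two sub-populations offset by 30 degrees: large spread
  maps <- array(0, c(12, 41, 41))
  for (c in 1:6) maps[c, , ] <- grid_kernel_map(spacing = 0.5)
  for (c in 7:12) maps[c, , ] <- grid_kernel_map(spacing = 0.5,
                                                 orientation = pi / 6)
  expect_gt(compute_angular_spread(maps), 8)
})

test_that("population autocorrelogram averages per-cell autocorrelograms", {
  pop <- ideal_grid_population(5, spacing = 0.5, phase_layout = "uniform",
                               noise_sd = 0.05, seed = 35)
  pac <- population_autocorrelogram(pop)
  acc <- 0
  for (i in 1:5) acc <- acc + compute_autocorrelogram(pop[i, , ])$values
  expect_equal(pac$values, acc / 5)
  # a single-cell stack equals the individual autocorrelogram
  one <- pop[1, , , drop = FALSE]
  expect_equal(population_autocorrelogram(one)$values,
               compute_autocorrelogram(pop[1, , ])$values)
  # aligned population keeps a hexagonal mean; random orientations blur it
  g_aligned <- compute_gridness(pac)
  set.seed(36)
  rnd <- array(0, c(8, 41, 41))
  for (c in 1:8) rnd[c, , ] <- grid_kernel_map(
    spacing = 0.5, orientation = runif(1, 0, pi / 3),
    phase = runif(2, 0, 0.4))
  pac_r <- population_autocorrelogram(rnd)
  g_rand <- compute_gridness(pac_r, 0.5)
  expect_gt(g_aligned, 0.8)
  expect_lt(g_rand, g_aligned / 2)
})
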