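cfg_small <- sim_config(n_steps = 1000, seed = 1)

test_that("input tuning curves have the specified Gaussian profile", {
  ctr <- input_centers(cfg_small)
  expect_equal(nrow(ctr), 225)
  # at a centre the cell fires at the peak rate
  r <- input_rates(ctr[113, ], cfg_small)
  expect_equal(max(r), 20)
  expect_equal(which.max(r), 113L)
  # one sigma away along x the same cell fires peak * exp(-1/2)
  p <- ctr[113, ] + c(cfg_small$input_sigma, 0)
  expect_equal(input_rates(p, cfg_small)[113], 20 * exp(-0.5))
  # brute-force evaluation: total drive at the centre beats a corner
  s_mid <- sum(input_rates(c(0.5, 0.5), cfg_small))
  s_corner <- sum(input_rates(c(0.01, 0.01), cfg_small))
  expect_gt(s_mid, s_corner)
})

test_that("compute_fields equals an explicit double-loop evaluation", {
  set.seed(2)
  st <- network_state(cfg_small)
  st$r_grid <- runif(100, 0, 0.3)
  r_in <- runif(225, 0, 20)
  h <- compute_fields(st, r_in, cfg_small)
  h_loop <- numeric(100)
  for (i in 1:100) {
    for (j in 1:225) h_loop[i] <- h_loop[i] + st$W_in[i, j] * r_in[j]
    rec <- 0
    for (k in 1:100) rec <- rec + st$W_rec[i, k] * st$r_grid[k]
    h_loop[i] <- h_loop[i] + rec / mean(st$r_grid)
  }
  expect_equal(h, h_loop)
  # zero recurrent matrix leaves a purely feedforward field
  st$W_rec <- matrix(0, 100, 100)
  expect_equal(compute_fields(st, r_in, cfg_small),
               drop(st$W_in %*% r_in))
  # all rates zero: no recurrent contribution and zero field for zero input
  st$r_grid <- numeric(100)
  expect_equal(compute_fields(st, numeric(225), cfg_small), numeric(100))
  expect_error(compute_fields(st, numeric(10), cfg_small), "length")
})

test_that("adaptation relaxes a sustained field and freezes when beta = 0", {
  st <- network_state(cfg_small)
  h <- runif(100, 0, 5)
  # one step from zero internal state reproduces the field
  st1 <- adaptation_step(st, h, cfg_small)
  expect_equal(st1$h_act, h)
  # iterating a constant field drives h_act to zero, h_inact to h
  st_i <- st
  for (t in 1:10000) st_i <- adaptation_step(st_i, h, cfg_small)
  expect_lt(max(abs(st_i$h_act)), 1e-8)
  expect_equal(st_i$h_inact, h, tolerance = 1e-8)
  # with beta = 0 the inactivation variable never moves
  cfg0 <- sim_config(beta_adapt = 0)
  st0 <- adaptation_step(network_state(cfg0), h, cfg0)
  st0 <- adaptation_step(st0, h * 2, cfg0)
  expect_equal(st0$h_inact, numeric(100))
  expect_equal(st0$h_act, h * 2)
})

test_that("transfer activates exactly the configured fraction", {
  set.seed(3)
  h_act <- rnorm(100)
  r <- apply_transfer(h_act, cfg_small)
  expect_equal(sum(r > 0), 60)
  expect_equal(mean(r), cfg_small$gain_G)  # normalisation identity
  expect_true(all(r >= 0))
  # the active set is the top of the h_act order
  expect_setequal(which(r > 0), order(-h_act)[1:60])
  # uniform scaling of the drive leaves the rates unchanged
  expect_equal(apply_transfer(2 * h_act, cfg_small), r)
  expect_equal(apply_transfer(h_act + 5, cfg_small), r)
  # degenerate all-equal drive produces silence
  expect_equal(apply_transfer(rep(1, 100), cfg_small), numeric(100))
})

test_that("Hebbian updates behave at stationarity and preserve invariants", {
  set.seed(4)
  st <- network_state(cfg_small)
  # r == rbar everywhere gives zero net update (rows are already unit
  # norm, so the normalization is a no-op)
  r_in <- runif(225, 0, 2)
  r_g <- runif(100, 0, 0.3)
  st$r_bar_in <- r_in
  st$r_bar_grid <- r_g
  W0 <- st$W_in
  st2 <- hebbian_update(st, r_in, r_g, cfg_small)
  expect_equal(st2$W_in, W0)
  # a single active pre/post pair with zero averages grows only that
  # weight; the row is then renormalized onto the unit sphere
  st$W_in <- matrix(0.01, 100, 225)
  st$r_bar_in <- numeric(225)
  st$r_bar_grid <- numeric(100)
  r_in1 <- numeric(225); r_in1[7] <- 3
  r_g1 <- numeric(100); r_g1[2] <- 0.5
  st3 <- hebbian_update(st, r_in1, r_g1, cfg_small)
  raw <- matrix(0.01, 100, 225)
  raw[2, 7] <- 0.01 + cfg_small$epsilon_learn * 3 * 0.5
  expected <- raw / sqrt(rowSums(raw^2))
  expect_equal(st3$W_in, expected)
  # invariant sweep: nonnegativity and unit-ball rows across random steps
  st <- network_state(cfg_small)
  for (t in 1:100) {
    r_in <- runif(225, 0, 20)
    r_g <- apply_transfer(rnorm(100), cfg_small)
    st <- hebbian_update(st, r_in, r_g, cfg_small)
    expect_true(all(st$W_in >= 0))
    expect_true(all(sqrt(rowSums(st$W_in^2)) <= 1 + 1e-12))
  }
})

test_that("rate-map accumulator updates only the traversed pixel", {
  maps <- array(0, c(3, 41, 41))
  r <- c(10, 0, 2)
  m1 <- update_rate_maps(maps, c(0.5, 0.5), r, cfg_small)
  expect_equal(m1[1, 21, 21], 10 * 0.03)
  expect_equal(m1[3, 21, 21], 2 * 0.03)
  expect_equal(sum(m1 != 0), 2)
  # repeated visits converge to the constant rate
  m <- maps
  for (t in 1:600) m <- update_rate_maps(m, c(0.5, 0.5), r, cfg_small)
  expect_equal(m[1, 21, 21], 10, tolerance = 1e-6)
  # a random visit sequence matches a per-pixel exponential-average replay
  set.seed(5)
  m <- maps
  ref <- array(0, c(3, 41, 41))
  for (t in 1:200) {
    pos <- runif(2, 0.1, 0.9)
    rr <- runif(3)
    m <- update_rate_maps(m, pos, rr, cfg_small)
    px <- 1 + floor((pos - 0.008) / 0.024)
    ref[, px[1], px[2]] <- ref[, px[1], px[2]] * 0.97 + rr * 0.03
  }
  expect_equal(m, ref)
})

test_that("trajectories respect step length, turning noise and the arena", {
  set.seed(6)
  tr <- generate_trajectory(cfg_small, 1e5)
  stp <- diff(tr$positions)
  expect_equal(sqrt(rowSums(stp^2)), rep(0.006, nrow(stp)), tolerance = 1e-9)
  expect_true(all(tr$positions >= 0 & tr$positions <= 1))
  # empirical s.d. of the turn increments (away from boundary redraws)
  inner <- rowSums(tr$positions > 0.1 & tr$positions < 0.9) == 2
  dh <- diff(tr$headings)
  dh <- (dh + pi) %% (2 * pi) - pi
  dh <- dh[inner[-1] & inner[-length(inner)]]
  expect_equal(sd(dh) * 180 / pi, 17, tolerance = 0.02)
  # reproducibility under a fixed seed
  set.seed(6)
  tr2 <- generate_trajectory(cfg_small, 1e5)
  expect_identical(tr$positions, tr2$positions)
  # zero turning noise: straight path until the boundary rule engages
  set.seed(7)
  cfg0 <- sim_config(turn_sd = 0)
  tr0 <- generate_trajectory(cfg0, 50)
  d2 <- diff(tr0$positions)
  expect_equal(sd(atan2(d2[1:20, 2], d2[1:20, 1])), 0, tolerance = 1e-12)
  expect_error(generate_trajectory(cfg_small, 0), "positive")
})
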