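cfg <- sim_config(seed = 1)

test_that("toroidal kernel is the three-cosine ideal grid", {
  W <- build_torus_architecture(cfg)
  expect_equal(diag(W), rep(3, 100))  # f(0) = 1 + (2/3) * 3
  expect_true(all(W >= -1e-12))
  expect_equal(W, t(W))
  # the kernel map built with the same wave vectors has a 60 cm ring
  ac <- compute_autocorrelogram(grid_kernel_map(spacing = 0.6))
  mx <- autocorr_maxima(ac)
  expect_equal(nrow(mx), 6)
  # peak detection on the windowed surface sits within ~2 pixels of the
  # design ring
  expect_lt(max(abs(mx$radius - 0.6)), 0.06)
  a <- sort(mx$angle)
  expect_equal(diff(a), rep(60, 5), tolerance = 3)
})

test_that("ring kernel is a circulant Gaussian of the minimum angle", {
  W <- build_ring_architecture(cfg)
  expect_equal(W, t(W))
  # nearest neighbours (3.6 deg apart) at the prescribed Gaussian value
  expect_equal(W[1, 2], exp(-(3.6 / 7.2)^2 / 2))
  # antipodal pair essentially disconnected
  expect_lt(W[1, 51], 1e-100)
  # every row is a cyclic shift of the first
  for (i in c(2, 17, 60)) {
    expect_equal(W[i, c(i:100, seq_len(i - 1))], W[1, ], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("stripe kernel is Toeplitz with depleted extremes", {
  W <- build_stripe_architecture(cfg)
  expect_equal(W, t(W))
  # boundary truncation: an end neuron collects less total input
  expect_lt(sum(W[1, ]) , sum(W[50, ]))
  # Toeplitz structure away from the boundary
  expect_equal(W[20, 25], W[40, 45])
  expect_equal(W[30, 33], W[60, 63])
})

test_that("fragmented kernel overlays short stripe attractors", {
  set.seed(11)
  W <- build_fragmented_architecture(cfg)
  expect_equal(W, t(W))
  # one fragment spanning all cells reduces to a stripe over a permutation
  cfg1 <- sim_config(architecture = "fragmented", fragment_reps = 1,
                     fragment_size = 100)
  set.seed(12)
  perm <- sample(100, 100)  # replay the single draw
  set.seed(12)
  W1 <- build_fragmented_architecture(cfg1)
  Ws <- build_stripe_architecture(cfg1)
  expect_equal(W1[perm, perm], Ws, ignore_attr = TRUE)
  # connectivity grows with the number of fragments
  set.seed(13)
  cfg5 <- sim_config(fragment_reps = 5)
  cfg40 <- sim_config(fragment_reps = 40)
  deg5 <- mean(build_fragmented_architecture(cfg5) > 1e-3)
  deg40 <- mean(build_fragmented_architecture(cfg40) > 1e-3)
  expect_gt(deg40, deg5)
})

test_that("assembled recurrent matrix is normalized, hollow and scalable", {
  for (arch in c("torus2d", "ring1d", "stripe1dl", "fragmented")) {
    cfgx <- sim_config(architecture = arch, seed = 2)
    set.seed(2)
    W <- build_architecture(cfgx)
    expect_equal(diag(W), rep(0, 100))
    rs <- rowSums(W)
    # cells left out of every fragment keep an empty row; all connected
    # rows are normalized to the recurrent gain
    expect_true(all(abs(rs - cfgx$recurrent_gain) < 1e-9 | rs == 0))
    expect_gt(mean(rs > 0), 0.8)
  }
  expect_equal(build_architecture(sim_config(architecture = "none")),
               matrix(0, 100, 100))
  # recurrent_scale multiplies on top
  cfgs <- sim_config(recurrent_scale = 5)
  set.seed(3)
  expect_equal(rowSums(build_architecture(cfgs)), rep(10, 100))
  # shuffling preserves each row's weight multiset
  cfgsh <- sim_config(architecture = "ring1d", shuffle_recurrent = TRUE)
  set.seed(4)
  Wsh <- build_architecture(cfgsh)
  Wref <- build_architecture(sim_config(architecture = "ring1d"))
  for (i in c(1, 42)) {
    expect_equal(sort(Wsh[i, -i]), sort(Wref[i, -i]))
  }
  expect_false(isTRUE(all.equal(Wsh, Wref)))
})
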