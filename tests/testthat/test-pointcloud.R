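test_that("kNN geodesic distances behave like intrinsic distances", {
  # evenly spaced points on a line with k = 2: geodesic equals Euclidean
  x <- cbind(seq(0, 1, length.out = 40) + 0.001 * sin(1:40), 0)
  G <- knn_geodesic_distance(x, 2)
  expect_equal(G, as.matrix(dist(x)), tolerance = 1e-12,
               ignore_attr = TRUE)
  # dense circle: geodesic between antipodes approximates the arc length
  set.seed(41)
  th <- sort(runif(200, 0, 2 * pi))
  circ <- cbind(cos(th), sin(th))
  G <- knn_geodesic_distance(circ, 10)
  i <- 1
  j <- which.min(abs(th - (th[1] + pi)))
  expect_gt(G[i, j], 2.5)            # chord would be about 2
  expect_equal(G[i, j], pi, tolerance = 0.2)
  # geodesic dominates Euclidean pointwise
  E <- as.matrix(dist(circ))
  expect_true(all(G >= E - 1e-9))
  # triangle inequality on a random sample
  set.seed(42)
  pts <- matrix(rnorm(50 * 3), 50)
  G <- knn_geodesic_distance(pts, 6)
  for (a in 1:10) for (b in 11:20) for (c in 21:30) {
    expect_lte(G[a, b], G[a, c] + G[c, b] + 1e-9)
  }
})

test_that("disconnected kNN graphs raise an informative error", {
  two <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 100), 10))
  expect_error(knn_geodesic_distance(two, 3), "component sizes")
})

test_that("correlation distance has the documented extremes", {
  a <- runif(30)
  pts <- rbind(a, a, 1 - a + 0.001 * runif(30))
  D <- correlation_distance(pts)
  expect_equal(D[1, 2], 0)
  expect_equal(D[1, 3], 2, tolerance = 0.01)
  expect_error(correlation_distance(rbind(a, rep(1, 30))), "constant")
})

test_that("population and neuron clouds are transposes of one matrix", {
  pop <- fx_population()
  M <- population_matrix(pop)
  expect_equal(dim(M), c(100, 625))
  pc <- build_population_cloud(pop)
  nc <- build_neuron_cloud(pop)
  expect_equal(dim(pc$points), c(625, 100))
  expect_equal(dim(nc$points), c(100, 625))
  expect_equal(t(pc$points), nc$points, ignore_attr = TRUE)
  # permuting neurons permutes coordinates but not pairwise distances
  perm <- sample(100)
  pc2 <- point_cloud(pc$points[, perm], metric = "knn_geodesic", k = 10)
  expect_equal(pc2$dist, pc$dist, tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(build_population_cloud(array(0, c(4, 41, 41))), "degenerate")
})
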