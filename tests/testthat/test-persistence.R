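test_that("engine agrees with brute-force reduction on random clouds", {
  set.seed(51)
  for (rep in 1:6) {
    n <- sample(6:11, 1)
    pts <- matrix(rnorm(n * sample(2:4, 1)), n)
    D <- as.matrix(dist(pts))
    thr <- min(apply(D, 1, max))  # same ceiling for engine and oracle
    for (p in c(2, 3)) {
      res <- rips_persistence(D, max_degree = 2, field = p, threshold = thr)
      orc <- brute_persistence(D, 2, p, threshold = thr)
      for (d in 0:2) {
        a <- finite_pairs(res, d)
        b <- oracle_pairs(orc, d)
        expect_equal(nrow(a), nrow(b),
                     label = sprintf("rep %d p %d dim %d count", rep, p, d))
        if (nrow(a)) expect_equal(a, b, tolerance = 1e-12,
                                  ignore_attr = TRUE)
      }
      # essential classes: one surviving component, nothing above
      expect_equal(sum(res$pairs$essential), orc[[1]]$n_essential)
    }
  }
})

test_that("engine agrees with the oracle on tie-rich graph metrics", {
  # shortest-path metrics have structured ties (a triangle's diameter
  # always equals its longest edge, path sums repeat)
  for (n in c(10, 12)) {
    D <- outer(1:n, 1:n, function(i, j) pmin(abs(i - j), n - abs(i - j))) * 0.5
    thr <- min(apply(D, 1, max))
    for (p in c(2, 3)) {
      res <- rips_persistence(D, max_degree = 2, field = p, threshold = thr)
      orc <- brute_persistence(D, 2, p, threshold = thr)
      for (d in 0:2) {
        expect_equal(finite_pairs(res, d), oracle_pairs(orc, d),
                     tolerance = 1e-12, ignore_attr = TRUE)
      }
    }
  }
})

test_that("diagrams are invariant under permutation and isometry", {
  set.seed(52)
  pts <- matrix(rnorm(40 * 3), 40)
  ps1 <- rips_persistence(pts, max_degree = 1)
  # random rotation + translation + relabelling
  qr_ <- qr.Q(qr(matrix(rnorm(9), 3)))
  pts2 <- (pts %*% qr_) [sample(40), ] + 5
  ps2 <- rips_persistence(pts2, max_degree = 1)
  for (d in 0:1) {
    expect_equal(finite_pairs(ps1, d), finite_pairs(ps2, d),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("known homologies are recovered: point, circle, torus", {
  # a single point: one essential component only
  one <- rips_persistence(matrix(0, 1, 1), max_degree = 1)
  expect_equal(unname(count_betti(one, c(0, 0))), c(1, 0))
  # a noisy circle: one dominant 1-cycle
  set.seed(53)
  th <- runif(300, 0, 2 * pi)
  circ <- cbind(cos(th), sin(th)) + matrix(rnorm(600, 0, 0.01), ncol = 2)
  ps <- rips_persistence(circ, max_degree = 1)
  co <- flexattractor:::diagram_cutoffs(ps)
  expect_equal(unname(count_betti(ps, co)[1:2]), c(1, 1))
  # a flat-torus sample (ambient Euclidean metric; at this moderate n the
  # kNN-geodesic noise cycles blur the cutoff, cf. the denser geodesic
  # fixture in the surface tests): betti (1, 2, 1)
  tor <- manifold_sample("torus", 400, noise_sd = 0.02, seed = 54)
  pst <- rips_persistence(tor, max_degree = 2)
  cot <- flexattractor:::diagram_cutoffs(pst)
  expect_equal(unname(count_betti(pst, cot)), c(1, 2, 1))
})

test_that("H0 essential bar gets a display lifetime above the diagram", {
  set.seed(55)
  pts <- matrix(rnorm(60 * 2), 60)
  ps <- rips_persistence(pts, max_degree = 1)
  ess <- ps$pairs[ps$pairs$essential, ]
  expect_equal(nrow(ess), 1)
  fin <- ps$pairs$lifetime[!ps$pairs$essential]
  expect_equal(ess$lifetime, 1.2 * max(fin))
})

test_that("automated lifetime cutoff lands in a bimodal gap", {
  set.seed(56)
  lt <- c(runif(300, 0, 0.1), runif(12, 0.8, 1))
  co <- lifetime_cutoff(lt)
  expect_false(attr(co, "flagged"))
  expect_gt(co, 0.1)
  expect_lt(co, 0.8)
  # invariance under pool duplication
  co2 <- lifetime_cutoff(rep(lt, 2))
  expect_equal(as.numeric(co), as.numeric(co2), tolerance = 1e-9)
  # degenerate all-equal pool is flagged
  expect_true(attr(lifetime_cutoff(rep(0.5, 40)), "flagged"))
})

test_that("betti counting respects per-degree cutoffs", {
  set.seed(57)
  th <- runif(200, 0, 2 * pi)
  circ <- cbind(cos(th), sin(th)) + matrix(rnorm(400, 0, 0.02), ncol = 2)
  ps <- rips_persistence(circ, max_degree = 1)
  # an absurdly high cutoff removes everything
  expect_equal(unname(count_betti(ps, c(1e6, 1e6))), c(0, 0))
  # a negative cutoff counts every generator
  expect_equal(sum(unname(count_betti(ps, c(-1, -1)))), nrow(ps$pairs))
})
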