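test_that("grid geometry: link distances are metric-like and local", {
  g <- som_grid(4, 5)
  expect_equal(dim(g$linkdist), c(20, 20))
  expect_true(all(diag(g$linkdist) == 0))
  expect_identical(g$linkdist, t(g$linkdist))
  expect_true(all(g$linkdist[g$linkdist > 0] >= 1))

  r <- som_grid(3, 3, topology = "rectangular")
  # corner to opposite corner: 4 orthogonal hops
  expect_equal(r$linkdist[1, 9], 4)
})

test_that("BMU matches an exhaustive distance scan and breaks ties low", {
  m <- som_fit(matrix(rnorm(40), 20, 2), som_grid(3, 3), iterations = 10,
               seed = 2)
  X <- withr::with_seed(4, matrix(rnorm(30), 15, 2))
  got <- som_predict(m, X)
  want <- apply(X, 1, function(x)
    which.min(sqrt(colSums((t(m$weights) - x)^2))))
  expect_identical(got, unname(want))

  # exact-match and tie cases on a hand-built model
  tie <- m
  tie$weights <- matrix(c(0, 0,  1, 0,  1, 0,  5, 5, 0, 0, 0, 0, 0, 0, 0, 0,
                          0, 0), 9, 2, byrow = TRUE)
  expect_equal(som_predict(tie, matrix(c(1, 0), 1)), 2)   # ties 2 vs 3 -> 2
  expect_equal(som_predict(tie, matrix(c(5, 5), 1)), 4)
  expect_error(som_predict(m, matrix(0, 1, 3)), "dimension mismatch")
})

test_that("batch training: one neuron averages, radius zero is Lloyd", {
  X <- withr::with_seed(1, matrix(rnorm(24), 12, 2))
  one <- som_fit(X, som_grid(1, 1), iterations = 1, seed = 1)
  expect_equal(as.numeric(one$weights), colMeans(X), tolerance = 1e-12)

  # radius pinned at zero: each epoch must equal one Lloyd step
  g <- som_grid(2, 2)
  m0 <- som_fit(X, g, iterations = 1, neighborhood0 = 0, radius_floor = 0,
                seed = 7)
  W0 <- matrix(withr::with_seed(7, runif(4 * 2, 0, 0.01)), 4, 2)
  Xc <- X[do.call(order, as.data.frame(X)), ]
  expect_equal(unname(m0$weights), unname(lloyd_step(W0, Xc)),
               tolerance = 1e-12)
})

test_that("batch training is exactly invariant to row permutation", {
  X <- withr::with_seed(12, matrix(rnorm(92), 46, 2))
  m1 <- som_fit(X, som_grid(6, 6), iterations = 50, seed = 3)
  perm <- withr::with_seed(99, sample.int(46))
  m2 <- som_fit(X[perm, ], som_grid(6, 6), iterations = 50, seed = 3)
  expect_identical(m1$weights, m2$weights)
})

test_that("batch weights stay in the convex hull of data and init", {
  X <- withr::with_seed(5, matrix(rnorm(60, 10, 2), 30, 2))
  m <- som_fit(X, som_grid(4, 4), iterations = 40, seed = 5)
  for (j in 1:2) {
    lo <- min(X[, j], 0); hi <- max(X[, j], 0.01)
    expect_true(all(m$weights[, j] >= lo - 1e-12 &
                      m$weights[, j] <= hi + 1e-12))
  }
})

test_that("quantization error is monotone for Lloyd and settles at radius 1", {
  X <- withr::with_seed(31, matrix(rnorm(80), 40, 2))

  # radius 0 is exactly Lloyd: QE can never increase
  lloyd <- som_fit(X, som_grid(4, 4), iterations = 100, neighborhood0 = 0,
                   radius_floor = 0, seed = 31)
  expect_true(all(diff(lloyd$qe) <= 1e-12))

  # the default radius-1 floor settles into a bounded fixed point or
  # short limit cycle: no upward drift and eventual periodicity
  m <- som_fit(X, som_grid(4, 4), iterations = 200, seed = 31)
  floor_phase <- m$qe[101:200]
  expect_lte(max(m$qe[191:200]), max(floor_phase[1:10]) + 1e-9)
  expect_lt(abs(m$qe[200] - m$qe[198]), 1e-9)
  expect_lt(abs(m$qe[199] - m$qe[197]), 1e-9)
})

test_that("sequential rule follows the learning-rate recursion", {
  x1 <- matrix(2.5, 1, 1)
  m <- som_fit(x1, som_grid(1, 1), iterations = 5, method = "sequential",
               mu0 = 1, mu_floor = 1, seed = 2)
  expect_equal(as.numeric(m$weights), 2.5)   # mu = 1 copies the sample

  w0 <- withr::with_seed(4, runif(1, 0, 0.01))
  mh <- som_fit(matrix(0, 1, 1), som_grid(1, 1), iterations = 10,
                method = "sequential", mu0 = 0.5, mu_floor = 0.5, seed = 4)
  expect_equal(as.numeric(mh$weights), w0 * 0.5^10, tolerance = 1e-12)

  expect_error(som_fit(x1, som_grid(1, 1), method = "sequential", mu0 = 0),
               "mu0")
})

test_that("hit counts tally BMUs and sum to the sample count", {
  X <- withr::with_seed(2, matrix(rnorm(50), 25, 2))
  m <- som_fit(X, som_grid(3, 3), iterations = 30, seed = 2)
  h <- som_hits(m, X)
  expect_equal(sum(h$hits), 25)
  expect_identical(h$hits, tabulate(som_predict(m, X), 9))
  h1 <- som_hits(m, X[1, , drop = FALSE])
  expect_equal(sum(h1$hits), 1)
})

test_that("U-matrix reflects weight-space discontinuities", {
  g <- som_grid(2, 2, topology = "rectangular")
  m <- som_fit(matrix(rnorm(20), 10, 2), g, iterations = 5, seed = 1)
  m$weights <- matrix(0, 4, 2)
  expect_true(all(som_umatrix(m)$distance == 0))

  m$weights[4, ] <- c(3, 4)       # one deviant neuron (dist 5 to others)
  u <- som_umatrix(m)
  # neuron 4's neighbors are 2 and 3; each has neighbors {itself's two}
  expect_equal(u$distance[4], 5)
  expect_equal(u$distance[1], 0)
  expect_equal(u$distance[2], 2.5)
  expect_true(all(u$distance >= 0))
})

test_that("weight planes mirror the input features", {
  X <- withr::with_seed(8, matrix(rnorm(60), 30, 2))
  X2 <- cbind(X, X[, 2])          # duplicated feature
  colnames(X2) <- c("a", "b", "b_copy")
  m <- som_fit(X2, som_grid(4, 4), iterations = 60, seed = 8)
  wp <- som_weight_planes(m)
  expect_equal(dplyr::n_distinct(wp$feature), 3)
  wide <- tidyr::pivot_wider(wp, names_from = "feature",
                             values_from = "weight")
  expect_gt(cor(wide$b, wide$b_copy), 0.99)
  expect_identical(wp$weight[wp$feature == "a"], unname(m$weights[, "a"]))
})

test_that("JSON serialization round-trips the model", {
  path <- withr::local_tempfile(fileext = ".json")
  m <- som_fit(matrix(rnorm(40), 20, 2), som_grid(3, 3), iterations = 20,
               seed = 6)
  som_to_json(m, path)
  back <- som_from_json(path)
  expect_equal(back$weights, m$weights, tolerance = 1e-12)
  expect_equal(back$grid$linkdist, m$grid$linkdist)
  Xnew <- withr::with_seed(61, matrix(rnorm(10), 5, 2))
  expect_identical(som_predict(back, Xnew), som_predict(m, Xnew))
})
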