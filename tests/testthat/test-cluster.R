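test_that("active prototypes partition the mapped data", {
  X <- withr::with_seed(13, matrix(rnorm(92), 46, 2))
  m <- som_fit(X, som_grid(6, 6), iterations = 80, seed = 13)
  pr <- active_prototypes(m, X)
  expect_equal(sum(lengths(pr$members)), 46)
  expect_true(all(lengths(pr$members) >= 1))
  # member lists are disjoint and cover every row
  expect_setequal(unlist(pr$members), 1:46)
  # each prototype is the centroid of its members
  for (i in seq_along(pr$members))
    expect_equal(as.numeric(pr$centers[i, ]),
                 colMeans(X[pr$members[[i]], , drop = FALSE]))
  # singleton prototypes coincide with their sample
  singles <- which(lengths(pr$members) == 1)
  if (length(singles))
    expect_equal(as.numeric(pr$centers[singles[1], ]),
                 as.numeric(X[pr$members[[singles[1]]][1], ]))
})

test_that("a one-neuron map collapses to the data mean prototype", {
  X <- withr::with_seed(14, matrix(rnorm(20), 10, 2))
  m <- som_fit(X, som_grid(1, 1), iterations = 3, seed = 1)
  pr <- active_prototypes(m, X)
  expect_equal(nrow(pr$centers), 1)
  expect_equal(as.numeric(pr$centers[1, ]), colMeans(X))
})

test_that("k-means finds the exhaustive-best two-blob partition", {
  X <- make_blobs(n_per = 4, gap = 12, sd = 0.4, seed = 21)
  km <- kmeans_pp(X, 2, seed = 1, restarts = 5)

  # exhaustive scan over all 2-partitions
  best <- Inf
  for (mask in 1:(2^8 - 2)) {
    grp <- as.logical(bitwAnd(mask, 2^(0:7)))
    if (!any(grp) || all(grp)) next
    w <- 0
    for (g in list(X[grp, , drop = FALSE], X[!grp, , drop = FALSE]))
      w <- w + sum(sweep(g, 2, colMeans(g))^2)
    best <- min(best, w)
  }
  expect_equal(km$wcss, best, tolerance = 1e-9)
  expect_equal(length(unique(km$cluster[1:4])), 1)
  expect_equal(length(unique(km$cluster[5:8])), 1)
})

test_that("k-means degenerate counts behave and WCSS is monotone", {
  X <- withr::with_seed(22, matrix(rnorm(30), 15, 2))
  all_own <- kmeans_pp(X, 15, seed = 2)
  expect_equal(all_own$wcss, 0, tolerance = 1e-12)

  one <- kmeans_pp(X, 1, seed = 2)
  expect_equal(as.numeric(one$centers), colMeans(X))

  expect_error(kmeans_pp(X, 16, seed = 1), "exceed")

  for (s in 1:5) {
    km <- kmeans_pp(X, 4, seed = s)
    expect_true(all(diff(km$wcss_trace) <= 1e-12))
  }
})

test_that("k-means solutions are locally optimal and match stats::kmeans", {
  X <- make_blobs(n_per = 8, gap = 8, sd = 1, seed = 30)
  km <- kmeans_pp(X, 3, seed = 3, restarts = 10)

  # no single-point reassignment lowers the WCSS
  wcss_of <- function(cl) {
    sum(vapply(unique(cl), function(c) {
      M <- X[cl == c, , drop = FALSE]
      sum(sweep(M, 2, colMeans(M))^2)
    }, numeric(1)))
  }
  base <- wcss_of(km$cluster)
  for (i in seq_len(nrow(X))) for (c in 1:3) {
    cl2 <- km$cluster
    if (cl2[i] == c || sum(cl2 == cl2[i]) == 1) next
    cl2[i] <- c
    expect_gte(wcss_of(cl2), base - 1e-9)
  }

  ref <- stats::kmeans(X, 3, nstart = 20)
  expect_equal(km$wcss, ref$tot.withinss, tolerance = 1e-6)
})

test_that("Davies-Bouldin equals the direct-formula oracle", {
  pts <- rbind(c(0, 0), c(0, 2), c(10, 0), c(10, 2))
  expect_equal(davies_bouldin(pts, c(1, 1, 2, 2)), 0.2, tolerance = 1e-12)
  expect_equal(davies_bouldin(rbind(c(0, 0), c(5, 5)), c(1, 2)), 0)
  expect_equal(davies_bouldin(3.7 * pts, c(1, 1, 2, 2)), 0.2,
               tolerance = 1e-12)

  for (case in 1:20) {
    n <- withr::with_seed(case, sample(6:20, 1))
    X <- withr::with_seed(case + 100, matrix(rnorm(2 * n), n, 2))
    k <- withr::with_seed(case + 200, sample(2:4, 1))
    cl <- withr::with_seed(case + 300,
                           c(1:k, sample(1:k, n - k, replace = TRUE)))
    expect_equal(davies_bouldin(X, cl), db_oracle(X, cl),
                 tolerance = 1e-12, info = paste("case", case))
  }

  expect_error(davies_bouldin(pts, c(1, 1, 1, 1)), "at least 2")
  dup <- rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1))
  expect_error(davies_bouldin(dup, c(1, 2, 1, 2)), "degenerate")
})

test_that("the DB scan bottoms out at the true blob count", {
  X <- make_blobs(n_per = 10, gap = 15, sd = 0.5, seed = 40)
  scan <- db_scan(X, k_range = 2:8, reps = 2, restarts = 5, seed = 1)
  expect_equal(scan$curve$k[which.min(scan$curve$mean_db)], 2)
  expect_true(2 %in% scan$minima)

  again <- db_scan(X, k_range = 2:8, reps = 2, restarts = 5, seed = 1)
  expect_identical(scan$curve, again$curve)

  expect_warning(clipped <- db_scan(X[1:6, ], k_range = 2:30, seed = 1),
                 "clipping")
  expect_lte(max(clipped$curve$k), 5)
})

test_that("K selection takes the highest-F minimum, ties to smaller K", {
  scan <- structure(list(
    curve = tibble::tibble(k = c(2, 4, 9, 15), mean_db = c(0.5, 0.4, 0.45, 0.6)),
    minima = c(2, 4, 9), reps = 1, seed = 1), class = "db_scan")
  expect_equal(choose_k(scan, c(`2` = 0.717, `4` = 0.448, `9` = 0.249)), 2)
  expect_equal(choose_k(scan, tibble::tibble(k = c(2, 4, 9),
                                             f = c(0.3, 0.9, 0.2))), 4)
  expect_equal(choose_k(scan, c(`2` = 0.5, `4` = 0.5, `9` = 0.2)), 2)
  single <- structure(list(curve = tibble::tibble(k = 3, mean_db = 1),
                           minima = 3, reps = 1, seed = 1),
                      class = "db_scan")
  expect_equal(choose_k(single, c(`3` = 0.4)), 3)
})

test_that("cluster propagation conserves membership", {
  X <- withr::with_seed(50, matrix(rnorm(20), 10, 2))
  m <- som_fit(X, som_grid(4, 4), iterations = 40, seed = 50)
  pr <- active_prototypes(m, X)
  cl <- rep_len(1:2, length(pr$members))
  assign <- propagate_clusters(pr, cl)
  expect_length(assign, 10)
  # manual join
  for (i in seq_along(pr$members))
    expect_true(all(assign[pr$members[[i]]] == cl[i]))
  expect_equal(sum(table(assign)), 10)

  # singleton prototypes give the identity mapping
  ids <- structure(list(centers = X, neuron = 1:10,
                        members = as.list(1:10), n_data = 10),
                   class = "sway_prototypes")
  expect_equal(propagate_clusters(ids, 1:10), 1:10)
})
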