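#' Self-organizing map grid
#'
#' Defines the neuron layout of a Kohonen map: a `rows` x `cols` lattice
#' with hexagonal (default) or rectangular topology, unit spacing between
#' adjacent neurons, and a link-distance metric (number of lattice hops
#' between neurons) used for neighborhood membership during training.
#'
#' @param rows,cols Grid dimensions (default 10 x 10 = 100 neurons).
#' @param topology `"hexagonal"` (default) or `"rectangular"`.
#' @return An object of class `som_grid`: list with `rows`, `cols`,
#'   `topology`, `pos` (n x 2 layout coordinates), `row`, `col` (integer
#'   indices per neuron) and `linkdist` (n x n integer hop distances).
#' @export
som_grid <- function(rows = 10, cols = 10,
                     topology = c("hexagonal", "rectangular")) {
  topology <- match.arg(topology)
  stopifnot(rows >= 1, cols >= 1)
  idx <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  if (topology == "hexagonal") {
    x <- (idx$col - 1) + 0.5 * ((idx$row - 1) %% 2)
    y <- (idx$row - 1) * sqrt(3) / 2
  } else {
    x <- idx$col - 1
    y <- idx$row - 1
  }
  pos <- cbind(x = x, y = y)
  n <- nrow(pos)
  # adjacency: neurons at unit layout distance
  d <- as.matrix(stats::dist(pos))
  adj <- d <= 1 + 1e-6 & d > 0
  linkdist <- matrix(Inf, n, n)
  diag(linkdist) <- 0
  for (s in seq_len(n)) {          # BFS hop counts from each neuron
    depth <- 0L
    frontier <- s
    seen <- rep(FALSE, n); seen[s] <- TRUE
    while (length(frontier)) {
      depth <- depth + 1L
      nxt <- which(!seen & colSums(adj[frontier, , drop = FALSE]) > 0)
      if (!length(nxt)) break
      linkdist[s, nxt] <- depth
      seen[nxt] <- TRUE
      frontier <- nxt
    }
  }
  structure(list(rows = rows, cols = cols, topology = topology,
                 pos = pos, row = idx$row, col = idx$col,
                 linkdist = linkdist),
            class = "som_grid")
}

# squared Euclidean distances, neurons x samples
neuron_dist2 <- function(W, X) {
  D2 <- matrix(rowSums(W^2), nrow(W), nrow(X)) +
    matrix(rowSums(X^2), nrow(W), nrow(X), byrow = TRUE) -
    2 * W %*% t(X)
  pmax(D2, 0)
}

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(dplyr::select(x, dplyr::where(is.numeric)))
  if (!is.matrix(x) || !is.numeric(x)) stop("`x` must be a numeric matrix or data frame")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  x
}

#' Best-matching units
#'
#' For each input row, the neuron whose weight vector has the smallest
#' Euclidean distance to it; ties are broken toward the lowest neuron
#' index.
#'
#' @param object A fitted `sway_som` model.
#' @param newdata Numeric matrix or data frame with the model's features.
#' @return Integer vector of winning neuron indices, one per row.
#' @export
som_predict <- function(object, newdata) {
  stopifnot(inherits(object, "sway_som"))
  X <- as_feature_matrix(newdata)
  if (ncol(X) != ncol(object$weights))
    stop("dimension mismatch: model has ", ncol(object$weights),
         " features, data has ", ncol(X))
  D2 <- neuron_dist2(object$weights, X)
  max.col(-t(D2), ties.method = "first")
}

#' Fit a Kohonen self-organizing map
#'
#' Competitive learning on a neuron lattice.  The batch rule (default, and
#' the one the clustering pipeline uses) updates every neuron once per
#' epoch to the mean of all samples whose best-matching unit lies within
#' the current neighborhood radius (step-function kernel on link distance);
#' neurons with an empty neighborhood keep their weights.  The radius
#' shrinks linearly from `neighborhood0` to `radius_floor` over the first
#' half of training (the ordering phase) and stays at the floor thereafter.
#' Because batch updates are means, the result does not depend on the order
#' in which samples are presented; input rows are canonicalised
#' (lexicographically sorted) before summation so the invariance is exact
#' even in floating point.
#'
#' The sequential rule updates weights after every sample presentation,
#' `W <- W + mu * h * (X - W)`, with a Gaussian neighborhood factor
#' `h = exp(-linkdist^2 / (2 * r^2))`; the learning rate `mu` and radius
#' decay linearly to their floors over training.
#'
#' @param x Numeric matrix or data frame (samples x features).
#' @param grid A [som_grid()] (default 10 x 10 hexagonal).
#' @param iterations Training iterations/epochs (default 1000).
#' @param neighborhood0 Initial neighborhood radius in neurons (default 3).
#' @param radius_floor Final radius (default 1; 0 makes each batch epoch a
#'   Lloyd step with one centroid per neuron).
#' @param method `"batch"` (default) or `"sequential"`.
#' @param mu0,mu_floor Initial/final learning rate (sequential only).
#' @param init `"random"` (small uniform weights in `[0, 0.01]`, seeded) or
#'   `"span"` (linear interpolation across each feature's data range).
#' @param seed Integer seed (controls initialization and, for the
#'   sequential rule, presentation order).
#' @return An object of class `sway_som`: list with `weights` (neurons x
#'   features), `grid`, `qe` (per-iteration quantization error, i.e. mean
#'   distance of samples to their BMU), and the training settings.
#' @export
#' @examples
#' m <- som_fit(matrix(rnorm(60), 30, 2), som_grid(3, 3), iterations = 20,
#'              seed = 1)
#' table(som_predict(m, matrix(rnorm(60), 30, 2)))
som_fit <- function(x, grid = som_grid(), iterations = 1000,
                    neighborhood0 = 3, radius_floor = 1,
                    method = c("batch", "sequential"),
                    mu0 = 0.5, mu_floor = 0.01,
                    init = c("random", "span"), seed = 1) {
  method <- match.arg(method)
  init <- match.arg(init)
  X <- as_feature_matrix(x)
  if (nrow(X) == 0) stop("`x` must contain at least one sample")
  if (method == "sequential" && (mu0 <= 0 || mu0 > 1))
    stop("`mu0` must lie in (0, 1]")
  stopifnot(iterations >= 1, neighborhood0 >= 0,
            radius_floor >= 0, radius_floor <= max(neighborhood0, radius_floor))
  nn <- grid$rows * grid$cols
  m <- ncol(X)

  W <- if (init == "random") {
    matrix(withr::with_seed(seed, runif(nn * m, 0, 0.01)), nn, m)
  } else {
    apply(X, 2, function(v) {
      rng <- range(v)
      rng[1] + (rng[2] - rng[1]) * (grid$col - 1) / max(1, grid$cols - 1)
    })
  }
  colnames(W) <- colnames(X)

  radius_at <- function(t) {
    t_ord <- ceiling(iterations / 2)
    if (t >= t_ord || neighborhood0 <= radius_floor) return(radius_floor)
    neighborhood0 - (neighborhood0 - radius_floor) * (t - 1) / max(1, t_ord - 1)
  }

  qe <- numeric(iterations)
  if (method == "batch") {
    # canonical row order => exact presentation-order invariance
    Xc <- X[do.call(order, as.data.frame(X)), , drop = FALSE]
    for (t in seq_len(iterations)) {
      D2 <- neuron_dist2(W, Xc)
      bmu <- max.col(-t(D2), ties.method = "first")
      qe[t] <- mean(sqrt(D2[cbind(bmu, seq_len(nrow(Xc)))]))
      r <- radius_at(t)
      M <- (grid$linkdist <= r) * 1
      S <- matrix(0, nn, m)
      sums <- rowsum(Xc, bmu)
      S[as.integer(rownames(sums)), ] <- sums
      cnt <- tabulate(bmu, nn)
      num <- M %*% S
      den <- as.numeric(M %*% cnt)
      upd <- den > 0
      W[upd, ] <- num[upd, , drop = FALSE] / den[upd]
    }
  } else {
    steps <- iterations
    withr::with_seed(seed + 1L, {
      for (t in seq_len(steps)) {
        ord <- sample.int(nrow(X))
        mu <- mu_floor + (mu0 - mu_floor) * (steps - t) / max(1, steps - 1)
        r <- max(radius_at(t), 1e-9)
        for (j in ord) {
          xj <- X[j, ]
          d2 <- rowSums((W - matrix(xj, nn, m, byrow = TRUE))^2)
          win <- which.min(d2)
          h <- exp(-grid$linkdist[win, ]^2 / (2 * r^2))
          W <- W + mu * h * (matrix(xj, nn, m, byrow = TRUE) - W)
        }
        D2 <- neuron_dist2(W, X)
        qe[t] <- mean(sqrt(apply(D2, 2, min)))
      }
    })
  }

  structure(list(weights = W, grid = grid, method = method,
                 iterations = iterations, neighborhood0 = neighborhood0,
                 radius_floor = radius_floor, seed = seed, qe = qe,
                 features = colnames(W)),
            class = "sway_som")
}

#' @export
print.sway_som <- function(x, ...) {
  cat("Kohonen self-organizing map (", x$method, ")\n", sep = "")
  cat("  grid: ", x$grid$rows, "x", x$grid$cols, " ", x$grid$topology,
      " (", nrow(x$weights), " neurons)\n", sep = "")
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  cat("  iterations:", x$iterations,
      " final quantization error:", signif(x$qe[x$iterations], 4), "\n")
  invisible(x)
}

#' Per-neuron hit counts
#'
#' Number of input samples whose best-matching unit is each neuron; the
#' counts sum to the number of samples.
#'
#' @param object A `sway_som` model.
#' @param data Samples to tally.
#' @return Tibble with columns `neuron`, `row`, `col`, `hits`.
#' @export
som_hits <- function(object, data) {
  bmu <- som_predict(object, data)
  tibble::tibble(
    neuron = seq_len(nrow(object$weights)),
    row = object$grid$row, col = object$grid$col,
    hits = tabulate(bmu, nrow(object$weights))
  )
}

#' Unified distance matrix (U-matrix)
#'
#' Mean weight-space Euclidean distance from each neuron to its immediate
#' lattice neighbors (link distance 1); large values mark cluster
#' boundaries on the map.
#'
#' @param object A `sway_som` model.
#' @return Tibble with columns `neuron`, `row`, `col`, `distance`.
#' @export
som_umatrix <- function(object) {
  stopifnot(inherits(object, "sway_som"))
  W <- object$weights
  ld <- object$grid$linkdist
  val <- vapply(seq_len(nrow(W)), function(i) {
    nb <- which(ld[i, ] == 1)
    mean(sqrt(rowSums((W[nb, , drop = FALSE] -
                         matrix(W[i, ], length(nb), ncol(W), byrow = TRUE))^2)))
  }, numeric(1))
  tibble::tibble(neuron = seq_len(nrow(W)),
                 row = object$grid$row, col = object$grid$col,
                 distance = val)
}

#' Weight planes
#'
#' One map per input feature holding the neuron weights for that feature;
#' visually similar planes indicate correlated inputs.
#'
#' @param object A `sway_som` model.
#' @return Long tibble with columns `feature`, `neuron`, `row`, `col`,
#'   `weight`.
#' @export
som_weight_planes <- function(object) {
  stopifnot(inherits(object, "sway_som"))
  W <- object$weights
  purrr::map_dfr(colnames(W), function(f) {
    tibble::tibble(feature = f, neuron = seq_len(nrow(W)),
                   row = object$grid$row, col = object$grid$col,
                   weight = W[, f])
  })
}

#' Serialize / restore a SOM model as JSON
#'
#' Stores the grid specification, weight matrix and training settings in a
#' plain JSON file.
#'
#' @param object A `sway_som` model.
#' @param path JSON file path.
#' @return `som_to_json()` returns `path` invisibly; `som_from_json()`
#'   returns the restored `sway_som` model.
#' @export
som_to_json <- function(object, path) {
  stopifnot(inherits(object, "sway_som"))
  payload <- list(
    grid = list(rows = object$grid$rows, cols = object$grid$cols,
                topology = object$grid$topology),
    features = object$features,
    weights = unname(object$weights),
    method = object$method, iterations = object$iterations,
    neighborhood0 = object$neighborhood0,
    radius_floor = object$radius_floor, seed = object$seed
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname som_to_json
#' @export
som_from_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- som_grid(p$grid$rows, p$grid$cols, p$grid$topology)
  W <- if (is.list(p$weights)) do.call(rbind, lapply(p$weights, as.numeric))
       else matrix(as.numeric(p$weights), nrow = grid$rows * grid$cols)
  colnames(W) <- p$features
  structure(list(weights = W, grid = grid, method = p$method,
                 iterations = p$iterations, neighborhood0 = p$neighborhood0,
                 radius_floor = p$radius_floor, seed = p$seed,
                 qe = NA_real_, features = p$features),
            class = "sway_som")
}
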