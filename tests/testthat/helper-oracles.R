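# Independent oracles used across the suite.  These are deliberately
# naive re-implementations (loops, direct formulas, exhaustive search)
# kept separate from the package's own code paths.

# Kendall tau-b by O(n^2) pair counting with tie correction
brute_kendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) next
    if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - count_ties(x)) * (n0 - count_ties(y)))
}
count_ties <- function(v) {
  t <- table(v)
  sum(t * (t - 1) / 2)
}

# Davies-Bouldin straight from the definition, loops only
db_oracle <- function(X, cl) {
  ids <- sort(unique(cl))
  k <- length(ids)
  mu <- list(); sig <- numeric(k)
  for (i in seq_len(k)) {
    M <- X[cl == ids[i], , drop = FALSE]
    mu[[i]] <- colMeans(M)
    sig[i] <- sqrt(mean(apply(M, 1, function(r) sum((r - mu[[i]])^2))))
  }
  DBi <- numeric(k)
  for (i in seq_len(k)) {
    worst <- -Inf
    for (j in seq_len(k)) {
      if (i == j) next
      gap <- sqrt(sum((mu[[i]] - mu[[j]])^2))
      worst <- max(worst, (sig[i] + sig[j]) / gap)
    }
    DBi[i] <- worst
  }
  mean(DBi)
}

# single Lloyd update of centroids W given data X (empty cells keep weights)
lloyd_step <- function(W, X) {
  assign <- apply(X, 1, function(x)
    which.min(colSums((t(W) - x)^2)))
  out <- W
  for (c in unique(assign))
    out[c, ] <- colMeans(X[assign == c, , drop = FALSE])
  out
}

# minimum cluster-averaged recall by recursive enumeration over all
# per-cluster (class1, class2) compositions; feasible for small sizes only
min_recall_enum <- function(k, A, B) {
  best <- Inf
  recur <- function(depth, a, b, acc) {
    if (depth == 0) {
      if (a == 0 && b == 0) best <<- min(best, acc)
      return(invisible())
    }
    if (acc >= best) return(invisible())
    for (i in 0:a) for (j in 0:b) {
      if (i + j == 0) next
      rec <- if (i >= j) i / A else j / B
      recur(depth - 1, a - i, b - j, acc + rec)
    }
  }
  recur(k, A, B, 0)
  best / k
}

# two well-separated Gaussian blobs in 2-D
make_blobs <- function(n_per = 10, gap = 10, sd = 0.5, seed = 1) {
  withr::with_seed(seed, {
    rbind(
      cbind(rnorm(n_per, 0, sd), rnorm(n_per, 0, sd)),
      cbind(rnorm(n_per, gap, sd), rnorm(n_per, 0, sd))
    )
  })
}

# deterministic feature table reproducing the collinearity pattern the
# screen must resolve: velocity ~ acceleration strongly, position weakly
make_screen_fixture <- function(n = 40, seed = 3) {
  withr::with_seed(seed, {
    pos <- exp(rnorm(n, 0, 0.3))
    vel <- exp(rnorm(n, 1, 0.5)) * pos^0.2
    acc <- vel^1.3 * exp(rnorm(n, 0, 0.05))
    tibble::tibble(rms_position_cm = pos, rms_velocity_cms = vel,
                   rms_acceleration_cms2 = acc)
  })
}

# small fast study configuration for pipeline unit tests (not the study
# defaults; those are exercised in the acceptance suite)
tiny_study <- function(features, seed = 1, n_reps = 2) {
  run_study(features, n_reps = n_reps, k_range = 2:6, select_reps = 2,
            grid = som_grid(5, 5), iterations = 60, restarts = 3,
            seed = seed)
}
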