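#' Active SOM prototypes
#'
#' The second clustering level operates on the map's active prototypes:
#' every neuron that wins at least one sample contributes one prototype,
#' taken as the centroid (mean) of the samples mapped to it.  Neurons with
#' no hits are excluded.  The raw neuron weight vector is available as an
#' alternative prototype definition.
#'
#' @param object A fitted `sway_som` model.
#' @param data The samples (matrix or data frame) to map onto the neurons.
#' @param type `"data_centroid"` (default; mean of member samples) or
#'   `"weight"` (the neuron's weight vector).
#' @return An object of class `sway_prototypes`: list with `centers`
#'   (prototypes x features matrix), `neuron` (neuron index per prototype)
#'   and `members` (list of member row indices per prototype).
#' @export
active_prototypes <- function(object, data,
                              type = c("data_centroid", "weight")) {
  type <- match.arg(type)
  X <- as_feature_matrix(data)
  bmu <- som_predict(object, X)
  active <- sort(unique(bmu))
  if (!length(active)) stop("no active prototypes: no sample hit any neuron")
  members <- lapply(active, function(n) which(bmu == n))
  centers <- if (type == "weight") {
    object$weights[active, , drop = FALSE]
  } else {
    do.call(rbind, lapply(members, function(ix)
      colMeans(X[ix, , drop = FALSE])))
  }
  colnames(centers) <- colnames(X)
  structure(list(centers = centers, neuron = active, members = members,
                 n_data = nrow(X)),
            class = "sway_prototypes")
}

#' K-means clustering (Lloyd iterations, k-means++ seeding)
#'
#' Minimises the within-cluster sum of squares (WCSS) under the Euclidean
#' metric.  Centroids are seeded with the k-means++ rule, then Lloyd
#' assignment/update steps run until the assignment stabilises.  A cluster
#' that empties is re-seeded at the point farthest from its current
#' centroid, which cannot increase the WCSS.  With `restarts > 1` the run
#' with the lowest WCSS is kept.  Fully deterministic given `seed`.
#'
#' @param points Numeric matrix or data frame (points x features).
#' @param k Number of clusters, `1 <= k <= nrow(points)`.
#' @param seed Integer seed.
#' @param max_iter Maximum Lloyd iterations (default 300).
#' @param restarts Independent seeded restarts (default 1).
#' @return An object of class `sway_kmeans`: list with `cluster` (integer
#'   assignment), `centers`, `wcss`, `wcss_trace` (WCSS after every Lloyd
#'   step) and `iterations`.
#' @export
kmeans_pp <- function(points, k, seed = 1, max_iter = 300, restarts = 1) {
  X <- as_feature_matrix(points)
  n <- nrow(X)
  if (k > n) stop("`k` must not exceed the number of points")
  stopifnot(k >= 1, restarts >= 1)

  one_run <- function(run_seed) {
    centers <- withr::with_seed(run_seed, {
      ix <- sample.int(n, 1)
      cen <- X[ix, , drop = FALSE]
      while (nrow(cen) < k) {
        d2 <- apply(neuron_dist2(cen, X), 2, min)
        ix <- if (sum(d2) == 0) sample.int(n, 1)
              else sample.int(n, 1, prob = d2 / sum(d2))
        cen <- rbind(cen, X[ix, , drop = FALSE])
      }
      cen
    })
    assign_prev <- rep(0L, n)
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      D2 <- neuron_dist2(centers, X)
      cl <- max.col(-t(D2), ties.method = "first")
      # re-seed empty clusters at the point farthest from its centroid
      empty <- setdiff(seq_len(k), unique(cl))
      while (length(empty)) {
        far <- which.max(D2[cbind(cl, seq_len(n))])
        centers[empty[1], ] <- X[far, ]
        D2 <- neuron_dist2(centers, X)
        cl <- max.col(-t(D2), ties.method = "first")
        empty <- setdiff(seq_len(k), unique(cl))
      }
      for (c in seq_len(k))
        centers[c, ] <- colMeans(X[cl == c, , drop = FALSE])
      trace <- c(trace, sum(neuron_dist2(centers, X)[cbind(cl, seq_len(n))]))
      if (identical(cl, assign_prev)) break
      assign_prev <- cl
    }
    list(cluster = cl, centers = centers, wcss = trace[length(trace)],
         wcss_trace = trace, iterations = length(trace))
  }

  runs <- lapply(seq_len(restarts) - 1L, function(r) one_run(seed + r))
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "wcss"))]]
  structure(best, class = "sway_kmeans")
}

#' Davies-Bouldin index
#'
#' Internal cluster-validity index: for clusters i and j with scatters
#' `sigma_i`, `sigma_j` (root-mean-square distance of members to the
#' cluster mean) and means `mu_i`, `mu_j`,
#' `DB_ij = (sigma_i + sigma_j) / ||mu_i - mu_j||`; each cluster takes its
#' worst ratio `DB_i = max_{j != i} DB_ij` and the index is the mean of the
#' `DB_i`.  Lower values indicate better-separated, tighter clusters.
#'
#' @param points Numeric matrix or data frame.
#' @param cluster Integer cluster assignment, at least 2 non-empty
#'   clusters.
#' @return The DB index (scalar).
#' @export
#' @examples
#' pts <- rbind(c(0, 0), c(0, 2), c(10, 0), c(10, 2))
#' davies_bouldin(pts, c(1, 1, 2, 2)) # 0.2
davies_bouldin <- function(points, cluster) {
  X <- as_feature_matrix(points)
  stopifnot(nrow(X) == length(cluster))
  ids <- sort(unique(cluster))
  k <- length(ids)
  if (k < 2) stop("need at least 2 non-empty clusters")
  mu <- do.call(rbind, lapply(ids, function(c)
    colMeans(X[cluster == c, , drop = FALSE])))
  sig <- vapply(seq_along(ids), function(i) {
    M <- X[cluster == ids[i], , drop = FALSE]
    sqrt(mean(rowSums((M - matrix(mu[i, ], nrow(M), ncol(M),
                                  byrow = TRUE))^2)))
  }, numeric(1))
  gap <- as.matrix(stats::dist(mu))
  if (any(gap[upper.tri(gap)] == 0))
    stop("degenerate clustering: coincident cluster centroids")
  DBi <- vapply(seq_len(k), function(i)
    max((sig[i] + sig[-i]) / gap[i, -i]), numeric(1))
  mean(DBi)
}

#' Davies-Bouldin scan over candidate cluster counts
#'
#' Runs K-means on the prototypes for each K in `k_range` (default 2..30),
#' recording the DB index averaged over `reps` seeded repetitions (each the
#' best of `restarts` k-means++ restarts by WCSS), and flags the local
#' minima of the mean-DB curve (endpoints compared one-sided).  K values
#' exceeding the number of points are clipped with a warning.
#'
#' @param points Prototype matrix, `sway_prototypes` object, or data frame.
#' @param k_range Candidate cluster counts (default `2:30`).
#' @param reps Repetitions per K (default 1).
#' @param restarts K-means restarts per repetition (default 10).
#' @param seed Integer seed.
#' @return An object of class `db_scan`: list with `curve` (tibble `k`,
#'   `mean_db`), `minima` (integer K values), `reps`, `seed`.
#' @export
db_scan <- function(points, k_range = 2:30, reps = 1, restarts = 10,
                    seed = 1) {
  if (inherits(points, "sway_prototypes")) points <- points$centers
  X <- as_feature_matrix(points)
  k_range <- sort(unique(as.integer(k_range)))
  if (max(k_range) > nrow(X) - 1) {
    warning("clipping `k_range` to the number of points minus one (",
            nrow(X) - 1, ")")
    k_range <- k_range[k_range <= nrow(X) - 1]
  }
  if (!length(k_range)) stop("no feasible K in `k_range`")
  mean_db <- vapply(k_range, function(k) {
    vals <- vapply(seq_len(reps), function(r) {
      km <- kmeans_pp(X, k, seed = seed + 1000L * r + k, restarts = restarts)
      tryCatch(davies_bouldin(X, km$cluster), error = function(e) NA_real_)
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  curve <- tibble::tibble(k = k_range, mean_db = mean_db)
  ok <- which(is.finite(mean_db))
  minima <- integer(0)
  for (i in ok) {
    left <- if (i > 1) mean_db[i] < mean_db[i - 1] else TRUE
    right <- if (i < length(mean_db)) mean_db[i] < mean_db[i + 1] else TRUE
    if (isTRUE(left) && isTRUE(right)) minima <- c(minima, k_range[i])
  }
  structure(list(curve = curve, minima = minima, reps = reps, seed = seed),
            class = "db_scan")
}

#' Choose the cluster count from DB minima by F-measure
#'
#' Among the candidate K values (the local minima of the DB curve; the
#' global minimum is always included), picks the K with the highest mean
#' F-measure; ties go to the smaller K.  The K chosen on the reference
#' condition pair (1 vs 4, where the largest sway differences are expected)
#' is reused for the other pairs.
#'
#' @param scan A [db_scan()] result.
#' @param f_by_k Named numeric vector (or tibble with columns `k`, `f`) of
#'   mean F-measures for the candidate K values.
#' @return The chosen K (integer).
#' @export
choose_k <- function(scan, f_by_k) {
  stopifnot(inherits(scan, "db_scan"))
  if (is.data.frame(f_by_k))
    f_by_k <- setNames(f_by_k$f, f_by_k$k)
  cand <- scan$minima
  gmin <- scan$curve$k[which.min(scan$curve$mean_db)]
  cand <- sort(unique(c(cand, gmin)))
  if (!length(cand)) stop("no candidate K values")
  have <- intersect(as.character(cand), names(f_by_k))
  if (!length(have)) stop("`f_by_k` covers none of the candidate K values")
  f <- f_by_k[have]
  ks <- as.integer(have)
  best <- max(f)
  min(ks[f == best])
}

#' Propagate prototype clusters to the data points
#'
#' Each data point inherits the cluster of the prototype (neuron) it was
#' mapped to during the first abstraction level.
#'
#' @param prototypes A [active_prototypes()] result.
#' @param proto_cluster Integer cluster per prototype (e.g. from
#'   [kmeans_pp()] on the prototype centers).
#' @return Integer cluster assignment, one entry per original data point.
#' @export
propagate_clusters <- function(prototypes, proto_cluster) {
  stopifnot(inherits(prototypes, "sway_prototypes"),
            length(proto_cluster) == length(prototypes$members))
  out <- integer(prototypes$n_data)
  for (i in seq_along(prototypes$members))
    out[prototypes$members[[i]]] <- proto_cluster[i]
  if (any(out == 0)) stop("propagation left unassigned points")
  out
}
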