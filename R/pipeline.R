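# distinct integer streams below 2^31 for each pipeline stage
seed_stream <- function(seed, idx) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(idx) * 104729) %% 2147483647)
}

# z-score columns; zero-variance columns are centred only
scale_columns <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  s[s == 0] <- 1
  sweep(sweep(X, 2, mu), 2, s, "/")
}

#' Assemble the feature matrix for one condition pair
#'
#' Builds the 2 x 23 = 46-row input for the clustering of one mCTSIB
#' condition against the reference condition: the retained RMS features of
#' the chosen direction, or, for `direction = "combined"`, the retained ML
#' and AP features concatenated per subject.  Columns are z-scored over the
#' assembled rows (after concatenation in combined mode) so position (cm)
#' and velocity (cm/s) contribute comparably to the Euclidean metric.
#'
#' @param features Feature tibble from [extract_sway_features()].
#' @param condition_b Condition to pair with the reference.
#' @param direction `"ML"`, `"AP"` or `"combined"`.
#' @param retained Character vector of retained feature columns, or (for
#'   combined) a named list with elements `ML` and `AP`.
#' @param reference Reference condition (default 1).
#' @param scale Z-score the columns (default `TRUE`).
#' @return List with `x` (numeric matrix), `labels` (condition per row) and
#'   `subject_id`.
#' @export
pair_matrix <- function(features, condition_b, direction, retained,
                        reference = 1, scale = TRUE) {
  conds <- c(reference, condition_b)
  if (!all(conds %in% features$condition))
    stop("condition ", setdiff(conds, features$condition)[1],
         " missing from the feature table")
  if (direction == "combined") {
    ret <- if (is.list(retained)) retained
           else list(ML = retained, AP = retained)
    parts <- purrr::imap(ret, function(cols, dir) {
      d <- dplyr::filter(features, .data$direction == dir,
                         .data$condition %in% conds)
      d <- dplyr::arrange(d, .data$condition, .data$subject_id)
      m <- as.matrix(d[, cols, drop = FALSE])
      colnames(m) <- paste(dir, cols, sep = "_")
      list(m = m, key = d[, c("subject_id", "condition")])
    })
    if (!identical(parts[[1]]$key, parts[[2]]$key))
      stop("ML and AP rows do not align")
    x <- cbind(parts[[1]]$m, parts[[2]]$m)
    key <- parts[[1]]$key
  } else {
    d <- dplyr::filter(features, .data$direction == !!direction,
                       .data$condition %in% conds)
    d <- dplyr::arrange(d, .data$condition, .data$subject_id)
    x <- as.matrix(d[, unlist(retained), drop = FALSE])
    key <- d[, c("subject_id", "condition")]
  }
  if (scale) x <- scale_columns(x)
  list(x = x, labels = key$condition, subject_id = key$subject_id)
}

#' Run one SOM + K-means clustering and evaluate it
#'
#' One pass of the two-level scheme: batch-train the map on the rows of
#' `x`, form the active prototypes, K-means the prototype centroids,
#' propagate the prototype clusters back to the data points and score the
#' result against the class labels.
#'
#' @param x Numeric matrix (samples x features), typically from
#'   [pair_matrix()].
#' @param labels Class labels per row.
#' @param k Number of clusters.
#' @param grid [som_grid()] for the first level (default 10 x 10).
#' @param iterations,neighborhood0 SOM training settings (defaults 1000
#'   and 3).
#' @param restarts K-means restarts (default 10).
#' @param seed Integer seed.
#' @param keep_models Keep the SOM/K-means objects in the result.
#' @return List with `measures` (one-row tibble), `assignment`, and (if
#'   `keep_models`) `som`, `prototypes`, `kmeans`.
#' @export
cluster_once <- function(x, labels, k, grid = som_grid(),
                         iterations = 1000, neighborhood0 = 3,
                         restarts = 10, seed = 1, keep_models = FALSE) {
  perm <- withr::with_seed(seed_stream(seed, 1), sample.int(nrow(x)))
  x <- x[perm, , drop = FALSE]
  labels <- labels[perm]
  som <- som_fit(x, grid = grid, iterations = iterations,
                 neighborhood0 = neighborhood0,
                 seed = seed_stream(seed, 2))
  protos <- active_prototypes(som, x)
  k_eff <- min(k, nrow(protos$centers))
  km <- kmeans_pp(protos$centers, k_eff, seed = seed_stream(seed, 3),
                  restarts = restarts)
  assignment <- propagate_clusters(protos, km$cluster)
  out <- list(measures = external_measures(assignment, labels),
              assignment = assignment, labels = labels, k = k_eff)
  if (keep_models) out <- c(out, list(som = som, prototypes = protos,
                                      kmeans = km))
  out
}

#' Select the cluster count on the reference pair
#'
#' Implements the K-selection protocol: scan the Davies-Bouldin index over
#' `k_range` on the active prototypes of the reference condition pair,
#' locate the local minima, compute the mean F-measure at each candidate K
#' over `reps` seeded repetitions, and keep the K with the highest F
#' (ties to the smaller K).
#'
#' @inheritParams cluster_once
#' @param k_range Candidate cluster counts (default `2:30`).
#' @param reps Repetitions for the scan and the per-K F-measures
#'   (default 10).
#' @return List with `k` (chosen), `scan` (the [db_scan()]), `f_by_k`
#'   (tibble `k`, `f`).
#' @export
select_cluster_count <- function(x, labels, k_range = 2:30, reps = 10,
                                 grid = som_grid(), iterations = 1000,
                                 neighborhood0 = 3, restarts = 10,
                                 seed = 1) {
  som <- som_fit(x, grid = grid, iterations = iterations,
                 neighborhood0 = neighborhood0,
                 seed = seed_stream(seed, 11))
  protos <- active_prototypes(som, x)
  scan <- suppressWarnings(
    db_scan(protos, k_range = k_range, reps = reps, restarts = restarts,
            seed = seed_stream(seed, 12)))
  gmin <- scan$curve$k[which.min(scan$curve$mean_db)]
  cand <- sort(unique(c(scan$minima, gmin)))
  f_by_k <- purrr::map_dfr(cand, function(k) {
    f <- vapply(seq_len(reps), function(r) {
      km <- kmeans_pp(protos$centers, k,
                      seed = seed_stream(seed, 100 + 31 * k + r),
                      restarts = restarts)
      f_measure(propagate_clusters(protos, km$cluster), labels)
    }, numeric(1))
    tibble::tibble(k = k, f = mean(f))
  })
  list(k = choose_k(scan, f_by_k), scan = scan, f_by_k = f_by_k)
}

#' Repeat the clustering of one condition pair
#'
#' Runs [cluster_once()] `n_reps` times with fresh row shuffles and fresh
#' SOM / K-means seeds, recording the external measures of every
#' repetition.
#'
#' @inheritParams cluster_once
#' @param n_reps Number of repetitions (default 30).
#' @return Tibble with columns `rep`, `purity`, `precision`, `recall`,
#'   `f_measure`.
#' @export
repeat_clustering <- function(x, labels, k, n_reps = 30, grid = som_grid(),
                              iterations = 1000, neighborhood0 = 3,
                              restarts = 10, seed = 1) {
  purrr::map_dfr(seq_len(n_reps), function(r) {
    res <- cluster_once(x, labels, k, grid = grid, iterations = iterations,
                        neighborhood0 = neighborhood0, restarts = restarts,
                        seed = seed_stream(seed, 2000 + r))
    dplyr::mutate(res$measures, rep = r, .before = 1)
  })
}

#' Cluster one mCTSIB condition against the reference
#'
#' Screens the direction's features, assembles the pair matrix, selects K
#' on the reference pair (1 vs 4) if not supplied, and repeats the
#' two-level clustering.
#'
#' @param features Feature tibble from [extract_sway_features()].
#' @param condition_b Condition paired with the reference (2, 3 or 4).
#' @param direction `"ML"`, `"AP"` or `"combined"`.
#' @param k Cluster count; selected on the reference pair when `NULL`.
#' @param reference Reference condition (default 1).
#' @param n_reps Clustering repetitions (default 30).
#' @param k_range Scan range for K selection (default `2:30`).
#' @inheritParams cluster_once
#' @return Tibble with columns `pair`, `direction`, `rep` and the four
#'   measures; the chosen `k` is attached as attribute `"k"`.
#' @export
run_condition_pair <- function(features, condition_b,
                               direction = c("AP", "ML", "combined"),
                               k = NULL, reference = 1, n_reps = 30,
                               k_range = 2:30, grid = som_grid(),
                               iterations = 1000, neighborhood0 = 3,
                               restarts = 10, seed = 1) {
  direction <- match.arg(direction)
  retained <- screen_retained(features, direction)
  if (is.null(k)) {
    ref <- pair_matrix(features, 4, direction, retained, reference)
    k <- select_cluster_count(ref$x, ref$labels, k_range = k_range,
                              grid = grid, iterations = iterations,
                              neighborhood0 = neighborhood0,
                              restarts = restarts, seed = seed)$k
  }
  pm <- pair_matrix(features, condition_b, direction, retained, reference)
  out <- repeat_clustering(pm$x, pm$labels, k, n_reps = n_reps, grid = grid,
                           iterations = iterations,
                           neighborhood0 = neighborhood0,
                           restarts = restarts, seed = seed)
  out <- dplyr::mutate(out,
                       pair = paste0(reference, "v", condition_b),
                       direction = direction, .before = 1)
  attr(out, "k") <- k
  out
}

# retained feature set(s) for a direction ("combined" returns a list)
screen_retained <- function(features, direction, threshold = 0.85,
                            alpha = 0.05) {
  one <- function(dir)
    screen_features(dplyr::filter(features, .data$direction == dir),
                    threshold = threshold, alpha = alpha)$retained
  if (direction == "combined") list(ML = one("ML"), AP = one("AP"))
  else one(direction)
}

#' Run the full between-condition sway study
#'
#' End-to-end protocol on an extracted feature table: per direction, screen
#' the collinear RMS features, choose the cluster count on the reference
#' pair (condition 1 vs 4), then repeat the two-level clustering `n_reps`
#' times for every condition pair (1v2, 1v3, 1v4), and finally compare the
#' pooled measures between the ML and AP directions.
#'
#' @param features Feature tibble from [extract_sway_features()].
#' @param directions Directions to analyse (default `c("ML", "AP")`;
#'   `"combined"` may be added).
#' @param pairs Conditions to pair against the reference (default `2:4`).
#' @param reference Reference condition (default 1).
#' @param n_reps Clustering repetitions per pair (default 30).
#' @param k_range DB scan range (default `2:30`).
#' @param select_reps Repetitions inside the K-selection stage
#'   (default 10).
#' @inheritParams cluster_once
#' @return An object of class `sway_eval`: list with
#'   * `results`: long tibble `pair`, `direction`, `rep`, `purity`,
#'     `precision`, `recall`, `f_measure`;
#'   * `summary`: median and IQR per pair x direction x measure;
#'   * `comparisons`: per-measure ML-vs-AP test results (pooled across
#'     pairs);
#'   * `k_by_direction`, `screens`, `scans`, `config`.
#' @export
run_study <- function(features, directions = c("ML", "AP"), pairs = 2:4,
                      reference = 1, n_reps = 30, k_range = 2:30,
                      select_reps = 10, grid = som_grid(),
                      iterations = 1000, neighborhood0 = 3, restarts = 10,
                      seed = 1) {
  screens <- purrr::map(
    setNames(c("ML", "AP"), c("ML", "AP")),
    ~ screen_features(dplyr::filter(features, .data$direction == .x)))

  k_by_direction <- list()
  scans <- list()
  results <- list()
  for (di in seq_along(directions)) {
    dir <- directions[di]
    retained <- if (dir == "combined")
      list(ML = screens$ML$retained, AP = screens$AP$retained)
    else screens[[dir]]$retained
    ref <- pair_matrix(features, 4, dir, retained, reference)
    sel <- select_cluster_count(ref$x, ref$labels, k_range = k_range,
                                reps = select_reps, grid = grid,
                                iterations = iterations,
                                neighborhood0 = neighborhood0,
                                restarts = restarts,
                                seed = seed_stream(seed, 3000 + di))
    k_by_direction[[dir]] <- sel$k
    scans[[dir]] <- sel$scan
    for (pi in seq_along(pairs)) {
      b <- pairs[pi]
      pm <- pair_matrix(features, b, dir, retained, reference)
      res <- repeat_clustering(pm$x, pm$labels, sel$k, n_reps = n_reps,
                               grid = grid, iterations = iterations,
                               neighborhood0 = neighborhood0,
                               restarts = restarts,
                               seed = seed_stream(seed, 4000 + 100 * di + pi))
      results[[paste(dir, b)]] <- dplyr::mutate(
        res, pair = paste0(reference, "v", b), direction = dir, .before = 1)
    }
  }
  results <- dplyr::bind_rows(results)

  summary <- results |>
    tidyr::pivot_longer(c("purity", "precision", "recall", "f_measure"),
                        names_to = "measure") |>
    dplyr::group_by(.data$pair, .data$direction, .data$measure) |>
    dplyr::summarise(median = median(.data$value),
                     iqr = IQR(.data$value), .groups = "drop")

  comparisons <- NULL
  if (all(c("ML", "AP") %in% directions)) {
    comparisons <- purrr::map_dfr(
      c("purity", "precision", "recall", "f_measure"),
      function(m) {
        ml <- results[[m]][results$direction == "ML"]
        ap <- results[[m]][results$direction == "AP"]
        dplyr::mutate(compare_directions(ml, ap), measure = m, .before = 1)
      })
  }

  structure(list(results = results, summary = summary,
                 comparisons = comparisons,
                 k_by_direction = k_by_direction,
                 screens = screens, scans = scans,
                 config = list(directions = directions, pairs = pairs,
                               reference = reference, n_reps = n_reps,
                               k_range = range(k_range),
                               iterations = iterations,
                               neighborhood0 = neighborhood0,
                               restarts = restarts, seed = seed)),
            class = "sway_eval")
}

#' @export
print.sway_eval <- function(x, ...) {
  cat("Between-condition sway clustering evaluation\n")
  cat("  repetitions:", x$config$n_reps,
      " pairs:", paste(paste0(x$config$reference, "v", x$config$pairs),
                       collapse = ", "), "\n")
  cat("  K by direction:",
      paste(names(x$k_by_direction), unlist(x$k_by_direction),
            sep = "=", collapse = ", "), "\n")
  print(x$summary, n = Inf)
  if (!is.null(x$comparisons)) {
    cat("\nML vs AP (pooled across pairs):\n")
    print(x$comparisons)
  }
  invisible(x)
}

#' Write the evaluation report to CSV files
#'
#' Writes `results.csv` (per-repetition long table), `summary.csv`
#' (medians/IQRs), `comparisons.csv` (ML-vs-AP tests) and one
#' `db_curve_<direction>.csv` per scanned direction into `dir`.
#'
#' @param eval A `sway_eval` from [run_study()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_eval <- function(eval, dir) {
  stopifnot(inherits(eval, "sway_eval"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(eval$results, file.path(dir, "results.csv"))
  readr::write_csv(eval$summary, file.path(dir, "summary.csv"))
  if (!is.null(eval$comparisons))
    readr::write_csv(eval$comparisons, file.path(dir, "comparisons.csv"))
  purrr::iwalk(eval$scans, ~ readr::write_csv(
    .x$curve, file.path(dir, paste0("db_curve_", .y, ".csv"))))
  invisible(dir)
}
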