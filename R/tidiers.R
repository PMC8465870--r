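#' Tidy a fitted SOM
#'
#' One row per neuron x feature with the neuron's grid position and weight.
#'
#' @param x A `sway_som` model.
#' @param ... Unused.
#' @return A tibble with columns `neuron`, `row`, `col`, `feature`,
#'   `weight`.
#' @export
#' @method tidy sway_som
tidy.sway_som <- function(x, ...) {
  som_weight_planes(x)[, c("neuron", "row", "col", "feature", "weight")]
}

#' @rdname tidy.sway_som
#' @return For `glance()`: a one-row tibble with `neurons`, `features`,
#'   `iterations`, `quantization_error` (final mean BMU distance),
#'   `topology`.
#' @export
#' @method glance sway_som
glance.sway_som <- function(x, ...) {
  tibble::tibble(
    neurons = nrow(x$weights),
    features = ncol(x$weights),
    iterations = x$iterations,
    quantization_error = x$qe[length(x$qe)],
    topology = x$grid$topology
  )
}

#' Tidy a K-means solution
#'
#' @param x A `sway_kmeans` object.
#' @param ... Unused.
#' @return One row per cluster: `cluster`, `size`, the centroid
#'   coordinates, and `withinss` share.
#' @export
#' @method tidy sway_kmeans
tidy.sway_kmeans <- function(x, ...) {
  cen <- tibble::as_tibble(x$centers)
  dplyr::mutate(cen, cluster = seq_len(nrow(cen)),
                size = tabulate(x$cluster, nrow(cen)), .before = 1)
}

#' @rdname tidy.sway_kmeans
#' @return For `glance()`: one row with `k`, `wcss`, `iterations`.
#' @export
#' @method glance sway_kmeans
glance.sway_kmeans <- function(x, ...) {
  tibble::tibble(k = nrow(x$centers), wcss = x$wcss,
                 iterations = x$iterations)
}

#' Tidy a DB-index scan
#'
#' @param x A `db_scan` object.
#' @param ... Unused.
#' @return The curve tibble (`k`, `mean_db`) with a logical `is_minimum`
#'   column.
#' @export
#' @method tidy db_scan
tidy.db_scan <- function(x, ...) {
  dplyr::mutate(x$curve, is_minimum = .data$k %in% x$minima)
}

#' Tidy a feature screen
#'
#' @param x A `sway_screen` object.
#' @param ... Unused.
#' @return The pairwise correlation tibble with a `collinear` flag and a
#'   `dropped` flag per pair member.
#' @export
#' @method tidy sway_screen
tidy.sway_screen <- function(x, ...) {
  dplyr::mutate(x$pairs,
                collinear = abs(.data$estimate) >= x$threshold,
                dropped_a = .data$feature_a %in% x$dropped,
                dropped_b = .data$feature_b %in% x$dropped)
}

#' Tidy a study evaluation
#'
#' @param x A `sway_eval` object from [run_study()].
#' @param ... Unused.
#' @return The per-repetition long results tibble.
#' @export
#' @method tidy sway_eval
tidy.sway_eval <- function(x, ...) x$results

#' @rdname tidy.sway_eval
#' @return For `glance()`: one row per direction with the chosen K and the
#'   grand median of each measure.
#' @export
#' @method glance sway_eval
glance.sway_eval <- function(x, ...) {
  meds <- x$results |>
    dplyr::group_by(.data$direction) |>
    dplyr::summarise(dplyr::across(c("purity", "precision", "recall",
                                     "f_measure"), median),
                     .groups = "drop")
  dplyr::mutate(meds,
                k = unlist(x$k_by_direction)[.data$direction],
                n_reps = x$config$n_reps, .after = 1)
}
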