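#' Cluster-by-class contingency table
#'
#' Cross-tabulates a cluster assignment against the known class labels
#' (here, mCTSIB condition identity).  Each cluster is labeled by its
#' majority class; ties go to the lower (earlier) class, i.e. the lower
#' condition index.
#'
#' @param cluster Integer/character cluster assignment.
#' @param labels Class labels, same length.
#' @return An object of class `sway_contingency`: list with `counts`
#'   (clusters x classes matrix), `majority` (majority class per cluster),
#'   `n` (grand total), `class_totals`.
#' @export
cluster_contingency <- function(cluster, labels) {
  stopifnot(length(cluster) == length(labels))
  if (!length(cluster)) stop("empty assignment")
  counts <- unclass(table(cluster, labels))
  maj <- apply(counts, 1, which.max)  # ties -> first (lower) class
  structure(list(counts = counts,
                 majority = colnames(counts)[maj],
                 majority_idx = maj,
                 n = sum(counts),
                 class_totals = colSums(counts)),
            class = "sway_contingency")
}

as_contingency <- function(x, labels = NULL) {
  if (inherits(x, "sway_contingency")) x else cluster_contingency(x, labels)
}

#' External cluster-validity measures
#'
#' Purity, cluster-averaged precision and recall, and F-measure of a
#' clustering against known class labels.  With `n_ij` elements of class j
#' in cluster i, `n_i` the cluster size, `m_j` the class size and `n` the
#' grand total:
#' * per-cluster purity = precision: `max_j(n_ij) / n_i`;
#' * purity: the cluster-size-weighted mean `sum_i (n_i / n) * purity_i`;
#' * precision: the unweighted mean of the `prec_i`;
#' * per-cluster recall: `n_ij* / m_j*` with j* the majority class;
#' * recall: the unweighted mean of the `recall_i`;
#' * `F_i = 2 * prec_i * recall_i / (prec_i + recall_i)`, `F` their mean.
#'
#' @param x A `sway_contingency`, or a cluster assignment vector.
#' @param labels Class labels (when `x` is an assignment).
#' @return A one-row tibble with columns `purity`, `precision`, `recall`,
#'   `f_measure`.  The per-cluster values are attached as attribute
#'   `"per_cluster"` (tibble: `cluster`, `majority`, `size`, `precision`,
#'   `recall`, `f`).
#' @export
#' @examples
#' external_measures(rep(1, 46), rep(c("a", "b"), 23))$purity # 0.5
external_measures <- function(x, labels = NULL) {
  ct <- as_contingency(x, labels)
  counts <- ct$counts
  ni <- rowSums(counts)
  nij_star <- counts[cbind(seq_len(nrow(counts)), ct$majority_idx)]
  mj_star <- ct$class_totals[ct$majority_idx]
  prec_i <- nij_star / ni
  rec_i <- nij_star / mj_star
  f_i <- ifelse(prec_i + rec_i == 0, 0,
                2 * prec_i * rec_i / (prec_i + rec_i))
  per <- tibble::tibble(
    cluster = rownames(counts), majority = ct$majority,
    size = as.numeric(ni), precision = as.numeric(prec_i),
    recall = as.numeric(rec_i), f = as.numeric(f_i)
  )
  out <- tibble::tibble(
    purity = sum(ni / ct$n * prec_i),
    precision = mean(prec_i),
    recall = mean(rec_i),
    f_measure = mean(f_i)
  )
  attr(out, "per_cluster") <- per
  out
}

#' @rdname external_measures
#' @export
cluster_purity <- function(x, labels = NULL) external_measures(x, labels)$purity

#' @rdname external_measures
#' @export
cluster_precision <- function(x, labels = NULL) external_measures(x, labels)$precision

#' @rdname external_measures
#' @export
cluster_recall <- function(x, labels = NULL) external_measures(x, labels)$recall

#' @rdname external_measures
#' @export
f_measure <- function(x, labels = NULL) external_measures(x, labels)$f_measure

#' Analytic floors and ceiling of the external measures
#'
#' For a two-class dataset partitioned into exactly `k` non-empty
#' clusters:
#' * the purity and cluster-averaged precision floors equal the largest
#'   class share (all samples collapsed together), 0.5 for balanced
#'   classes;
#' * the cluster-averaged recall floor is found exactly by minimising over
#'   every integer composition of per-cluster class counts (a dynamic
#'   programme over the two remaining class totals), which gives `1/k` for
#'   balanced classes;
#' * every measure is bounded above by 1, attained by a pure and complete
#'   clustering.
#'
#' @param k Number of non-empty clusters (>= 1).
#' @param class_sizes Integer vector of the two class sizes
#'   (default `c(23, 23)`).
#' @return A one-row tibble with columns `min_purity`, `min_precision`,
#'   `min_recall`, `max_all`.
#' @export
#' @examples
#' min_bounds(2)$min_recall  # 0.5
#' min_bounds(4)$min_recall  # 0.25
min_bounds <- function(k, class_sizes = c(23, 23)) {
  if (k < 1) stop("`k` must be at least 1")
  stopifnot(length(class_sizes) == 2, all(class_sizes >= 1))
  if (k > sum(class_sizes))
    stop("`k` exceeds the number of samples; clusters must be non-empty")
  A <- class_sizes[1]; B <- class_sizes[2]

  # per-cluster recall for a cluster holding (i, j) members of each class;
  # majority ties resolve to the first class
  rec_cell <- outer(0:A, 0:B, function(i, j)
    ifelse(i >= j, i / A, j / B))
  rec_cell[1, 1] <- Inf  # clusters must be non-empty

  # dp[a+1, b+1] = min total per-cluster recall using the clusters so far,
  # having consumed a of class 1 and b of class 2
  dp <- matrix(Inf, A + 1, B + 1)
  dp[1, 1] <- 0
  for (step in seq_len(k)) {
    new <- matrix(Inf, A + 1, B + 1)
    for (i in 0:A) for (j in 0:B) {
      if (i == 0 && j == 0) next
      cost <- rec_cell[i + 1, j + 1]
      # adding a cluster with (i, j): shift dp by (i, j) and add cost
      tgt_a <- (i + 1):(A + 1); tgt_b <- (j + 1):(B + 1)
      src_a <- 1:(A + 1 - i); src_b <- 1:(B + 1 - j)
      new[tgt_a, tgt_b] <- pmin(new[tgt_a, tgt_b, drop = FALSE],
                                dp[src_a, src_b, drop = FALSE] + cost)
    }
    dp <- new
  }
  min_rec <- dp[A + 1, B + 1] / k

  tibble::tibble(
    min_purity = max(class_sizes) / sum(class_sizes),
    min_precision = max(class_sizes) / sum(class_sizes),
    min_recall = min_rec,
    max_all = 1
  )
}

#' Compare external measures between sway directions
#'
#' Shapiro-Wilk gated two-sample comparison of a measure's repeated values
#' between the ML and AP directions: if both samples pass the normality
#' check at `alpha`, an independent-samples t-test is used; otherwise a
#' two-sided Mann-Whitney U-test.
#'
#' @param ml_values,ap_values Numeric samples of the measure per direction.
#' @param alpha Normality significance level (default 0.05).
#' @return A one-row tibble with columns `test`, `statistic`, `p_value`,
#'   `normal_ml_p`, `normal_ap_p`.
#' @export
compare_directions <- function(ml_values, ap_values, alpha = 0.05) {
  norm_ml <- suppressWarnings(check_normality(ml_values, alpha))
  norm_ap <- suppressWarnings(check_normality(ap_values, alpha))
  if (norm_ml$is_normal && norm_ap$is_normal) {
    tt <- t.test(ml_values, ap_values, var.equal = TRUE)
    out <- tibble::tibble(test = "t-test",
                          statistic = unname(tt$statistic),
                          p_value = tt$p.value)
  } else {
    wt <- suppressWarnings(
      wilcox.test(ml_values, ap_values, alternative = "two.sided"))
    out <- tibble::tibble(test = "mann-whitney",
                          statistic = unname(wt$statistic),
                          p_value = wt$p.value)
  }
  dplyr::mutate(out, normal_ml_p = norm_ml$p_value,
                normal_ap_p = norm_ap$p_value)
}
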