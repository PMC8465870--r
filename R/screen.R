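#' Shapiro-Wilk normality check
#'
#' @param x Numeric sample of length >= 3.
#' @param alpha Significance level (default 0.05); the sample is called
#'   normal when `p >= alpha`.
#' @return A one-row tibble with columns `p_value`, `is_normal`.
#' @export
check_normality <- function(x, alpha = 0.05) {
  if (length(x) < 3) stop("insufficient data: Shapiro-Wilk needs n >= 3")
  if (sd(x) == 0) {
    warning("constant sample: zero variance, reported non-normal")
    return(tibble::tibble(p_value = 0, is_normal = FALSE))
  }
  p <- shapiro.test(x)$p.value
  tibble::tibble(p_value = p, is_normal = p >= alpha)
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall tau with a two-sided p-value.
#'
#' @param x,y Equal-length numeric samples (n >= 2).
#' @return A one-row tibble with columns `estimate`, `p_value`, `method`.
#' @export
#' @examples
#' kendall_tau(c(1, 2, 3, 4), c(1, 3, 2, 4))$estimate # 2/3
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 2) stop("need at least 2 observations")
  est <- cor(x, y, method = "kendall")
  p <- suppressWarnings(
    cor.test(x, y, method = "kendall", exact = FALSE)$p.value)
  tibble::tibble(estimate = est, p_value = p, method = "kendall")
}

#' Pearson correlation
#'
#' @param x,y Equal-length numeric samples (n >= 3 for a p-value).
#' @return A one-row tibble with columns `estimate`, `p_value`, `method`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(estimate = unname(ct$estimate), p_value = ct$p.value,
                 method = "pearson")
}

#' Screen collinear sway features
#'
#' Normality-gated correlation screen over the candidate RMS features.
#' Each feature's pooled sample (all rows of `features`, so typically both
#' conditions of a pair or the whole cohort for one direction) is first
#' tested with Shapiro-Wilk; a pair of features is correlated with Pearson
#' if both members pass the normality check and with Kendall's tau-b
#' otherwise.  Pairs with `|coefficient| >= threshold` are collinear; one
#' member of each offending pair is dropped, most-correlated pair first,
#' until no pair exceeds the threshold.
#'
#' Which member to drop is governed by `drop_rule`:
#' * `"later"` (default): drop the later-listed feature, i.e. the
#'   higher-order kinematic measure (position < velocity < acceleration).
#'   When velocity and acceleration are interchangeable this retains
#'   position and velocity.
#' * `"mean_abs_corr"`: drop the member with the larger mean absolute
#'   correlation to all other candidate features (ties: later-listed).
#'
#' @param features Feature tibble (rows pooled as supplied) containing the
#'   candidate columns.
#' @param candidates Character vector of feature column names, in kinematic
#'   order.
#' @param threshold Collinearity threshold on `|coefficient|`
#'   (default 0.85).
#' @param alpha Normality significance level (default 0.05).
#' @param drop_rule See Details.
#' @return An object of class `sway_screen`: list with `retained`
#'   (character), `dropped`, `pairs` (tibble: `feature_a`, `feature_b`,
#'   `method`, `estimate`, `p_value`), `normality` (tibble: `feature`,
#'   `p_value`, `is_normal`), `threshold`, `alpha`.
#' @export
screen_features <- function(features,
                            candidates = c("rms_position_cm",
                                           "rms_velocity_cms",
                                           "rms_acceleration_cms2"),
                            threshold = 0.85, alpha = 0.05,
                            drop_rule = c("later", "mean_abs_corr")) {
  drop_rule <- match.arg(drop_rule)
  if (length(candidates) < 2) stop("need at least 2 candidate features")
  stopifnot(all(candidates %in% names(features)))
  vals <- purrr::map(setNames(candidates, candidates),
                     ~ features[[.x]])

  normality <- purrr::imap_dfr(vals, function(v, f)
    dplyr::mutate(check_normality(v, alpha), feature = f, .before = 1))

  pair_idx <- utils::combn(length(candidates), 2)
  pairs <- purrr::map_dfr(seq_len(ncol(pair_idx)), function(k) {
    i <- pair_idx[1, k]; j <- pair_idx[2, k]
    both_normal <- normality$is_normal[i] && normality$is_normal[j]
    res <- if (both_normal) pearson_r(vals[[i]], vals[[j]])
           else kendall_tau(vals[[i]], vals[[j]])
    dplyr::mutate(res, feature_a = candidates[i], feature_b = candidates[j],
                  .before = 1)
  })

  coef_mat <- matrix(0, length(candidates), length(candidates),
                     dimnames = list(candidates, candidates))
  for (k in seq_len(nrow(pairs))) {
    coef_mat[pairs$feature_a[k], pairs$feature_b[k]] <- pairs$estimate[k]
    coef_mat[pairs$feature_b[k], pairs$feature_a[k]] <- pairs$estimate[k]
  }

  retained <- candidates
  repeat {
    cm <- abs(coef_mat[retained, retained, drop = FALSE])
    diag(cm) <- 0
    if (length(retained) < 2 || max(cm) < threshold) break
    worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    a <- retained[worst[1]]; b <- retained[worst[2]]
    later_of <- function(u, v) c(u, v)[which.max(match(c(u, v), candidates))]
    drop <- if (drop_rule == "later") {
      later_of(a, b)
    } else {
      full <- abs(coef_mat[retained, retained, drop = FALSE])
      diag(full) <- NA
      ma <- mean(full[a, ], na.rm = TRUE)
      mb <- mean(full[b, ], na.rm = TRUE)
      if (ma > mb) a
      else if (mb > ma) b
      else later_of(a, b)
    }
    retained <- setdiff(retained, drop)
  }

  structure(list(retained = retained,
                 dropped = setdiff(candidates, retained),
                 pairs = pairs, normality = normality,
                 threshold = threshold, alpha = alpha),
            class = "sway_screen")
}

#' @export
print.sway_screen <- function(x, ...) {
  cat("Feature screen (|coef| >=", x$threshold, "collinear)\n")
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  if (length(x$dropped))
    cat("  dropped: ", paste(x$dropped, collapse = ", "), "\n")
  print(x$pairs)
  invisible(x)
}
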