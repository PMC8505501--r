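# Cycle 1: probability cut-point selection by the screening index and the
# binary HAD/non-HAD classification metrics.
#
# The screening index S = F1 x recall weights threshold selection toward
# recall: the screen must not miss actual HAD use, at the price of false
# positives that the post-hoc readjustment later filters.

#' Screening index
#'
#' The recall-weighted selection criterion for the binary cut point:
#' `S = F1 * recall`. Both arguments must lie in `[0, 1]`; vectorised.
#'
#' @param f1,recall Numeric vectors in `[0, 1]`.
#' @return `f1 * recall`.
#' @export
#' @examples
#' s_index(0.36, 0.83)
s_index <- function(f1, recall) {
  if (any(f1 < 0 | f1 > 1, na.rm = TRUE) ||
      any(recall < 0 | recall > 1, na.rm = TRUE)) {
    abort("`f1` and `recall` must lie in [0, 1].")
  }
  f1 * recall
}

# internal: HAD-class precision/recall/F1 at one cut point.
# Predicted HAD <=> prob > cutpoint (strict); precision is 0 when nothing is
# predicted positive and recall is 0 when there are no actual positives, so
# the scan is total on the grid.
prf_at <- function(probs, actual, cutpoint) {
  pred <- probs > cutpoint
  tp <- sum(pred & actual)
  precision <- if (sum(pred) == 0) 0 else tp / sum(pred)
  recall <- if (sum(actual) == 0) 0 else tp / sum(actual)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Scan probability cut points
#'
#' Computes HAD-class precision, recall, F1 and the screening index on a
#' moving cut point over `[0, 1]`. At each cut point `c` a visit is predicted
#' HAD iff its probability is strictly above `c`.
#'
#' @param probs Numeric vector of per-visit HAD probabilities.
#' @param labels Binary labels aligned with `probs` (factor/character
#'   `"HAD"`/`"non-HAD"`, or logical).
#' @param step Grid step; must divide 1 evenly (default 0.01, matching the
#'   two-decimal rounding of the selected cut point).
#' @return A tibble of class `had_cutpoint_scan` with columns `cutpoint`,
#'   `precision`, `recall`, `f1`, `s_index`.
#' @export
scan_cutpoints <- function(probs, labels, step = 0.01) {
  if (length(probs) == 0) abort("Empty input.")
  if (length(probs) != length(labels)) {
    abort("`probs` and `labels` must be aligned.")
  }
  n_steps <- 1 / step
  if (abs(n_steps - round(n_steps)) > 1e-8) {
    abort("`step` must divide 1 evenly.")
  }
  grid <- (0:round(n_steps)) / round(n_steps)
  actual <- as_binary_label(labels) == "HAD"
  m <- t(vapply(grid, function(cp) prf_at(probs, actual, cp), numeric(3)))
  out <- tibble::tibble(
    cutpoint = grid,
    precision = m[, "precision"],
    recall = m[, "recall"],
    f1 = m[, "f1"],
    s_index = s_index(m[, "f1"], m[, "recall"])
  )
  class(out) <- c("had_cutpoint_scan", class(out))
  out
}

#' Select the S-index-optimal cut point
#'
#' Takes the grid point with the highest screening index (ties break toward
#' the smallest cut point, favouring recall) and rounds it down to two
#' decimal places.
#'
#' @param scan A `had_cutpoint_scan` from [scan_cutpoints()].
#' @return An object of class `had_cutpoint` with elements `value` (the
#'   floored cut point), `s_index` (S at the selected grid point) and
#'   `grid_cutpoint` (the unrounded argmax).
#' @export
select_cutpoint <- function(scan) {
  if (nrow(scan) == 0) abort("Empty scan.")
  idx <- which.max(scan$s_index)  # first maximum = smallest cut point
  structure(
    list(value = floor(scan$cutpoint[idx] * 100) / 100,
         s_index = scan$s_index[idx],
         grid_cutpoint = scan$cutpoint[idx]),
    class = "had_cutpoint"
  )
}

#' @export
print.had_cutpoint <- function(x, ...) {
  cat(sprintf("<had_cutpoint> %.2f (S-index %.4f at grid point %.3f)\n",
              x$value, x$s_index, x$grid_cutpoint))
  invisible(x)
}

#' Classify visits at a cut point
#'
#' A visit is predicted HAD iff its probability is strictly above the cut
#' point; a probability equal to the cut point predicts non-HAD.
#'
#' @param prob Numeric vector of HAD probabilities.
#' @param cutpoint A `had_cutpoint` or a plain number.
#' @return Factor with levels `non-HAD`, `HAD`.
#' @export
classify_binary <- function(prob, cutpoint) {
  value <- if (inherits(cutpoint, "had_cutpoint")) cutpoint$value else cutpoint
  as_binary_label(prob > value)
}

#' Per-class binary performance metrics
#'
#' Accuracy, precision, recall and F1 for both the HAD and non-HAD class,
#' with the actual class counts. Accuracy is the overall fraction correct
#' (identical on both rows); undefined ratios are reported as 0.
#'
#' @param predicted,actual Aligned binary labels.
#' @return A tibble with one row per class: `class`, `accuracy`,
#'   `precision`, `recall`, `f1`, `n`.
#' @export
binary_metrics <- function(predicted, actual) {
  if (length(predicted) == 0) abort("Empty input.")
  if (length(predicted) != length(actual)) abort("Inputs must be aligned.")
  predicted <- as_binary_label(predicted, "predicted")
  actual <- as_binary_label(actual, "actual")
  acc <- mean(predicted == actual)
  per_class <- purrr::map(binary_levels(), function(cls) {
    tp <- sum(predicted == cls & actual == cls)
    precision <- if (sum(predicted == cls) == 0) 0 else tp / sum(predicted == cls)
    recall <- if (sum(actual == cls) == 0) 0 else tp / sum(actual == cls)
    f1 <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    tibble::tibble(class = cls, accuracy = acc, precision = precision,
                   recall = recall, f1 = f1, n = sum(actual == cls))
  })
  purrr::list_rbind(per_class)
}

#' Plot a cut-point scan
#'
#' Precision, recall, F1 and the screening index against the moving cut
#' point, with a vertical line at the selected cut point.
#'
#' @param object A `had_cutpoint_scan`.
#' @param cutpoint Optional `had_cutpoint` (or number) to mark.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.had_cutpoint_scan <- function(object, cutpoint = NULL, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("precision", "recall", "f1", "s_index"),
                              names_to = "metric", values_to = "value")
  long$metric <- factor(long$metric,
                        levels = c("precision", "recall", "f1", "s_index"),
                        labels = c("Precision", "Recall", "F1-score", "S-index"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$cutpoint, y = .data$value,
                                          colour = .data$metric,
                                          linetype = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Probability cut point", y = "Metric value",
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(cutpoint)) {
    value <- if (inherits(cutpoint, "had_cutpoint")) cutpoint$value else cutpoint
    p <- p + ggplot2::geom_vline(xintercept = value, linetype = "dashed")
  }
  p
}

#' @rdname autoplot.had_cutpoint_scan
#' @param scan A `had_cutpoint_scan`.
#' @export
plot_cutpoint_scan <- function(scan, cutpoint = NULL) {
  autoplot.had_cutpoint_scan(scan, cutpoint = cutpoint)
}

#' @export
glance.had_cutpoint_scan <- function(x, ...) {
  sel <- select_cutpoint(x)
  tibble::tibble(cutpoint = sel$value, s_index = sel$s_index,
                 grid_cutpoint = sel$grid_cutpoint, n_grid = nrow(x))
}
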