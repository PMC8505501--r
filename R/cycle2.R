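# Cycle 2: HAD-type classification with P25/P75 uncertainty zones.
#
# Visits passing the cycle-1 cut point are re-labelled with the six
# pharmacological HAD types (plus non-HAD), a multiclass model predicts
# per-type probabilities, and each type's prediction distribution on the
# test set yields two percentile cut points: at or below P25 means no use,
# above P75 means use, and the zone in between is excluded as uncertain.

#' Filter visits by the cycle-1 cut point
#'
#' Visits whose HAD probability is strictly above the selected cut point are
#' included in the type-classification cycle; the rest are retained for
#' evaluation-mode re-screening.
#'
#' @param visits A visit tibble.
#' @param probs Numeric vector of cycle-1 HAD probabilities, one per visit.
#' @param cutpoint A `had_cutpoint` or plain number.
#' @return A list with tibbles `included` and `excluded`, each carrying an
#'   added `prob_had` column.
#' @export
filter_by_cutpoint <- function(visits, probs, cutpoint) {
  if (nrow(visits) != length(probs)) abort("`probs` must align with `visits`.")
  value <- if (inherits(cutpoint, "had_cutpoint")) cutpoint$value else cutpoint
  visits <- dplyr::mutate(visits, prob_had = probs)
  keep <- probs > value
  list(included = visits[keep, , drop = FALSE],
       excluded = visits[!keep, , drop = FALSE])
}

#' Percentile cut points per HAD type
#'
#' Computes the 25th and 75th percentile of each type's predicted
#' probabilities over the test set, by linear interpolation between closest
#' ranks. With `pooled = TRUE` the percentiles are computed once over all
#' six types' predictions and shared.
#'
#' @param predictions A tibble of per-visit type probabilities with one
#'   column per HAD type (as returned by [predict_had()] for a type model).
#' @param types Types to process (default [had_types()]); the `non-HAD`
#'   column is never interpreted.
#' @param pooled Pool predictions across types before taking percentiles?
#' @return A tibble of class `had_type_cutpoints` with columns `type`,
#'   `p25`, `p75`.
#' @export
percentile_cutpoints <- function(predictions, types = had_types(),
                                 pooled = FALSE) {
  missing_types <- setdiff(types, names(predictions))
  if (length(missing_types) > 0) {
    abort(sprintf("Prediction columns missing for type(s): %s",
                  paste(missing_types, collapse = ", ")))
  }
  if (pooled) {
    all_p <- unlist(predictions[types], use.names = FALSE)
    if (length(all_p) < 2) abort("Need at least 2 predictions.")
    q <- quantile(all_p, c(0.25, 0.75), type = 7, names = FALSE)
    out <- tibble::tibble(type = types, p25 = q[1], p75 = q[2])
  } else {
    out <- purrr::map(types, function(tt) {
      p <- predictions[[tt]]
      if (length(p) < 2) {
        abort(sprintf("Fewer than 2 predictions for type %s.", tt))
      }
      q <- quantile(p, c(0.25, 0.75), type = 7, names = FALSE)
      tibble::tibble(type = tt, p25 = q[1], p75 = q[2])
    }) |> purrr::list_rbind()
  }
  class(out) <- c("had_type_cutpoints", class(out))
  out
}

# internal: the three-rule tri-state interpretation. The no-use rule
# (prob <= P25) is applied before the use rule, so P25 = P75 with
# prob = P25 resolves to no_use.
tri_state <- function(prob, p25, p75) {
  out <- ifelse(prob <= p25, "no_use", ifelse(prob > p75, "use", "uncertain"))
  factor(out, levels = c("no_use", "uncertain", "use"))
}

#' Tri-state interpretation of type probabilities
#'
#' Applies the three rules per type: probability at or below P25 means no
#' use of that type, above P75 means use, and the P25–P75 band is the
#' uncertainty zone excluded from interpretation.
#'
#' @inheritParams percentile_cutpoints
#' @param cuts A `had_type_cutpoints` tibble.
#' @return A tibble with `txn` (if present in `predictions`) and one
#'   tri-state factor column per type.
#' @export
classify_type <- function(predictions, cuts) {
  out <- if ("txn" %in% names(predictions)) {
    tibble::tibble(txn = predictions$txn)
  } else {
    tibble::tibble(.rows = nrow(predictions))
  }
  for (k in seq_len(nrow(cuts))) {
    tt <- cuts$type[k]
    out[[tt]] <- tri_state(predictions[[tt]], cuts$p25[k], cuts$p75[k])
  }
  out
}

#' Interpret the per-type confusion
#'
#' For each HAD type: a `use` call on a visit that was actually prescribed
#' that type counts as a true positive, a `use` call without actual use a
#' false positive, a `no_use` call with actual use a false negative, a
#' `no_use` call without actual use a true negative, and `uncertain` calls
#' are excluded. The non-HAD column is never interpreted.
#'
#' @param tristates A tibble with `txn` and one tri-state column per type
#'   (see [classify_type()]).
#' @param actual_types A list-column (or list) of per-visit character
#'   vectors of actually prescribed HAD types, aligned with `tristates`.
#' @param types Types to interpret (default [had_types()]).
#' @return A tibble of class `had_type_confusion` with per-type counts
#'   `tp`, `fp`, `fn`, `tn`, `excluded` and derived `accuracy`,
#'   `precision`, `recall`, `f1`, `n` (actual positives).
#' @export
interpret_type_confusion <- function(tristates, actual_types,
                                     types = had_types()) {
  if (nrow(tristates) != length(actual_types)) {
    abort("`actual_types` must align with `tristates`.")
  }
  out <- purrr::map(types, function(tt) {
    call <- tristates[[tt]]
    act <- purrr::map_lgl(actual_types, ~ tt %in% .x)
    tp <- sum(call == "use" & act)
    fp <- sum(call == "use" & !act)
    fn <- sum(call == "no_use" & act)
    tn <- sum(call == "no_use" & !act)
    excluded <- sum(call == "uncertain")
    denom <- tp + fp + fn + tn
    precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
    recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
    tibble::tibble(
      type = tt, tp = tp, fp = fp, fn = fn, tn = tn, excluded = excluded,
      accuracy = if (denom == 0) NA_real_ else (tp + tn) / denom,
      precision = precision, recall = recall,
      f1 = if (precision + recall == 0) 0 else
        2 * precision * recall / (precision + recall),
      n = sum(act)
    )
  }) |> purrr::list_rbind()
  class(out) <- c("had_type_confusion", class(out))
  out
}

#' Per-ICD10 prevalence of one HAD type (ICD10 percent)
#'
#' The percentage of visits carrying an ICD10 code that were prescribed at
#' least one high-alert drug of the given type — the per-type analogue of
#' [compute_had_percent()], used to validate type-level predictions against
#' prescribing practice.
#'
#' @param visits A visit tibble.
#' @param registry A `had_registry`.
#' @param type One of [had_types()].
#' @param min_total Denominator below which an entry is flagged
#'   `low_reliability` (default 5).
#' @return A tibble of class `had_percent_table` with columns `icd10`,
#'   `had_visits`, `total_visits`, `had_percent`, `low_reliability`; the
#'   type is recorded in attribute `"had_type"`.
#' @export
icd10_percent <- function(visits, registry, type, min_total = 5) {
  if (!type %in% had_types()) {
    abort(sprintf("`type` must be one of %s.",
                  paste(had_types(), collapse = ", ")))
  }
  type_registry <- registry[registry$had_type == type, , drop = FALSE]
  tab <- compute_had_percent(visits, type_registry, min_total = min_total)
  attr(tab, "had_type") <- type
  tab
}

#' Adjust per-type confusion counts by HAD-use likelihood
#'
#' Applies the prevalence-based confusion adjustment independently within
#' each HAD type: `use`/`no_use` calls play the role of predicted HAD /
#' non-HAD, actual use of the type the role of the actual label, and the
#' likelihood comes from that type's own prevalence table. Counts are
#' conserved within each type.
#'
#' @param records A tibble with columns `type`, `predicted` (`"use"` /
#'   `"no_use"`; uncertain calls must already be excluded), `actual`
#'   (logical: was the type actually prescribed) and `likelihood`
#'   (`"low"`/`"high"` from that type's prevalence table).
#' @return A tibble of class `had_type_adjustment`: one row per type with
#'   raw counts, `fp_high`, `fn_low` and adjusted counts.
#' @export
adjust_type_confusion <- function(records) {
  if (nrow(records) == 0) abort("Empty input.")
  if (!all(records$predicted %in% c("use", "no_use"))) {
    abort("`predicted` must be 'use' or 'no_use' (exclude uncertain calls first).")
  }
  out <- records |>
    dplyr::group_by(.data$type) |>
    dplyr::group_map(function(g, key) {
      adj <- adjust_confusion(tibble::tibble(
        predicted = ifelse(g$predicted == "use", "HAD", "non-HAD"),
        actual = ifelse(g$actual, "HAD", "non-HAD"),
        likelihood = g$likelihood
      ))
      tibble::tibble(
        type = key$type,
        tp = adj$tp, fp = adj$fp, fn = adj$fn, tn = adj$tn,
        fp_high = adj$fp_high, fn_low = adj$fn_low,
        atp = adj$atp, afp = adj$afp, afn = adj$afn, atn = adj$atn,
        n = adj$n
      )
    }) |> purrr::list_rbind()
  class(out) <- c("had_type_adjustment", class(out))
  out
}

#' Plot per-type screening performance
#'
#' Bar chart of precision, recall and F1 by HAD type, showing the screening
#' character of the type cycle (high recall, tolerant precision).
#'
#' @param object A `had_type_confusion`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.had_type_confusion <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("precision", "recall", "f1"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$type, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "HAD type", y = "Metric value", fill = NULL) +
    ggplot2::theme_minimal()
}
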