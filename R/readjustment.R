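# Post-hoc result readjustment: per-ICD10 HAD-use prevalence ("HAD percent"),
# visit-level high/low likelihood, adjustment of the confusion matrix, and
# the per-ICD10 specific false-negative ratio.
#
# The readjustment separates unusual-but-harmless prescriptions from probable
# errors: a false positive whose diagnoses frequently co-occur with HAD is
# reinterpreted as a true positive, and a false negative whose diagnoses
# rarely co-occur with HAD is reinterpreted as a true negative.

#' Per-ICD10 HAD-use prevalence (HAD percent)
#'
#' For every ICD10 code, the percentage of visits carrying that code that
#' were prescribed at least one high-alert drug:
#' `had_percent = 100 * had_visits / total_visits`.
#'
#' When `sample_size` is given, whole visits are drawn in a random
#' prescription-weighted order (inclusion probability proportional to a
#' visit's prescription count) until the sampled prescriptions reach
#' `sample_size`; this mirrors estimating the table from a fixed-size random
#' prescription sample. The default uses all visits.
#'
#' @param visits A visit tibble (see [aggregate_visits()]).
#' @param registry A `had_registry`.
#' @param sample_size Optional number of prescriptions to sample; `NULL`
#'   (default) uses all visits.
#' @param seed Seed for the sampling step (only used with `sample_size`).
#' @param min_total Denominator below which an entry is flagged
#'   `low_reliability` (default 5): prevalence from a handful of visits is a
#'   weak signal.
#' @return A tibble of class `had_percent_table` with columns `icd10`,
#'   `had_visits`, `total_visits`, `had_percent`, `low_reliability`;
#'   sampling metadata is stored in attributes.
#' @export
compute_had_percent <- function(visits, registry, sample_size = NULL,
                                seed = 1, min_total = 5) {
  if (!is.null(sample_size)) {
    if (sample_size <= 0) abort("`sample_size` must be positive.")
    ord <- withr::with_seed(seed, sample.int(nrow(visits),
                                             prob = visits$total_drugs))
    keep <- ord[cumsum(visits$total_drugs[ord]) <= sample_size]
    if (length(keep) == 0) keep <- ord[1]
    visits <- visits[sort(keep), , drop = FALSE]
  }
  labelled <- label_binary(visits, registry)
  tab <- labelled |>
    dplyr::select("txn", "icd10", "label") |>
    tidyr::unnest_longer("icd10") |>
    dplyr::distinct(.data$txn, .data$icd10, .keep_all = TRUE) |>
    dplyr::group_by(.data$icd10) |>
    dplyr::summarise(
      had_visits = sum(.data$label == "HAD"),
      total_visits = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      had_percent = 100 * .data$had_visits / .data$total_visits,
      low_reliability = .data$total_visits < min_total
    )
  attr(tab, "sample_size") <- sample_size
  attr(tab, "seed") <- if (is.null(sample_size)) NA_integer_ else seed
  attr(tab, "n_visits") <- nrow(visits)
  class(tab) <- c("had_percent_table", class(tab))
  tab
}

#' Classify visits as high or low HAD-use likelihood
#'
#' A visit is `high` likelihood iff at least one of its ICD10 codes has a
#' HAD percent at or above the threshold. Codes absent from the table
#' contribute no evidence; a visit none of whose codes are covered is
#' classed `low` (and counted in a message).
#'
#' @param visits A visit tibble.
#' @param table A `had_percent_table`.
#' @param threshold HAD-percent threshold separating high from low HAD use
#'   (percent; default 50).
#' @return `visits` with added columns `likelihood` (factor `low`/`high`)
#'   and `icd10_covered` (any code present in the table).
#' @export
visit_likelihood <- function(visits, table, threshold = 50) {
  high_codes <- table$icd10[table$had_percent >= threshold]
  covered_codes <- table$icd10
  visits <- visits |>
    dplyr::mutate(
      likelihood = factor(
        ifelse(purrr::map_lgl(.data$icd10, ~ any(.x %in% high_codes)),
               "high", "low"),
        levels = c("low", "high")),
      icd10_covered = purrr::map_lgl(.data$icd10,
                                     ~ length(.x) > 0 && any(.x %in% covered_codes))
    )
  n_uncovered <- sum(!visits$icd10_covered)
  if (n_uncovered > 0) {
    inform(sprintf(
      "%d visit(s) with no ICD10 covered by the HAD-percent table; classed low.",
      n_uncovered))
  }
  visits
}

#' Adjust a confusion matrix by HAD-use likelihood
#'
#' Recomputes the four confusion counts using the prevalence evidence:
#' false positives with high likelihood become adjusted true positives
#' (`aFP = FP - FP_high`, `aTP = TP + FP_high`) and false negatives with low
#' likelihood become adjusted true negatives (`aFN = FN - FN_low`,
#' `aTN = TN + FN_low`). Totals are conserved.
#'
#' @param records A tibble with columns `predicted` and `actual` (binary
#'   labels) and `likelihood` (`"low"`/`"high"`), one row per visit.
#' @return An object of class `had_confusion_adjustment` with the raw
#'   counts, the reassigned counts (`fp_high`, `fn_low`) and the adjusted
#'   counts.
#' @export
adjust_confusion <- function(records) {
  if (nrow(records) == 0) abort("Empty input.")
  predicted <- as_binary_label(records$predicted, "predicted")
  actual <- as_binary_label(records$actual, "actual")
  likelihood <- as.character(records$likelihood)
  if (!all(likelihood %in% c("low", "high"))) {
    abort("`likelihood` must be 'low' or 'high'.")
  }
  tp <- sum(predicted == "HAD" & actual == "HAD")
  fp <- sum(predicted == "HAD" & actual == "non-HAD")
  fn <- sum(predicted == "non-HAD" & actual == "HAD")
  tn <- sum(predicted == "non-HAD" & actual == "non-HAD")
  fp_high <- sum(predicted == "HAD" & actual == "non-HAD" & likelihood == "high")
  fn_low <- sum(predicted == "non-HAD" & actual == "HAD" & likelihood == "low")
  structure(
    list(tp = tp, fp = fp, fn = fn, tn = tn,
         fp_high = fp_high, fn_low = fn_low,
         atp = tp + fp_high, afp = fp - fp_high,
         afn = fn - fn_low, atn = tn + fn_low,
         n = nrow(records)),
    class = "had_confusion_adjustment"
  )
}

#' @export
print.had_confusion_adjustment <- function(x, ...) {
  cat("<had_confusion_adjustment>\n")
  cat(sprintf("  raw:      TP %d  FP %d  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  adjusted: aTP %d aFP %d aFN %d aTN %d  (FP_high %d, FN_low %d)\n",
              x$atp, x$afp, x$afn, x$atn, x$fp_high, x$fn_low))
  invisible(x)
}

#' @export
tidy.had_confusion_adjustment <- function(x, ...) {
  tibble::tibble(
    count = c("tp", "fp", "fn", "tn"),
    raw = c(x$tp, x$fp, x$fn, x$tn),
    adjusted = c(x$atp, x$afp, x$afn, x$atn)
  )
}

#' @export
glance.had_confusion_adjustment <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    accuracy = (x$tp + x$tn) / x$n,
    adjusted_accuracy = (x$atp + x$atn) / x$n,
    fp_high = x$fp_high, fn_low = x$fn_low
  )
}

#' Specific false-negative ratio per ICD10
#'
#' For each ICD10 code, the number of false-negative visits carrying that
#' code divided by the total visits carrying it
#' (`sfnr = fn_count / total_visits`). A visit contributes to every ICD10 it
#' carries. Low sFNR for a code means the screen rarely misses HAD use under
#' that diagnosis.
#'
#' @param records A tibble with columns `txn`, `predicted`, `actual` and an
#'   `icd10` list-column (the visit's code set).
#' @param table Optional `had_percent_table`; when given, `had_percent` is
#'   joined in so entries can be ranked by prevalence.
#' @return A tibble `icd10`, `fn_count`, `total_visits`, `sfnr` (plus
#'   `had_percent` when `table` is supplied), sorted by `had_percent`
#'   descending when available.
#' @export
specific_fnr <- function(records, table = NULL) {
  fn_flag <- as_binary_label(records$predicted, "predicted") == "non-HAD" &
    as_binary_label(records$actual, "actual") == "HAD"
  out <- records |>
    dplyr::mutate(.fn = fn_flag) |>
    dplyr::select("txn", "icd10", ".fn") |>
    tidyr::unnest_longer("icd10") |>
    dplyr::distinct(.data$txn, .data$icd10, .keep_all = TRUE) |>
    dplyr::group_by(.data$icd10) |>
    dplyr::summarise(
      fn_count = sum(.data$.fn),
      total_visits = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(sfnr = .data$fn_count / .data$total_visits)
  if (!is.null(table)) {
    out <- out |>
      dplyr::left_join(
        dplyr::select(tibble::as_tibble(table), "icd10", "had_percent"),
        by = "icd10") |>
      dplyr::arrange(dplyr::desc(.data$had_percent))
  }
  out
}

#' Plot the HAD-percent distribution
#'
#' Histogram of per-ICD10 HAD percent with the likelihood threshold marked;
#' the mass near 0 and near 100 shows how separable high- from low-HAD-use
#' diagnoses are.
#'
#' @param object A `had_percent_table`.
#' @param threshold Threshold to mark (default 50).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.had_percent_table <- function(object, threshold = 50, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$had_percent)) +
    ggplot2::geom_histogram(binwidth = 5, boundary = 0,
                            fill = "grey40", colour = "white") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "HAD percent", y = "ICD10 codes") +
    ggplot2::theme_minimal()
}
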