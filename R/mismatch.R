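# HAD-ICD10 mismatch reporting.
#
# A visit that actually received a high-alert drug, that the model predicted
# non-HAD, and whose diagnoses all show low HAD-use prevalence is a mismatch
# candidate — a probable prescription error to be reviewed by a clinician.
# The same pattern with high prevalence is instead a model
# misclassification. Adjudicating a candidate's cause (incomplete ICD10,
# incorrect ICD10, or a genuinely wrong prescription) is a human step; the
# report carries the evidence, not a verdict.

#' Flag HAD-ICD10 mismatch candidates
#'
#' Every visit with an actual HAD prescription and a non-HAD prediction is
#' categorised: `mismatch_candidate` when its HAD-use likelihood is low,
#' `model_misclassification` when it is high. Each distinct high-alert drug
#' of such a visit contributes one candidate row (the drug-level summary
#' tallies drugs, not visits).
#'
#' @param records A tibble with one row per visit and columns `txn`,
#'   `predicted`, `actual` (binary labels), `likelihood` (`"low"`/`"high"`),
#'   `drugs` (list-column of drug codes), `icd10` (list-column), and
#'   optionally `prob_had` and `setting`.
#' @param registry A `had_registry` used to identify the visit's high-alert
#'   drugs and their names.
#' @return A tibble with one row per (visit, HAD drug): `txn`, `drug_code`,
#'   `drug_name`, `had_type`, `category`, `likelihood`, `icd10` (list),
#'   plus `prob_had` and `setting` when present in `records`.
#' @export
flag_candidates <- function(records, registry) {
  predicted <- as_binary_label(records$predicted, "predicted")
  actual <- as_binary_label(records$actual, "actual")
  keep <- actual == "HAD" & predicted == "non-HAD"
  hits <- records[keep, , drop = FALSE]
  if (nrow(hits) == 0) {
    return(tibble::tibble(
      txn = character(), drug_code = character(), drug_name = character(),
      had_type = character(), category = character(), likelihood = character(),
      icd10 = list()))
  }
  hits$category <- ifelse(as.character(hits$likelihood) == "low",
                          "mismatch_candidate", "model_misclassification")
  out <- hits |>
    dplyr::mutate(drug_code = purrr::map(.data$drugs,
                                         ~ unique(.x[.x %in% registry$drug_code]))) |>
    tidyr::unnest_longer("drug_code") |>
    dplyr::mutate(
      drug_name = registry$drug_name[match(.data$drug_code, registry$drug_code)],
      had_type = had_type_of(.data$drug_code, registry),
      likelihood = as.character(.data$likelihood)
    )
  keep_cols <- intersect(
    c("txn", "drug_code", "drug_name", "had_type", "category", "likelihood",
      "prob_had", "setting", "icd10"),
    names(out))
  out[, keep_cols]
}

#' Drug-level mismatch summary
#'
#' Tallies candidates per drug and setting (OPD/IPD) and reports each drug's
#' share of all candidates, sorted by total count descending, with a totals
#' row appended.
#'
#' @param candidates A candidate tibble from [flag_candidates()], typically
#'   filtered to `category == "mismatch_candidate"`. Rows lacking a
#'   `setting` column are counted as OPD.
#' @return A tibble of class `had_mismatch_summary` with columns
#'   `drug_name`, `opd`, `ipd`, `total`, `proportion` (percent of all
#'   candidates, one decimal).
#' @export
summarize_mismatches <- function(candidates) {
  if (nrow(candidates) == 0) {
    out <- tibble::tibble(drug_name = "Total", opd = 0L, ipd = 0L,
                          total = 0L, proportion = NA_real_)
    class(out) <- c("had_mismatch_summary", class(out))
    return(out)
  }
  if (!"setting" %in% names(candidates)) candidates$setting <- "OPD"
  if (!"drug_name" %in% names(candidates)) {
    candidates$drug_name <- candidates$drug_code
  }
  tab <- candidates |>
    dplyr::count(.data$drug_name, .data$setting) |>
    tidyr::pivot_wider(names_from = "setting", values_from = "n",
                       values_fill = 0L)
  for (col in c("OPD", "IPD")) if (!col %in% names(tab)) tab[[col]] <- 0L
  grand_total <- nrow(candidates)
  out <- tab |>
    dplyr::transmute(
      drug_name = .data$drug_name,
      opd = .data$OPD, ipd = .data$IPD,
      total = .data$OPD + .data$IPD,
      proportion = round(100 * .data$total / grand_total, 1)
    ) |>
    dplyr::arrange(dplyr::desc(.data$total))
  totals <- tibble::tibble(
    drug_name = "Total",
    opd = sum(out$opd), ipd = sum(out$ipd), total = sum(out$total),
    proportion = round(sum(out$proportion), 1)
  )
  out <- dplyr::bind_rows(out, totals)
  class(out) <- c("had_mismatch_summary", class(out))
  out
}
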