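# Reading and writing prescription tables and the HAD registry.
#
# The canonical prescription table has one row per prescribed drug:
#   txn        visit identifier (character; one hospital visit)
#   gender     "male" / "female"
#   age        integer years, >= 0
#   icd10      one diagnosis code (may repeat across rows of a visit)
#   drug_code  prescribed drug identifier
#   drug_name  human-readable drug name

prescription_fields <- function() {
  c("txn", "gender", "age", "icd10", "drug_code", "drug_name")
}

#' Read a visit-level prescription table
#'
#' Reads a delimited text file with one prescription per row and validates it
#' against the canonical schema. Rows violating a row-level invariant
#' (missing or empty `txn` or `drug_code`, unparseable or negative `age`) are
#' rejected with a warning; a missing mandatory column is an error.
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter (default `","`).
#' @param col_map Optional named character vector mapping canonical field
#'   names (`txn`, `gender`, `age`, `icd10`, `drug_code`, `drug_name`) to the
#'   column names used in the file, e.g. `c(txn = "visit_id")`.
#' @return A tibble with the six canonical columns. The number of rejected
#'   rows is attached as attribute `"n_rejected"`.
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' sim <- simulate_prescriptions(scenario_preset("clean", n_visits = 20))
#' write_prescriptions(sim$prescriptions, path)
#' rx <- read_prescriptions(path)
#' attr(rx, "n_rejected")
read_prescriptions <- function(path, delim = ",", col_map = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  wanted <- prescription_fields()
  file_names <- setNames(wanted, wanted)
  if (!is.null(col_map)) file_names[names(col_map)] <- unname(col_map)
  missing_cols <- setdiff(unname(file_names), names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("Mandatory column(s) missing from %s: %s",
                  path, paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::tibble(
    txn       = raw[[file_names[["txn"]]]],
    gender    = tolower(raw[[file_names[["gender"]]]]),
    age       = suppressWarnings(as.integer(raw[[file_names[["age"]]]])),
    icd10     = raw[[file_names[["icd10"]]]],
    drug_code = raw[[file_names[["drug_code"]]]],
    drug_name = raw[[file_names[["drug_name"]]]]
  )
  ok <- !is.na(out$txn) & nzchar(out$txn) &
    !is.na(out$drug_code) & nzchar(out$drug_code) &
    !is.na(out$age) & out$age >= 0
  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    warn(sprintf("Rejected %d malformed prescription row(s) from %s.",
                 n_rejected, path))
  }
  out <- out[ok, , drop = FALSE]
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Write a prescription table
#'
#' Inverse of [read_prescriptions()]: writes the canonical columns as
#' delimited text so that a write/read round trip preserves all fields.
#'
#' @param rows A tibble of prescription rows.
#' @param path Output file path.
#' @inheritParams read_prescriptions
#' @return `path`, invisibly.
#' @export
write_prescriptions <- function(rows, path, delim = ",") {
  readr::write_delim(rows[, prescription_fields()], path, delim = delim)
  invisible(path)
}

#' Read a high-alert-drug registry
#'
#' The registry lists every high-alert drug with its group (Institutional HAD
#' list category) and pharmacological type. Drugs absent from the registry
#' are by definition not high-alert. A HAD row missing its type, an unknown
#' group/type label, or a duplicated `drug_code` is an error.
#'
#' @param path Path to a CSV (columns `drug_code`, `drug_name`, `had_group`,
#'   `had_type`) or a JSON array of objects with those fields.
#' @return A tibble of class `had_registry`.
#' @seealso [default_registry()] for the packaged registry.
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    reg <- tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    reg <- readr::read_csv(path, col_types = readr::cols(
      .default = readr::col_character()
    ), progress = FALSE)
  }
  required <- c("drug_code", "had_group", "had_type")
  missing_cols <- setdiff(required, names(reg))
  if (length(missing_cols) > 0) {
    abort(sprintf("Registry is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (!"drug_name" %in% names(reg)) reg$drug_name <- reg$drug_code
  reg <- reg[, c("drug_code", "drug_name", "had_group", "had_type")]
  if (anyDuplicated(reg$drug_code)) {
    abort("Registry has duplicate drug_code entries; each drug must map to exactly one entry.")
  }
  if (any(is.na(reg$had_type) | !nzchar(reg$had_type))) {
    abort("Every registry (HAD) row must carry a had_type.")
  }
  bad_group <- setdiff(unique(reg$had_group), had_groups())
  if (length(bad_group) > 0) {
    abort(sprintf("Unknown had_group value(s): %s", paste(bad_group, collapse = ", ")))
  }
  bad_type <- setdiff(unique(reg$had_type), had_types())
  if (length(bad_type) > 0) {
    abort(sprintf("Unknown had_type value(s): %s", paste(bad_type, collapse = ", ")))
  }
  class(reg) <- c("had_registry", class(reg))
  reg
}

#' Packaged default HAD registry
#'
#' The registry shipped with the package: the institutional high-alert drug
#' list (general HADs, narcotics and psychotropic drugs, intravenous and oral
#' cytotoxic chemotherapy) with each drug's pharmacological type (ANS, BIG,
#' CVS, CNS, END, Tumor).
#'
#' @return A tibble of class `had_registry`.
#' @export
#' @examples
#' reg <- default_registry()
#' reg[reg$drug_name == "Digoxin", ]
default_registry <- function() {
  read_registry(system.file("extdata", "had_registry.csv",
                            package = "hadscreen", mustWork = TRUE))
}

#' Is a drug a high-alert drug?
#'
#' @param drug_code Character vector of drug codes.
#' @param registry A `had_registry` tibble.
#' @return `is_had()`: logical vector; `had_type_of()`: character vector of
#'   HAD types with `NA` for non-HAD drugs.
#' @export
is_had <- function(drug_code, registry) {
  drug_code %in% registry$drug_code
}

#' @rdname is_had
#' @export
had_type_of <- function(drug_code, registry) {
  registry$had_type[match(drug_code, registry$drug_code)]
}

#' Aggregate prescription rows into visits
#'
#' Collapses a prescription table to one record per visit (`txn`): the
#' deduplicated ICD10 set, the multiset of prescribed drug codes, and the
#' total number of prescriptions — the `total_drugs` feature. Conflicting
#' gender or age within a visit keeps the first occurrence with a warning.
#' Visits without any ICD10 code are retained and flagged (`no_icd10`); they
#' contribute no diagnosis-level prevalence evidence downstream.
#'
#' @param rows A tibble of prescription rows (see [read_prescriptions()]).
#' @return A tibble with one row per visit: `txn`, `gender`, `age`, `icd10`
#'   (list-column of unique codes), `drugs` (list-column of drug codes),
#'   `total_drugs`, `no_icd10`.
#' @export
aggregate_visits <- function(rows) {
  if (nrow(rows) == 0) abort("No prescription rows to aggregate.")
  conflicts <- rows |>
    dplyr::group_by(.data$txn) |>
    dplyr::summarise(
      g = dplyr::n_distinct(.data$gender, na.rm = TRUE),
      a = dplyr::n_distinct(.data$age, na.rm = TRUE),
      .groups = "drop"
    )
  n_conflict <- sum(conflicts$g > 1 | conflicts$a > 1)
  if (n_conflict > 0) {
    warn(sprintf(
      "%d visit(s) with conflicting gender/age; keeping first occurrence.",
      n_conflict))
  }
  visits <- rows |>
    dplyr::group_by(.data$txn) |>
    dplyr::summarise(
      gender = dplyr::first(.data$gender),
      age = dplyr::first(.data$age),
      icd10 = list(unique(.data$icd10[!is.na(.data$icd10) & nzchar(.data$icd10)])),
      drugs = list(.data$drug_code),
      total_drugs = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(no_icd10 = lengths(.data$icd10) == 0)
  visits
}
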