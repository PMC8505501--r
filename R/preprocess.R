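# Feature construction and labelling for both screening cycles.
#
# Cycle-1 features: male indicator, age, one 0/1 indicator per ICD10 code in
# the training vocabulary, and total_drugs. Cycle 2 appends the cycle-1 HAD
# probability. Drug identities are never features — they are the labels.

#' Label visits as HAD or non-HAD
#'
#' A visit is labelled `HAD` when at least one of its prescriptions is on the
#' high-alert drug registry; otherwise `non-HAD`.
#'
#' @param visits A visit tibble (see [aggregate_visits()]).
#' @param registry A `had_registry` tibble.
#' @return `visits` with an added factor column `label`
#'   (levels `non-HAD`, `HAD`).
#' @export
label_binary <- function(visits, registry) {
  had <- purrr::map_lgl(visits$drugs, function(d) any(d %in% registry$drug_code))
  dplyr::mutate(visits, label = as_binary_label(had))
}

#' Expand visits into HAD-type instances
#'
#' The type-classification cycle works on one instance per distinct HAD type
#' prescribed in a visit; a visit with no high-alert prescription contributes
#' exactly one `non-HAD` instance. All instances of a visit share its feature
#' row — only the label differs.
#'
#' @inheritParams label_binary
#' @return A tibble with the visit columns plus a factor `type_label`
#'   over the seven classes ([type_levels()]).
#' @export
expand_type_instances <- function(visits, registry) {
  types <- purrr::map(visits$drugs, function(d) {
    tt <- unique(had_type_of(d, registry))
    tt <- tt[!is.na(tt)]
    if (length(tt) == 0) "non-HAD" else tt
  })
  visits |>
    dplyr::mutate(type_label = types) |>
    tidyr::unnest_longer("type_label") |>
    dplyr::mutate(type_label = factor(.data$type_label, levels = type_levels()))
}

#' Build the model feature matrix
#'
#' Encodes visits into the fixed tabular schema: `male` (0/1), `age`
#' (years), one 0/1 indicator per ICD10 code in the vocabulary,
#' `total_drugs`, and — when `cycle1_prob` is supplied — the cycle-1 HAD
#' probability `had_prob`. The ICD10 vocabulary is frozen at fit time by
#' passing `vocabulary = NULL` on training data and reusing the returned
#' vocabulary at predict time; codes outside the vocabulary are dropped (an
#' unseen code carries no learned signal) and counted in a message.
#'
#' @param visits A visit tibble.
#' @param vocabulary Character vector of ICD10 codes defining the indicator
#'   columns, or `NULL` to derive it from `visits`.
#' @param cycle1_prob Optional numeric vector in `[0, 1]`, one per visit: the
#'   cycle-1 HAD probability feature used by the type-classification cycle.
#' @return An object of class `had_features`: a list with the sparse matrix
#'   `x`, the `vocabulary`, the column manifest `columns`, and the visit
#'   `txn`s.
#' @export
build_features <- function(visits, vocabulary = NULL, cycle1_prob = NULL) {
  n <- nrow(visits)
  if (!is.null(cycle1_prob)) {
    if (length(cycle1_prob) != n) {
      abort("`cycle1_prob` must have one value per visit.")
    }
    if (any(cycle1_prob < 0 | cycle1_prob > 1, na.rm = TRUE)) {
      abort("`cycle1_prob` values must lie in [0, 1].")
    }
  }
  observed <- unique(unlist(visits$icd10))
  if (is.null(vocabulary)) {
    vocabulary <- sort(observed)
  } else {
    unseen <- setdiff(observed, vocabulary)
    if (length(unseen) > 0) {
      inform(sprintf("Dropping %d ICD10 code(s) outside the fitted vocabulary.",
                     length(unseen)))
    }
  }
  codes <- visits$icd10
  i <- rep.int(seq_len(n), lengths(codes))
  j <- match(unlist(codes), vocabulary)
  keep <- !is.na(j)
  ind <- Matrix::sparseMatrix(
    i = i[keep], j = j[keep], x = 1,
    dims = c(n, length(vocabulary)),
    dimnames = list(NULL, vocabulary)
  )
  male <- as.numeric(visits$gender == "male")
  male[is.na(male)] <- 0
  left <- Matrix::Matrix(cbind(male = male, age = as.numeric(visits$age)),
                         sparse = TRUE)
  right <- Matrix::Matrix(cbind(total_drugs = as.numeric(visits$total_drugs)),
                          sparse = TRUE)
  x <- cbind(left, ind, right)
  if (!is.null(cycle1_prob)) {
    x <- cbind(x, Matrix::Matrix(cbind(had_prob = as.numeric(cycle1_prob)),
                                 sparse = TRUE))
  }
  x <- methods::as(x, "CsparseMatrix")
  structure(
    list(x = x, vocabulary = vocabulary, columns = colnames(x),
         txn = visits$txn),
    class = "had_features"
  )
}

#' @export
print.had_features <- function(x, ...) {
  cat(sprintf("<had_features> %d visits x %d columns (%d ICD10 indicators)\n",
              nrow(x$x), ncol(x$x), length(x$vocabulary)))
  invisible(x)
}

#' @export
dim.had_features <- function(x) dim(x$x)

#' Deterministic shuffled train/test split
#'
#' Shuffles rows with the given seed and splits them into train and test
#' sets at the given ratio. The test-set size is `N * (1 - ratio)` rounded
#' half up, so a 75:25 split of 35,268 visits yields an 8,817-visit test set.
#'
#' @param data A data frame (or vector) of items to split.
#' @param ratio Training fraction, strictly between 0 and 1 (default 0.75).
#' @param seed Integer seed; equal seeds give identical partitions.
#' @return A list with elements `train` and `test`.
#' @export
split_train_test <- function(data, ratio = 0.75, seed = 1) {
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  if (n < 2) abort("Need at least 2 items to split.")
  if (!(ratio > 0 && ratio < 1)) abort("`ratio` must be in (0, 1).")
  n_test <- round_half_up(n * (1 - ratio))
  n_test <- max(1L, min(n - 1L, n_test))
  idx <- withr::with_seed(seed, sample.int(n))
  test_idx <- sort(idx[seq_len(n_test)])
  train_idx <- sort(idx[-seq_len(n_test)])
  if (is.data.frame(data)) {
    list(train = data[train_idx, , drop = FALSE],
         test = data[test_idx, , drop = FALSE])
  } else {
    list(train = data[train_idx], test = data[test_idx])
  }
}
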