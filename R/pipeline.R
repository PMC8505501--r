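# End-to-end orchestration of the two screening cycles.
#
# run_cycle1(): label -> split -> fit the boosted binary model -> scan and
# select the S-index cut point -> metrics -> HAD-percent table -> likelihood
# -> confusion adjustment -> sFNR -> mismatch candidates on the test set.
#
# run_cycle2(): score all visits with the cycle-1 model -> filter by the
# cut point -> expand to type instances -> fit the multiclass model ->
# P25/P75 tri-state interpretation -> per-type confusion and adjustment ->
# per-type ICD10 percent -> evaluation-mode re-screen of excluded visits.

#' Allocate visits between the two cycles
#'
#' Randomly draws (without replacement) the visits used to develop the
#' binary classification cycle; the remainder is reserved for the
#' type-classification cycle.
#'
#' @param visits A visit tibble.
#' @param n_cycle1 Number of visits for cycle 1.
#' @param seed Integer seed.
#' @return A list with tibbles `cycle1` and `cycle2`.
#' @export
allocate_cycles <- function(visits, n_cycle1, seed = 1) {
  n <- nrow(visits)
  if (n_cycle1 < 1 || n_cycle1 >= n) {
    abort("`n_cycle1` must be in [1, nrow(visits) - 1].")
  }
  idx <- withr::with_seed(seed, sample.int(n, n_cycle1))
  list(cycle1 = visits[sort(idx), , drop = FALSE],
       cycle2 = visits[-sort(idx), , drop = FALSE])
}

#' Run the binary HAD classification cycle
#'
#' @param visits A visit tibble (see [aggregate_visits()]).
#' @param registry A `had_registry`.
#' @param setting `"OPD"` or `"IPD"`; models, cut points and prevalence
#'   tables are never shared across settings.
#' @param ratio Train fraction of the shuffled fixed split (default 0.75).
#' @param seed Integer seed driving the split and the model fit.
#' @param step Cut-point grid step (default 0.01).
#' @param max_depth_grid Depth grid for the boosted model.
#' @param nrounds Boosting rounds.
#' @param threshold HAD-percent threshold for high/low likelihood
#'   (percent; default 50).
#' @param sample_size Optional prescription sample size for the HAD-percent
#'   table (default: all visits).
#' @return An object of class `had_cycle1` holding the fitted model, the
#'   cut-point scan and selection, test-set metrics, the HAD-percent table,
#'   the confusion adjustment, the sFNR table, the mismatch candidates and
#'   a reproducibility manifest.
#' @export
run_cycle1 <- function(visits, registry, setting = c("OPD", "IPD"),
                       ratio = 0.75, seed = 1, step = 0.01,
                       max_depth_grid = c(1L, 2L, 3L), nrounds = 100,
                       threshold = 50, sample_size = NULL) {
  setting <- match.arg(setting)
  labelled <- label_binary(visits, registry)
  parts <- split_train_test(labelled, ratio = ratio, seed = seed)
  train_features <- build_features(parts$train)
  test_features <- build_features(parts$test,
                                  vocabulary = train_features$vocabulary)
  model <- fit_had_classifier(train_features, parts$train$label,
                              max_depth_grid = max_depth_grid,
                              nrounds = nrounds, seed = seed)
  test_probs <- predict_had(model, test_features)$prob_had
  scan <- scan_cutpoints(test_probs, parts$test$label, step = step)
  cutpoint <- select_cutpoint(scan)
  predicted <- classify_binary(test_probs, cutpoint)
  metrics <- binary_metrics(predicted, parts$test$label)
  had_percent <- compute_had_percent(labelled, registry,
                                     sample_size = sample_size, seed = seed)
  test_eval <- visit_likelihood(parts$test, had_percent,
                                threshold = threshold) |>
    dplyr::mutate(predicted = predicted, actual = .data$label,
                  prob_had = test_probs, setting = setting)
  adjustment <- adjust_confusion(test_eval)
  sfnr <- specific_fnr(test_eval, table = had_percent)
  candidates <- flag_candidates(test_eval, registry)
  manifest <- list(
    stage = "cycle1", setting = setting, seed = seed, ratio = ratio,
    step = step, max_depth_grid = as.integer(max_depth_grid),
    nrounds = nrounds, threshold = threshold,
    sample_size = sample_size, n_visits = nrow(visits),
    package_version = as.character(utils::packageVersion("hadscreen"))
  )
  manifest$hash <- rlang::hash(manifest)
  structure(
    list(model = model, scan = scan, cutpoint = cutpoint,
         metrics = metrics, had_percent = had_percent,
         adjustment = adjustment, sfnr = sfnr, candidates = candidates,
         test = test_eval, manifest = manifest),
    class = "had_cycle1"
  )
}

#' @export
print.had_cycle1 <- function(x, ...) {
  cat(sprintf("<had_cycle1> [%s] cut point %.2f; test HAD recall %.2f, precision %.2f\n",
              x$manifest$setting, x$cutpoint$value,
              x$metrics$recall[x$metrics$class == "HAD"],
              x$metrics$precision[x$metrics$class == "HAD"]))
  invisible(x)
}

#' Run the HAD type classification cycle
#'
#' Scores fresh visits with the cycle-1 model, keeps those above the
#' selected cut point, fits the seven-class type model on the expanded type
#' instances, interprets the test-set predictions through the P25/P75
#' tri-state rules, adjusts the per-type confusion by each type's own
#' prevalence table, and re-screens the excluded visits with actual HAD use
#' for mismatch candidates (evaluation mode).
#'
#' @param visits A visit tibble (typically the cycle-2 allocation).
#' @param registry A `had_registry`.
#' @param cycle1 A `had_cycle1` result providing the trained binary model
#'   and the selected cut point.
#' @param ratio,seed,nrounds,threshold As in [run_cycle1()].
#' @param max_depth_grid Depth grid for the multiclass model (default: the
#'   depth selected in cycle 1).
#' @param pooled Pool the P25/P75 percentiles across types?
#' @return An object of class `had_cycle2` with the filtered sets, the type
#'   model, type cut points, tri-state calls, per-type confusion (raw and
#'   adjusted), per-type prevalence tables, evaluation-mode mismatch
#'   candidates, and a manifest.
#' @export
run_cycle2 <- function(visits, registry, cycle1, ratio = 0.75, seed = 2,
                       nrounds = 100, threshold = 50,
                       max_depth_grid = NULL, pooled = FALSE) {
  stopifnot(inherits(cycle1, "had_cycle1"))
  if (is.null(cycle1$cutpoint)) abort("cycle1 result carries no cut point.")
  if (is.null(max_depth_grid)) max_depth_grid <- cycle1$model$max_depth
  labelled <- label_binary(visits, registry)
  feats <- build_features(labelled, vocabulary = cycle1$model$vocabulary)
  probs <- predict_had(cycle1$model, feats)$prob_had
  parts0 <- filter_by_cutpoint(labelled, probs, cycle1$cutpoint)
  included <- parts0$included
  excluded <- parts0$excluded

  # evaluation mode: excluded visits with actual HAD, re-screened by
  # prevalence and routed to the mismatch report
  excluded_eval <- visit_likelihood(excluded, cycle1$had_percent,
                                    threshold = threshold) |>
    dplyr::mutate(predicted = factor("non-HAD", levels = binary_levels()),
                  actual = .data$label,
                  setting = cycle1$manifest$setting)
  evaluation_candidates <- flag_candidates(excluded_eval, registry)

  instances <- expand_type_instances(included, registry)
  parts <- split_train_test(instances, ratio = ratio, seed = seed)
  train_features <- build_features(parts$train,
                                   vocabulary = cycle1$model$vocabulary,
                                   cycle1_prob = parts$train$prob_had)
  test_features <- build_features(parts$test,
                                  vocabulary = cycle1$model$vocabulary,
                                  cycle1_prob = parts$test$prob_had)
  type_model <- fit_had_classifier(train_features, parts$train$type_label,
                                   max_depth_grid = max_depth_grid,
                                   nrounds = nrounds, seed = seed)
  predictions <- predict_had(type_model, test_features)
  observed_types <- intersect(had_types(), names(predictions))
  cuts <- percentile_cutpoints(predictions, types = observed_types,
                               pooled = pooled)
  tristates <- classify_type(predictions, cuts)

  # one interpreted row per test visit: its actual type set
  test_visits <- parts$test |>
    dplyr::distinct(.data$txn, .keep_all = TRUE)
  actual_types <- purrr::map(test_visits$drugs, function(d) {
    tt <- unique(had_type_of(d, registry)); tt[!is.na(tt)]
  })
  visit_tristates <- tristates |>
    dplyr::distinct(.data$txn, .keep_all = TRUE) |>
    dplyr::left_join(tibble::tibble(txn = test_visits$txn,
                                    .row = seq_len(nrow(test_visits))),
                     by = "txn")
  actual_types <- actual_types[visit_tristates$.row]
  test_visits <- test_visits[visit_tristates$.row, , drop = FALSE]
  visit_tristates$.row <- NULL
  confusion <- interpret_type_confusion(visit_tristates, actual_types,
                                        types = observed_types)

  # per-type prevalence tables and likelihood-adjusted confusion
  type_tables <- purrr::map(observed_types,
                            ~ icd10_percent(labelled, registry, .x))
  names(type_tables) <- observed_types
  type_records <- purrr::map(observed_types, function(tt) {
    call <- visit_tristates[[tt]]
    keep <- call != "uncertain"
    if (!any(keep)) return(NULL)
    lk <- visit_likelihood(test_visits[keep, , drop = FALSE],
                           type_tables[[tt]], threshold = threshold)
    tibble::tibble(
      type = tt,
      predicted = as.character(call[keep]),
      actual = purrr::map_lgl(actual_types[keep], ~ tt %in% .x),
      likelihood = as.character(lk$likelihood)
    )
  }) |> purrr::list_rbind()
  adjusted <- adjust_type_confusion(type_records)

  manifest <- list(
    stage = "cycle2", setting = cycle1$manifest$setting, seed = seed,
    ratio = ratio, nrounds = nrounds, threshold = threshold,
    pooled = pooled, cutpoint = cycle1$cutpoint$value,
    n_visits = nrow(visits), cycle1_hash = cycle1$manifest$hash,
    package_version = as.character(utils::packageVersion("hadscreen"))
  )
  manifest$hash <- rlang::hash(manifest)
  structure(
    list(included = included, excluded = excluded,
         evaluation_candidates = evaluation_candidates,
         model = type_model, predictions = predictions,
         type_cutpoints = cuts, tristates = visit_tristates,
         confusion = confusion, adjusted = adjusted,
         type_tables = type_tables, manifest = manifest),
    class = "had_cycle2"
  )
}

#' @export
print.had_cycle2 <- function(x, ...) {
  cat(sprintf(
    "<had_cycle2> [%s] %d included / %d excluded; mean type recall %.2f\n",
    x$manifest$setting, nrow(x$included), nrow(x$excluded),
    mean(x$confusion$recall)))
  invisible(x)
}

#' Write run artifacts to a directory
#'
#' Exports a cycle result as plain CSV/JSON files plus a `manifest.json`
#' recording seeds, parameters and the configuration hash, so a rerun from
#' the manifest reproduces identical outputs.
#'
#' @param result A `had_cycle1` or `had_cycle2` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_artifacts <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w_json <- function(x, f) jsonlite::write_json(
    x, file.path(dir, f), auto_unbox = TRUE, digits = NA, na = "null")
  if (inherits(result, "had_cycle1")) {
    readr::write_csv(tibble::as_tibble(result$scan), file.path(dir, "scan.csv"))
    w_json(unclass(result$cutpoint), "cutpoint.json")
    readr::write_csv(result$metrics, file.path(dir, "metrics.csv"))
    readr::write_csv(tibble::as_tibble(result$had_percent),
                     file.path(dir, "had_percent.csv"))
    w_json(unclass(result$adjustment), "confusion_adjustment.json")
    readr::write_csv(result$sfnr, file.path(dir, "sfnr.csv"))
    readr::write_csv(dplyr::select(result$candidates, -dplyr::any_of("icd10")),
                     file.path(dir, "mismatch_candidates.csv"))
  } else if (inherits(result, "had_cycle2")) {
    readr::write_csv(tibble::as_tibble(result$type_cutpoints),
                     file.path(dir, "type_cutpoints.csv"))
    readr::write_csv(tibble::as_tibble(result$confusion),
                     file.path(dir, "type_confusion.csv"))
    readr::write_csv(tibble::as_tibble(result$adjusted),
                     file.path(dir, "type_confusion_adjusted.csv"))
    for (tt in names(result$type_tables)) {
      readr::write_csv(tibble::as_tibble(result$type_tables[[tt]]),
                       file.path(dir, sprintf("icd10_percent_%s.csv", tt)))
    }
    readr::write_csv(
      dplyr::select(result$evaluation_candidates, -dplyr::any_of("icd10")),
      file.path(dir, "evaluation_mismatch_candidates.csv"))
  } else {
    abort("`result` must be a had_cycle1 or had_cycle2 object.")
  }
  w_json(result$manifest, "manifest.json")
  invisible(dir)
}
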