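# Shared synthetic association data: one strongly HAD-linked code, one
# weakly linked code.
assoc_visits <- function(n, seed) {
  withr::with_seed(seed, {
    code <- sample(c("HI", "LO"), n, replace = TRUE)
    p <- ifelse(code == "HI", 0.95, 0.05)
    had <- stats::runif(n) < p
    toy_visits(
      icd10 = as.list(code),
      drugs = lapply(had, function(h) if (h) c("D1", "N1") else "N1"),
      gender = sample(c("male", "female"), n, replace = TRUE),
      age = sample(20:80, n, replace = TRUE)
    )
  })
}

test_that("the most-frequent-class baseline matches the class balance", {
  n <- 400
  v <- toy_visits(
    icd10 = rep(list("X"), n),
    drugs = c(rep(list("D1"), 0.16 * n), rep(list("N1"), 0.84 * n))
  )
  lab <- label_binary(v, toy_registry())
  f <- build_features(lab)
  rep <- benchmark_classifiers(f, lab$label, families = "dummy", seed = 1)
  expect_equal(attr(rep, "baseline_accuracy"), 0.84, tolerance = 0.01)
})

test_that("non-trivial families separate perfectly separable data", {
  # label is a deterministic function of a single diagnosis indicator
  v <- assoc_visits(300, seed = 2)
  lab <- label_binary(v, toy_registry())
  det <- lab
  det$label <- factor(ifelse(purrr::map_lgl(det$icd10, ~ "HI" %in% .x),
                             "HAD", "non-HAD"), levels = binary_levels())
  f <- build_features(det)
  rep <- benchmark_classifiers(
    f, det$label, families = c("dummy", "decision_tree", "gradient_boosting"),
    seed = 3)
  accs <- rep$accuracy[rep$family != "dummy"]
  expect_true(all(accs == 1))
  expect_true(all(rep$accuracy >= 0 & rep$accuracy <= 1))
  expect_gte(min(accs), attr(rep, "baseline_accuracy"))
  expect_equal(attr(rep, "selected_family"), "decision_tree")
})

test_that("the boosted ensemble beats the baseline on association data", {
  v <- assoc_visits(500, seed = 4)
  lab <- label_binary(v, toy_registry())
  f <- build_features(lab)
  rep <- benchmark_classifiers(f, lab$label,
                               families = c("dummy", "gradient_boosting"),
                               seed = 5)
  expect_gt(rep$accuracy[rep$family == "gradient_boosting"],
            attr(rep, "baseline_accuracy"))
  rep2 <- benchmark_classifiers(f, lab$label,
                                families = c("dummy", "gradient_boosting"),
                                seed = 5)
  expect_equal(tibble::as_tibble(rep), tibble::as_tibble(rep2))
})

test_that("a failing family is recorded and excluded from selection", {
  v <- assoc_visits(60, seed = 6)
  lab <- label_binary(v, toy_registry())
  f <- build_features(lab)
  rep <- benchmark_classifiers(f, lab$label,
                               families = c("dummy", "no_such_family",
                                            "gradient_boosting"),
                               seed = 1)
  expect_true(rep$failed[rep$family == "no_such_family"])
  expect_equal(attr(rep, "selected_family"), "gradient_boosting")
})

test_that("depth search prefers stumps when stumps suffice", {
  v <- assoc_visits(600, seed = 8)
  lab <- label_binary(v, toy_registry())
  f <- build_features(lab)
  model <- fit_had_classifier(f, lab$label, max_depth_grid = c(1, 3), seed = 9)
  expect_equal(model$max_depth, 1L)
  expect_equal(nrow(model$cv), 2)
  single <- fit_had_classifier(f, lab$label, max_depth_grid = 2, seed = 9)
  expect_equal(single$max_depth, 2L)
  expect_true(all(is.na(single$cv$cv_accuracy)))
})

test_that("single-class labels are fatal", {
  v <- toy_visits(icd10 = list("X", "Y"), drugs = list("N1", "N2"))
  lab <- label_binary(v, toy_registry())
  f <- build_features(lab)
  expect_error(fit_had_classifier(f, lab$label), "single class")
})

test_that("a serialised model reloads with identical predictions", {
  v <- assoc_visits(200, seed = 10)
  lab <- label_binary(v, toy_registry())
  f <- build_features(lab)
  model <- fit_had_classifier(f, lab$label, max_depth_grid = 1, seed = 11)
  p1 <- predict_had(model, f)
  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(model, path)
  p2 <- predict_had(readRDS(path), f)
  expect_identical(p1, p2)
})

test_that("predicted probabilities respect their contracts", {
  v <- assoc_visits(300, seed = 12)
  lab <- label_binary(v, toy_registry())
  f <- build_features(lab)
  model <- fit_had_classifier(f, lab$label, max_depth_grid = 1, seed = 13)
  p <- predict_had(model, f)
  expect_true(all(p$prob_had >= 0 & p$prob_had <= 1))
  # duplicate rows score identically
  dup <- v[c(1, 1), ]
  pd <- predict_had(model, build_features(dup, vocabulary = f$vocabulary))
  expect_equal(pd$prob_had[1], pd$prob_had[2])
  # strong association separates mean probabilities
  hi <- purrr::map_lgl(v$icd10, ~ "HI" %in% .x)
  expect_gt(mean(p$prob_had[hi]), mean(p$prob_had[!hi]))
  # column-manifest mismatch is fatal
  other <- build_features(toy_visits(icd10 = list("Q"), drugs = list("N1")))
  expect_error(predict_had(model, other), "manifest")
})

test_that("multiclass probability vectors are normalised", {
  sim <- simulate_prescriptions(
    scenario_preset("mismatch_rich", n_visits = 400, seed = 14))
  v <- aggregate_visits(sim$prescriptions)
  inst <- expand_type_instances(v, sim$registry)
  f <- build_features(inst)
  model <- fit_had_classifier(f, inst$type_label, max_depth_grid = 1,
                              nrounds = 30, seed = 15)
  p <- predict_had(model, f)
  pm <- as.matrix(p[, model$classes])
  expect_true(all(pm >= 0 & pm <= 1))
  expect_equal(unname(rowSums(pm)), rep(1, nrow(pm)), tolerance = 1e-9)
})

test_that("lasso relevance ranks a planted signal above noise", {
  withr::with_seed(16, {
    n <- 300
    signal <- sample(0:1, n, replace = TRUE)
    codes <- purrr::map2(signal, sample(paste0("N", 1:8), n, replace = TRUE),
                         function(s, nz) c(if (s == 1) "SIG", nz))
    v <- toy_visits(icd10 = codes,
                    drugs = lapply(signal, function(s) if (s == 1) "D1" else "N1"))
  })
  lab <- label_binary(v, toy_registry())
  f <- build_features(lab)
  rel <- feature_relevance(f, lab$label, penalty = 0.01, k = 5)
  expect_lte(nrow(rel), 10)
  expect_equal(rel$feature[1], "SIG")
  expect_equal(rel$direction[1], "positive")
  noise <- rel$coefficient[grepl("^N", rel$feature)]
  if (length(noise) > 0) {
    expect_lt(max(abs(noise)), rel$coefficient[1])
  }
})
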