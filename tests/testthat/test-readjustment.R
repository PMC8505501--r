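test_that("HAD percent is the per-diagnosis visit proportion", {
  v <- toy_visits(
    icd10 = list("X", "X", "X", "X", "Y"),
    drugs = list(c("D1", "N1"), "D2", "N1", "N2", "N1")
  )
  tab <- compute_had_percent(v, toy_registry())
  x <- tab[tab$icd10 == "X", ]
  expect_equal(x$had_visits, 2L)
  expect_equal(x$total_visits, 4L)
  expect_equal(x$had_percent, 50)
  expect_equal(tab$had_percent[tab$icd10 == "Y"], 0)
  expect_true(all(tab$low_reliability))
})

test_that("the estimator recovers a planted association within binomial error", {
  p <- 0.9; n <- 500
  v <- bernoulli_visits(n, "X", p, seed = 31)
  tab <- compute_had_percent(v, toy_registry())
  se3 <- 3 * sqrt(p * (1 - p) / n) * 100
  expect_lt(abs(tab$had_percent - 90), se3)
})

test_that("the estimator is unbiased over replicates", {
  p <- 0.7
  est <- vapply(1:200, function(i) {
    v <- bernoulli_visits(300, "X", p, seed = 1000 + i)
    compute_had_percent(v, toy_registry())$had_percent
  }, numeric(1))
  expect_lt(abs(mean(est) - 70), 1)
})

test_that("prescription-weighted sampling honours the budget and the seed", {
  v <- toy_visits(
    icd10 = rep(list("X"), 50),
    drugs = rep(list(c("D1", "N1", "N2")), 50)
  )
  tab <- compute_had_percent(v, toy_registry(), sample_size = 30, seed = 3)
  expect_lte(tab$total_visits, 10)  # 3 prescriptions per sampled visit
  tab2 <- compute_had_percent(v, toy_registry(), sample_size = 30, seed = 3)
  expect_equal(tibble::as_tibble(tab), tibble::as_tibble(tab2))
  expect_error(compute_had_percent(v, toy_registry(), sample_size = 0),
               "positive")
})

test_that("visit likelihood uses the any-high-code rule", {
  tab <- tibble::tibble(icd10 = c("A", "B", "C"),
                        had_visits = c(92L, 10L, 49L),
                        total_visits = c(100L, 100L, 100L),
                        had_percent = c(92, 10, 49),
                        low_reliability = FALSE)
  class(tab) <- c("had_percent_table", class(tab))
  v <- toy_visits(icd10 = list(c("A", "B"), c("B", "C"), "Z"),
                  drugs = list("N1", "N1", "N1"))
  out <- suppressMessages(visit_likelihood(v, tab, threshold = 50))
  expect_equal(as.character(out$likelihood), c("high", "low", "low"))
  expect_equal(out$icd10_covered, c(TRUE, TRUE, FALSE))
  # threshold exactly at a code's percent counts as high
  out49 <- suppressMessages(visit_likelihood(v, tab, threshold = 49))
  expect_equal(as.character(out49$likelihood)[2], "high")
})

test_that("confusion adjustment reproduces the worked false-negative example", {
  records <- tibble::tibble(
    predicted = rep("non-HAD", 130),
    actual = rep("HAD", 130),
    likelihood = c(rep("low", 97), rep("high", 33))
  )
  adj <- adjust_confusion(records)
  expect_equal(adj$fn, 130L)
  expect_equal(adj$fn_low, 97L)
  expect_equal(adj$afn, 33L)
  expect_equal(adj$atn, 97L)
})

test_that("high-likelihood false positives migrate to adjusted true positives", {
  records <- tibble::tibble(
    predicted = c("HAD", "HAD", "HAD"),
    actual = c("non-HAD", "non-HAD", "HAD"),
    likelihood = c("high", "high", "low")
  )
  adj <- adjust_confusion(records)
  expect_equal(adj$afp, 0L)
  expect_equal(adj$atp, 3L)
  td <- tidy(adj)
  expect_equal(td$adjusted[td$count == "fp"], 0L)
  expect_equal(sum(td$adjusted), adj$n)
})

test_that("adjustment conserves totals on random records", {
  withr::with_seed(32, {
    records <- tibble::tibble(
      predicted = sample(binary_levels(), 1000, replace = TRUE),
      actual = sample(binary_levels(), 1000, replace = TRUE),
      likelihood = sample(c("low", "high"), 1000, replace = TRUE)
    )
  })
  adj <- adjust_confusion(records)
  expect_equal(adj$atp + adj$afp + adj$afn + adj$atn, 1000L)
  expect_equal(adj$tp + adj$fp + adj$fn + adj$tn, 1000L)
  expect_true(all(c(adj$atp, adj$afp, adj$afn, adj$atn) >= 0))
})

test_that("raising the likelihood threshold moves aFP up and aFN down", {
  withr::with_seed(33, {
    v <- toy_visits(
      icd10 = as.list(sample(LETTERS[1:6], 200, replace = TRUE)),
      drugs = lapply(runif(200) < 0.4,
                     function(h) if (h) c("D1", "N1") else "N1")
    )
  })
  tab <- compute_had_percent(v, toy_registry())
  predicted <- withr::with_seed(34,
    sample(binary_levels(), 200, replace = TRUE))
  lab <- label_binary(v, toy_registry())
  prev_afp <- -1L; prev_afn <- .Machine$integer.max
  for (thr in c(20, 50, 80)) {
    lk <- visit_likelihood(v, tab, threshold = thr)
    adj <- adjust_confusion(tibble::tibble(
      predicted = predicted, actual = lab$label, likelihood = lk$likelihood))
    expect_gte(adj$afp, prev_afp)
    expect_lte(adj$afn, prev_afn)
    prev_afp <- adj$afp; prev_afn <- adj$afn
  }
})

test_that("specific false-negative ratios match per-code counting", {
  v <- toy_visits(
    icd10 = list("X", "X", "X", "X", "Y"),
    drugs = list(c("D1"), "D1", "N1", "N1", "D1")
  )
  records <- label_binary(v, toy_registry()) |>
    dplyr::mutate(predicted = c("non-HAD", "HAD", "non-HAD", "non-HAD", "HAD"),
                  actual = label)
  out <- specific_fnr(records)
  x <- out[out$icd10 == "X", ]
  expect_equal(x$fn_count, 1L)
  expect_equal(x$total_visits, 4L)
  expect_equal(x$sfnr, 0.25)
  expect_equal(out$sfnr[out$icd10 == "Y"], 0)

  # randomised cross-check against a brute-force per-code loop
  withr::with_seed(35, {
    vr <- toy_visits(
      icd10 = replicate(80, sample(LETTERS[1:5], sample(1:3, 1)),
                        simplify = FALSE),
      drugs = lapply(runif(80) < 0.5,
                     function(h) if (h) "D1" else "N1")
    )
    pred <- sample(binary_levels(), 80, replace = TRUE)
  })
  rec <- label_binary(vr, toy_registry()) |>
    dplyr::mutate(predicted = pred, actual = label)
  out2 <- specific_fnr(rec)
  for (k in seq_len(nrow(out2))) {
    code <- out2$icd10[k]
    carries <- vapply(vr$icd10, function(s) code %in% s, logical(1))
    fn <- sum(carries & pred == "non-HAD" & rec$label == "HAD")
    expect_equal(out2$fn_count[k], fn)
    expect_equal(out2$total_visits[k], sum(carries))
  }
  expect_true(all(out2$sfnr >= 0 & out2$sfnr <= 1))
})
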