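# Model benchmarking, the gradient-boosted screening model, and lasso-based
# feature relevance.
#
# The learner itself is xgboost (stumps by default: the depth grid is tuned
# by cross-validated accuracy and ties break toward the smallest depth); the
# screening protocol built around it is what this package contributes.

# internal: stratified fold assignment, deterministic given seed
stratified_folds <- function(labels, folds, seed) {
  assign <- integer(length(labels))
  withr::with_seed(seed, {
    for (lv in unique(labels)) {
      idx <- which(labels == lv)
      assign[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  assign
}

# internal: fit one benchmark family on a dense training block and return
# predicted class labels for the test block
fit_predict_family <- function(family, x_train, y_train, x_test, seed) {
  lev <- levels(y_train)
  switch(
    family,
    dummy = {
      most <- names(which.max(table(y_train)))
      factor(rep(most, nrow(x_test)), levels = lev)
    },
    decision_tree = {
      if (!requireNamespace("rpart", quietly = TRUE)) abort("rpart unavailable")
      df <- as.data.frame(as.matrix(x_train)); df$.y <- y_train
      fit <- rpart::rpart(.y ~ ., data = df, method = "class")
      predict(fit, as.data.frame(as.matrix(x_test)), type = "class")
    },
    sgd = {
      # regularised linear classifier (coordinate-descent logistic lasso),
      # the linear-model entry of the roster
      fit <- glmnet::glmnet(x_train, y_train, family = "binomial",
                            lambda = 1e-4)
      p <- predict(fit, x_test, type = "response")[, 1]
      factor(ifelse(p > 0.5, lev[2], lev[1]), levels = lev)
    },
    knn = {
      if (!requireNamespace("class", quietly = TRUE)) abort("class unavailable")
      withr::with_seed(seed, class::knn(as.matrix(x_train), as.matrix(x_test),
                                        y_train, k = 5))
    },
    naive_bayes = {
      if (!requireNamespace("e1071", quietly = TRUE)) abort("e1071 unavailable")
      fit <- e1071::naiveBayes(as.matrix(x_train), y_train)
      predict(fit, as.matrix(x_test))
    },
    random_forest = {
      if (!requireNamespace("ranger", quietly = TRUE)) abort("ranger unavailable")
      df <- as.data.frame(as.matrix(x_train))
      names(df) <- make.names(names(df)); df$.y <- y_train
      fit <- ranger::ranger(.y ~ ., data = df, num.trees = 100, seed = seed,
                            num.threads = 1)
      dft <- as.data.frame(as.matrix(x_test)); names(dft) <- make.names(names(dft))
      predict(fit, dft, num.threads = 1)$predictions
    },
    gradient_boosting = {
      booster <- fit_xgb(x_train, y_train, max_depth = 3, nrounds = 50,
                         eta = 0.3, seed = seed)
      p <- predict_xgb(booster, x_test, levels(y_train))
      factor(lev[max.col(p)], levels = lev)
    },
    abort(sprintf("Unknown classifier family: %s", family))
  )
}

#' Benchmark candidate classifier families
#'
#' Runs stratified k-fold cross-validation of the requested classifier
#' families against a most-frequent-class baseline and reports mean accuracy
#' per family. A family that fails to fit is recorded as failed and excluded
#' from selection. Stratification is used because HAD class balance can be
#' as skewed as 92:8.
#'
#' @param features A `had_features` object (see [build_features()]).
#' @param labels Factor of binary labels aligned with the feature rows.
#' @param families Character vector of family names among `"dummy"`,
#'   `"decision_tree"`, `"sgd"`, `"knn"`, `"naive_bayes"`,
#'   `"random_forest"`, `"gradient_boosting"`.
#' @param folds Number of cross-validation folds (default 3).
#' @param seed Integer seed; results are deterministic given the seed.
#' @return A tibble of class `had_benchmark` with columns `family`,
#'   `accuracy`, `failed`; attributes `baseline_accuracy` and
#'   `selected_family` (maximal mean accuracy among non-baseline families).
#' @export
benchmark_classifiers <- function(features, labels,
                                  families = c("dummy", "decision_tree", "sgd",
                                               "knn", "naive_bayes",
                                               "random_forest",
                                               "gradient_boosting"),
                                  folds = 3, seed = 1) {
  stopifnot(inherits(features, "had_features"))
  if (folds < 2) abort("`folds` must be at least 2.")
  labels <- as_binary_label(labels)
  fold_of <- stratified_folds(labels, folds, seed)
  res <- purrr::map(families, function(fam) {
    accs <- tryCatch({
      vapply(seq_len(folds), function(k) {
        tr <- fold_of != k
        pred <- fit_predict_family(fam, features$x[tr, , drop = FALSE],
                                   droplevels(labels[tr]),
                                   features$x[!tr, , drop = FALSE], seed + k)
        mean(as.character(pred) == as.character(labels[!tr]))
      }, numeric(1))
    }, error = function(e) NULL)
    if (is.null(accs)) {
      tibble::tibble(family = fam, accuracy = NA_real_, failed = TRUE)
    } else {
      tibble::tibble(family = fam, accuracy = mean(accs), failed = FALSE)
    }
  }) |> purrr::list_rbind()
  candidates <- res[!res$failed & res$family != "dummy", ]
  selected <- if (nrow(candidates) > 0) {
    candidates$family[which.max(candidates$accuracy)]
  } else {
    NA_character_
  }
  attr(res, "baseline_accuracy") <-
    if ("dummy" %in% res$family) res$accuracy[res$family == "dummy"] else NA_real_
  attr(res, "selected_family") <- selected
  attr(res, "folds") <- folds
  attr(res, "seed") <- seed
  class(res) <- c("had_benchmark", class(res))
  res
}

#' @export
print.had_benchmark <- function(x, ...) {
  cat(sprintf("<had_benchmark> %d-fold stratified CV; selected: %s\n",
              attr(x, "folds"), attr(x, "selected_family")))
  print(tibble::as_tibble(x))
  invisible(x)
}

# internal: train an xgboost booster (binary or multiclass) --------------

fit_xgb <- function(x, y, max_depth, nrounds, eta, seed) {
  lev <- levels(y)
  if (length(lev) == 2) {
    params <- list(objective = "binary:logistic", max_depth = max_depth,
                   eta = eta, nthread = 1, seed = seed)
    dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
  } else {
    params <- list(objective = "multi:softprob", num_class = length(lev),
                   max_depth = max_depth, eta = eta, nthread = 1, seed = seed)
    dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
  }
  xgboost::xgb.train(params = params, data = dtrain, nrounds = nrounds,
                     verbose = 0)
}

# internal: probability matrix with one column per class
predict_xgb <- function(booster, x, classes) {
  p <- predict(booster, xgboost::xgb.DMatrix(x))
  if (length(classes) == 2) {
    cbind(1 - p, p)
  } else if (is.matrix(p)) {
    unname(p)
  } else {
    matrix(p, ncol = length(classes), byrow = TRUE)
  }
}

#' Fit the gradient-boosted screening model
#'
#' Grid-searches `max_depth` by stratified cross-validated accuracy (ties
#' break toward the smallest depth, trading model efficacy against
#' simplicity), then fits the selected gradient-boosted tree ensemble on all
#' rows. Works for both the binary HAD screen (two label levels) and the
#' seven-class HAD-type screen.
#'
#' @inheritParams benchmark_classifiers
#' @param labels Factor with two or more levels; a single observed class is
#'   an error.
#' @param max_depth_grid Integer vector of candidate tree depths.
#' @param nrounds Number of boosting rounds (default 100).
#' @param eta Learning rate (default 0.3).
#' @return An object of class `had_model`: the serialised booster, the
#'   column manifest, the class levels, the selected depth and the CV table.
#' @export
fit_had_classifier <- function(features, labels, max_depth_grid = c(1L, 2L, 3L),
                               nrounds = 100, eta = 0.3, folds = 3, seed = 1) {
  stopifnot(inherits(features, "had_features"))
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) abort("Labels contain a single class; cannot fit.")
  max_depth_grid <- sort(unique(as.integer(max_depth_grid)))
  if (length(max_depth_grid) > 1) {
    fold_of <- stratified_folds(labels, folds, seed)
    cv <- purrr::map(max_depth_grid, function(d) {
      accs <- vapply(seq_len(folds), function(k) {
        tr <- fold_of != k
        booster <- fit_xgb(features$x[tr, , drop = FALSE], labels[tr],
                           max_depth = d, nrounds = nrounds, eta = eta,
                           seed = seed)
        p <- predict_xgb(booster, features$x[!tr, , drop = FALSE],
                         levels(labels))
        mean(levels(labels)[max.col(p)] == as.character(labels[!tr]))
      }, numeric(1))
      tibble::tibble(max_depth = d, cv_accuracy = mean(accs))
    }) |> purrr::list_rbind()
    best_depth <- cv$max_depth[which.max(cv$cv_accuracy)]  # first max = smallest depth
  } else {
    cv <- tibble::tibble(max_depth = max_depth_grid, cv_accuracy = NA_real_)
    best_depth <- max_depth_grid
  }
  booster <- fit_xgb(features$x, labels, max_depth = best_depth,
                     nrounds = nrounds, eta = eta, seed = seed)
  structure(
    list(raw = xgboost::xgb.save.raw(booster),
         columns = features$columns,
         vocabulary = features$vocabulary,
         classes = levels(labels),
         max_depth = best_depth,
         nrounds = nrounds, eta = eta, seed = seed, cv = cv),
    class = "had_model"
  )
}

#' @export
print.had_model <- function(x, ...) {
  cat(sprintf(
    "<had_model> gradient-boosted trees: %d classes, max_depth %d, %d rounds, %d features\n",
    length(x$classes), x$max_depth, x$nrounds, length(x$columns)))
  invisible(x)
}

#' Predict class probabilities for visits
#'
#' For a binary model returns one HAD-use probability per visit; for the
#' seven-class type model returns one probability column per class (rows sum
#' to one by construction of the softmax output).
#'
#' @param model A `had_model`.
#' @param features A `had_features` object built with the model's vocabulary;
#'   a column-manifest mismatch is an error.
#' @return A tibble with `txn` and either `prob_had` or one column per class.
#' @export
predict_had <- function(model, features) {
  stopifnot(inherits(model, "had_model"), inherits(features, "had_features"))
  if (!identical(model$columns, features$columns)) {
    abort("Feature columns do not match the model's fit-time manifest.")
  }
  booster <- xgboost::xgb.load.raw(model$raw)
  p <- predict_xgb(booster, features$x, model$classes)
  if (length(model$classes) == 2) {
    tibble::tibble(txn = features$txn, prob_had = p[, 2])
  } else {
    out <- tibble::as_tibble(as.data.frame(p / rowSums(p)),
                             .name_repair = "minimal")
    names(out) <- model$classes
    dplyr::bind_cols(tibble::tibble(txn = features$txn), out)
  }
}

#' Lasso feature relevance
#'
#' Fits an L1-penalised linear model of the (0/1-coded) label on the
#' internally standardised features and returns the top positive and top
#' negative coefficients — the features most associated with, and most
#' protective against, HAD use.
#'
#' @inheritParams benchmark_classifiers
#' @param penalty Positive lasso penalty (the `lambda` of the L1 fit).
#' @param k Number of features reported on each side (default 5).
#' @return A tibble `feature`, `coefficient`, `direction` with at most
#'   `2 * k` rows, ordered from most positive to most negative.
#' @export
feature_relevance <- function(features, labels, penalty = 0.001, k = 5) {
  stopifnot(inherits(features, "had_features"))
  if (penalty <= 0) abort("`penalty` must be positive.")
  y <- as.numeric(as_binary_label(labels) == "HAD")
  fit <- glmnet::glmnet(features$x, y, alpha = 1, lambda = penalty,
                        family = "gaussian", standardize = TRUE)
  beta <- as.numeric(fit$beta[, 1])
  tab <- tibble::tibble(feature = features$columns, coefficient = beta)
  pos <- tab |> dplyr::filter(.data$coefficient > 0) |>
    dplyr::arrange(dplyr::desc(.data$coefficient)) |> head(k) |>
    dplyr::mutate(direction = "positive")
  neg <- tab |> dplyr::filter(.data$coefficient < 0) |>
    dplyr::arrange(.data$coefficient) |> head(k) |>
    dplyr::mutate(direction = "negative")
  dplyr::bind_rows(pos, neg[rev(seq_len(nrow(neg))), ]) |>
    dplyr::arrange(dplyr::desc(.data$coefficient))
}
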