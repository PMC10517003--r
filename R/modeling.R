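# Model selection and evaluation: stratified K-fold comparison of seven
# classifiers, random-forest base model, hyperparameter search, and the
# full multiclass metric report.

#' The seven candidate classification algorithms
#'
#' @return character vector of algorithm identifiers: k-nearest neighbors,
#'   linear discriminant analysis, Gaussian naive Bayes, decision tree,
#'   support-vector machine, random forest, multinomial logistic regression.
#' @export
glioma_algorithms <- function() {
  c("knn", "lda", "naive_bayes", "decision_tree", "svm",
    "random_forest", "logistic")
}

# Fit on (X_train, y_train), predict classes for X_test. y is a factor.
fit_predict_algorithm <- function(algorithm, x_train, y_train, x_test, seed) {
  withr::with_seed(seed, switch(
    algorithm,
    knn = class::knn(x_train, x_test, y_train, k = 5),
    lda = {
      fit <- MASS::lda(x_train, grouping = y_train)
      predict(fit, x_test)$class
    },
    naive_bayes = {
      fit <- e1071::naiveBayes(x_train, y_train)
      predict(fit, x_test)
    },
    decision_tree = {
      df <- as.data.frame(x_train); df$.y <- y_train
      fit <- rpart::rpart(.y ~ ., data = df, method = "class")
      predict(fit, as.data.frame(x_test), type = "class")
    },
    svm = {
      fit <- e1071::svm(x_train, y_train, kernel = "radial")
      predict(fit, x_test)
    },
    random_forest = {
      fit <- fit_random_forest(x_train, y_train, rf_default_params(),
                               seed = seed)
      predict_rf_class(fit, x_test)
    },
    logistic = {
      df <- as.data.frame(x_train); df$.y <- y_train
      fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE, maxit = 200)
      predict(fit, as.data.frame(x_test))
    },
    abort(paste("unknown algorithm:", algorithm))
  ))
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin over the K folds.
make_stratified_folds <- function(y, K, seed) {
  withr::with_seed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(K), length(idx))
    }
    fold
  })
}

# Split a prepared table into the numeric design matrix and class factor.
design_matrix <- function(data, class_col = "class", feature_cols = NULL) {
  if (is.null(feature_cols)) {
    feature_cols <- intersect(glioma_feature_names(), names(data))
  }
  list(x = as.matrix(data[, feature_cols]),
       y = factor(data[[class_col]], levels = sort(unique(data[[class_col]]))),
       feature_cols = feature_cols)
}

#' Cross-validated comparison of the candidate algorithms
#'
#' Runs stratified K-fold cross-validation (one shared fold assignment for
#' all algorithms) over the prepared training table and scores every
#' algorithm by its mean fold accuracy and standard deviation. The winner is
#' the algorithm with the highest mean accuracy; ties are broken by lower
#' standard deviation, then alphabetically, so the result does not depend on
#' the order of `algorithms`.
#'
#' @param train prepared training tibble (standardized, selected).
#' @param K number of folds (default 10); reduced with a warning if some
#'   class has fewer than K rows.
#' @param seed integer seed for fold assignment and the fitted learners.
#' @param algorithms algorithm identifiers, default [glioma_algorithms()].
#' @param class_col,feature_cols column specification.
#' @return object of class `glioma_cv`: list with `scores` (tibble
#'   `algorithm`, `mean_accuracy`, `sd_accuracy`), `winner`, `K`.
#' @export
crossvalidate_algorithms <- function(train, K = 10L, seed = 42L,
                                     algorithms = glioma_algorithms(),
                                     class_col = "class",
                                     feature_cols = NULL) {
  d <- design_matrix(train, class_col, feature_cols)
  min_class <- min(table(d$y))
  if (min_class < K) {
    warning("reducing folds from ", K, " to ", min_class,
            " (smallest class size)")
    K <- min_class
  }
  fold <- make_stratified_folds(d$y, K, seed)
  scores <- purrr::map(algorithms, function(alg) {
    acc <- purrr::map_dbl(seq_len(K), function(f) {
      tr <- fold != f
      pred <- fit_predict_algorithm(alg, d$x[tr, , drop = FALSE], d$y[tr],
                                    d$x[!tr, , drop = FALSE],
                                    seed = seed + f)
      mean(pred == d$y[!tr])
    })
    tibble(algorithm = alg, mean_accuracy = mean(acc),
           sd_accuracy = sd(acc))
  }) |> purrr::list_rbind()
  ord <- order(-scores$mean_accuracy, scores$sd_accuracy, scores$algorithm)
  structure(list(scores = scores, winner = scores$algorithm[ord[1]], K = K),
            class = "glioma_cv")
}

#' Random-forest hyperparameters
#'
#' `rf_default_params()` is the untuned base configuration (100 trees, Gini
#' impurity, unlimited depth, bootstrap resampling, split threshold 2, leaf
#' size 1, square-root feature subsampling). `paper_tuned_params()` is a
#' named preset of the tuned optimum reported for this protocol
#' (108 trees, depth 50, no bootstrap, leaf 1, split 2).
#'
#' @return named list with `n_estimators`, `max_depth` (`NULL` = unlimited),
#'   `min_samples_split`, `min_samples_leaf`, `max_features`, `bootstrap`.
#' @export
rf_default_params <- function() {
  list(n_estimators = 100L, max_depth = NULL, min_samples_split = 2L,
       min_samples_leaf = 1L, max_features = "sqrt", bootstrap = TRUE)
}

#' @rdname rf_default_params
#' @export
paper_tuned_params <- function() {
  list(n_estimators = 108L, max_depth = 50L, min_samples_split = 2L,
       min_samples_leaf = 1L, max_features = "sqrt", bootstrap = FALSE)
}

# Probability random forest behind the hyperparameter surface above.
fit_random_forest <- function(x, y, params, seed) {
  mtry <- if (identical(params$max_features, "sqrt")) {
    max(1L, floor(sqrt(ncol(x))))
  } else {
    as.integer(params$max_features)
  }
  ranger::ranger(
    x = x, y = y, probability = TRUE,
    num.trees = params$n_estimators,
    mtry = mtry,
    min.node.size = params$min_samples_split,
    min.bucket = params$min_samples_leaf,
    max.depth = params$max_depth %||% 0L,
    replace = params$bootstrap,
    sample.fraction = 1,
    splitrule = "gini",
    seed = seed, num.threads = 1L)
}

predict_rf_prob <- function(fit, x) {
  predict(fit, data = x, num.threads = 1L)$predictions
}

predict_rf_class <- function(fit, x) {
  p <- predict_rf_prob(fit, x)
  factor(colnames(p)[max.col(p, ties.method = "first")],
         levels = colnames(p))
}

#' Train the random-forest classification model
#'
#' Fits a probability random forest on the prepared training table with the
#' given hyperparameters (defaults: [rf_default_params()]).
#'
#' @param train prepared training tibble.
#' @param seed integer seed (default 42).
#' @param params hyperparameter list.
#' @param class_col,feature_cols column specification.
#' @return object of class `glioma_model`.
#' @export
train_base_model <- function(train, seed = 42L, params = rf_default_params(),
                             class_col = "class", feature_cols = NULL) {
  d <- design_matrix(train, class_col, feature_cols)
  fit <- fit_random_forest(d$x, d$y, params, seed = seed)
  structure(list(fit = fit, params = params, feature_cols = d$feature_cols,
                 class_levels = levels(d$y), class_col = class_col,
                 seed = seed),
            class = "glioma_model")
}

#' @export
predict.glioma_model <- function(object, newdata, type = c("class", "prob"),
                                 ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata[, object$feature_cols])
  if (type == "prob") predict_rf_prob(object$fit, x)
  else predict_rf_class(object$fit, x)
}

#' Classification metrics from a confusion matrix
#'
#' Bookkeeping arithmetic of the model report, exposed so that any 3 x 3
#' table of counts (rows = true class, columns = predicted class) can be
#' turned into overall accuracy, error and per-class precision, recall and
#' F1. Accuracy is `trace(confusion) / sum(confusion)`.
#'
#' @param confusion square integer matrix, rows = truth, columns = predicted,
#'   with identical row/column names.
#' @return list with `accuracy` (fraction), `accuracy_pct`, `error_pct`, and
#'   `class_metrics` tibble (`class`, `precision`, `recall`, `f1`,
#'   `support`).
#' @examples
#' cm <- matrix(c(112, 10, 8, 12, 109, 8, 6, 10, 121), 3, 3, byrow = TRUE)
#' dimnames(cm) <- list(0:2, 0:2)
#' confusion_metrics(cm)$accuracy_pct
#' @export
confusion_metrics <- function(confusion) {
  stopifnot(nrow(confusion) == ncol(confusion))
  total <- sum(confusion)
  acc <- sum(diag(confusion)) / total
  support <- rowSums(confusion)
  predicted <- colSums(confusion)
  recall <- diag(confusion) / support
  precision <- ifelse(predicted > 0, diag(confusion) / predicted, NA_real_)
  f1 <- ifelse(!is.na(precision) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall), 0)
  list(accuracy = acc, accuracy_pct = 100 * acc,
       error_pct = 100 * (1 - acc),
       class_metrics = tibble(class = rownames(confusion),
                              precision = as.numeric(precision),
                              recall = as.numeric(recall),
                              f1 = as.numeric(f1),
                              support = as.numeric(support)))
}

#' Evaluate a fitted model on a held-out test set
#'
#' Predicts the test rows and assembles the full report: confusion matrix
#' (rows = true class, columns = predicted), overall accuracy and error in
#' percent, per-class precision/recall/F1, and per-class one-vs-rest ROC
#' AUC computed from the predicted class probabilities. Metrics are stored
#' at full precision; [tidy()] renders them rounded to 2 decimals.
#'
#' @param model a [train_base_model()] result.
#' @param test prepared test tibble.
#' @return object of class `model_report`: list with `confusion`,
#'   `accuracy`, `accuracy_pct`, `error_pct`, `class_metrics`, `ovr_auc`,
#'   and `probabilities` (tibble of true class + per-class scores, kept for
#'   ROC curves).
#' @export
evaluate_model <- function(model, test) {
  stopifnot(inherits(model, "glioma_model"))
  truth <- factor(test[[model$class_col]], levels = model$class_levels)
  probs <- predict(model, test, type = "prob")
  pred <- factor(colnames(probs)[max.col(probs, ties.method = "first")],
                 levels = model$class_levels)
  confusion <- table(truth = truth, predicted = pred)
  cm <- confusion_metrics(unclass(confusion))
  ovr <- purrr::map(model$class_levels, function(cl) {
    is_cl <- truth == cl
    auc <- if (!any(is_cl) || all(is_cl)) NA_real_ else {
      as.numeric(pROC::auc(pROC::roc(
        response = is_cl, predictor = probs[, cl],
        levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)))
    }
    tibble(class = cl, auc = auc)
  }) |> purrr::list_rbind()
  structure(list(confusion = unclass(confusion),
                 accuracy = cm$accuracy, accuracy_pct = cm$accuracy_pct,
                 error_pct = cm$error_pct,
                 class_metrics = cm$class_metrics, ovr_auc = ovr,
                 probabilities = bind_cols(tibble(truth = truth),
                                           as_tibble(probs))),
            class = "model_report")
}

#' Hyperparameter search space of the random forest
#'
#' The configured ranges: `n_estimators` 100 to 1000 (step 400 on the grid,
#' i.e. 100/500/900; uniform integers for random search), `max_depth` 10 to
#' 110 in 11 steps, `min_samples_split` \{2, 5, 10\},
#' `min_samples_leaf` \{1, 2, 4\}, `bootstrap` \{TRUE, FALSE\},
#' `max_features` square-root.
#'
#' @return named list describing the space.
#' @export
rf_param_grid <- function() {
  list(n_estimators = c(100L, 1000L), n_estimators_step = 400L,
       max_depth = seq(10L, 110L, by = 10L),
       min_samples_split = c(2L, 5L, 10L),
       min_samples_leaf = c(1L, 2L, 4L),
       max_features = "sqrt",
       bootstrap = c(TRUE, FALSE))
}

grid_candidates <- function(grid) {
  g <- expand.grid(
    n_estimators = seq(grid$n_estimators[1], grid$n_estimators[2],
                       by = grid$n_estimators_step),
    max_depth = grid$max_depth,
    min_samples_split = grid$min_samples_split,
    min_samples_leaf = grid$min_samples_leaf,
    bootstrap = grid$bootstrap,
    stringsAsFactors = FALSE)
  purrr::map(seq_len(nrow(g)), function(i) {
    c(as.list(g[i, ]), list(max_features = grid$max_features))
  })
}

random_candidates <- function(grid, n_iter) {
  purrr::map(seq_len(n_iter), function(i) {
    list(n_estimators = sample(grid$n_estimators[1]:grid$n_estimators[2], 1),
         max_depth = sample(grid$max_depth, 1),
         min_samples_split = sample(grid$min_samples_split, 1),
         min_samples_leaf = sample(grid$min_samples_leaf, 1),
         bootstrap = sample(grid$bootstrap, 1),
         max_features = grid$max_features)
  })
}

#' Tune random-forest hyperparameters by cross-validated search
#'
#' Scores candidate hyperparameter combinations by stratified K-fold
#' cross-validation accuracy on the training table (one shared fold
#' assignment for all candidates) and returns the best. `method = "grid"`
#' enumerates the full grid; `method = "random"` (default) draws `n_iter`
#' combinations, sampling `n_estimators` uniformly over its whole integer
#' range. Ties are broken in favour of the simpler model: fewer trees, then
#' shallower depth.
#'
#' @param train prepared training tibble.
#' @param grid search space, default [rf_param_grid()]; a list of explicit
#'   candidate parameter lists is also accepted.
#' @param method `"random"` or `"grid"`.
#' @param n_iter random-search draws (default 100).
#' @param K CV folds (default 10).
#' @param seed integer seed.
#' @param class_col,feature_cols column specification.
#' @return object of class `glioma_tuning`: list with `best` (parameter
#'   list), `best_score`, and `results` (one row per candidate).
#' @export
tune_hyperparameters <- function(train, grid = rf_param_grid(),
                                 method = c("random", "grid"),
                                 n_iter = 100L, K = 10L, seed = 42L,
                                 class_col = "class", feature_cols = NULL) {
  method <- match.arg(method)
  d <- design_matrix(train, class_col, feature_cols)
  candidates <- if (is.list(grid) && is.null(names(grid))) {
    grid # explicit list of parameter lists
  } else if (method == "grid") {
    grid_candidates(grid)
  } else {
    withr::with_seed(seed, random_candidates(grid, n_iter))
  }
  if (length(candidates) == 0) abort("empty hyperparameter grid")
  K_eff <- min(K, min(table(d$y)))
  fold <- make_stratified_folds(d$y, K_eff, seed)
  results <- purrr::imap(candidates, function(p, i) {
    acc <- purrr::map_dbl(seq_len(K_eff), function(f) {
      tr <- fold != f
      fit <- fit_random_forest(d$x[tr, , drop = FALSE], d$y[tr], p,
                               seed = seed + f)
      mean(predict_rf_class(fit, d$x[!tr, , drop = FALSE]) == d$y[!tr])
    })
    tibble(candidate = i, n_estimators = p$n_estimators,
           max_depth = p$max_depth %||% Inf,
           min_samples_split = p$min_samples_split,
           min_samples_leaf = p$min_samples_leaf,
           bootstrap = p$bootstrap,
           mean_accuracy = mean(acc), sd_accuracy = sd(acc))
  }) |> purrr::list_rbind()
  ord <- order(-results$mean_accuracy, results$n_estimators,
               results$max_depth)
  best_i <- results$candidate[ord[1]]
  structure(list(best = candidates[[best_i]],
                 best_score = results$mean_accuracy[ord[1]],
                 results = results, K = K_eff, method = method),
            class = "glioma_tuning")
}

#' @export
print.glioma_cv <- function(x, ...) {
  cat("<glioma_cv> K=", x$K, ", winner: ", x$winner, "\n", sep = "")
  print(x$scores)
  invisible(x)
}

#' @export
print.model_report <- function(x, ...) {
  cat("<model_report> accuracy ", sprintf("%.2f%%", x$accuracy_pct),
      " (error ", sprintf("%.2f%%", x$error_pct), ")\n", sep = "")
  print(x$confusion)
  print(x$class_metrics |> mutate(across(c("precision", "recall", "f1"),
                                         ~ round(.x, 2))))
  invisible(x)
}

#' @export
print.glioma_tuning <- function(x, ...) {
  cat("<glioma_tuning> ", x$method, " search, ", nrow(x$results),
      " candidates, K=", x$K, ", best CV accuracy ",
      sprintf("%.4f", x$best_score), "\n", sep = "")
  utils::str(x$best)
  invisible(x)
}
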