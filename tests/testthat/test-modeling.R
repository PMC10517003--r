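fc4 <- paste0("f", 1:4)

test_that("all seven algorithms near-perfectly solve a separable problem", {
  tbl <- separable_table(n_per_class = 30, sep = 8, seed = 20)
  cv <- crossvalidate_algorithms(tbl, K = 5, seed = 1, feature_cols = fc4)
  expect_equal(nrow(cv$scores), 7)
  expect_setequal(cv$scores$algorithm, glioma_algorithms())
  expect_true(all(cv$scores$mean_accuracy > 0.9))
  expect_true(all(cv$scores$sd_accuracy < 0.12))
})

test_that("label permutation drives every algorithm to chance level", {
  tbl <- separable_table(n_per_class = 60, sep = 8, seed = 21)
  tbl$class <- withr::with_seed(22, sample(tbl$class))
  cv <- crossvalidate_algorithms(tbl, K = 5, seed = 2, feature_cols = fc4)
  expect_true(all(abs(cv$scores$mean_accuracy - 1 / 3) < 0.15))
})

test_that("the CV winner does not depend on algorithm ordering", {
  tbl <- separable_table(n_per_class = 25, sep = 2, seed = 23)
  cv1 <- crossvalidate_algorithms(tbl, K = 4, seed = 3, feature_cols = fc4)
  cv2 <- crossvalidate_algorithms(tbl, K = 4, seed = 3, feature_cols = fc4,
                                  algorithms = rev(glioma_algorithms()))
  expect_equal(cv1$winner, cv2$winner)
  s2 <- cv2$scores[match(cv1$scores$algorithm, cv2$scores$algorithm), ]
  expect_equal(cv1$scores$mean_accuracy, s2$mean_accuracy)
})

test_that("fold counts adapt to small classes with a warning", {
  tbl <- separable_table(n_per_class = 6, sep = 8, seed = 24)
  expect_warning(cv <- crossvalidate_algorithms(tbl, K = 10, seed = 4,
                                                feature_cols = fc4),
                 "reducing folds")
  expect_equal(cv$K, 6)
})

test_that("the base model solves a separable problem and keeps books", {
  tbl <- separable_table(n_per_class = 40, sep = 8, seed = 25)
  sp <- split_train_test(tbl, 0.3, seed = 5)
  m <- train_base_model(sp$train, seed = 6, feature_cols = fc4)
  # training-set predictions on a separable table are perfect
  expect_equal(mean(predict(m, sp$train) == factor(sp$train$class)), 1)
  r <- evaluate_model(m, sp$test)
  expect_equal(as.numeric(rowSums(r$confusion)),
               as.numeric(table(sp$test$class)))
  expect_equal(r$accuracy, sum(diag(r$confusion)) / sum(r$confusion))
  expect_equal(r$class_metrics$support, as.numeric(table(sp$test$class)))
  expect_true(all(r$ovr_auc$auc > 0.95))
})

test_that("confusion-matrix arithmetic is recomputable", {
  cm <- matrix(c(50, 3, 2, 4, 40, 1, 1, 2, 30), 3, 3, byrow = TRUE)
  dimnames(cm) <- list(0:2, 0:2)
  met <- confusion_metrics(cm)
  expect_equal(met$accuracy * sum(cm), sum(diag(cm)))
  expect_equal(met$class_metrics$recall, unname(diag(cm) / rowSums(cm)))
  expect_equal(met$class_metrics$precision, unname(diag(cm) / colSums(cm)))
  p <- met$class_metrics$precision; r <- met$class_metrics$recall
  expect_equal(met$class_metrics$f1, 2 * p * r / (p + r))
})

test_that("one-vs-rest AUC equals the brute-force pairwise oracle", {
  # hand-built 6-point score set with a tie
  truth <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  score <- c(0.9, 0.8, 0.4, 0.8, 0.3, 0.1)
  auc_ref <- brute_auc(score, truth)
  auc_proc <- as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = score,
    levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)))
  expect_equal(auc_proc, auc_ref, tolerance = 1e-12)
  # and through the model report on random data
  withr::with_seed(26, {
    tbl <- separable_table(n_per_class = 15, sep = 1, seed = 27)
    sp <- split_train_test(tbl, 0.4, seed = 7)
    m <- train_base_model(sp$train, seed = 8, feature_cols = fc4)
    r <- evaluate_model(m, sp$test)
    probs <- r$probabilities
    for (cl in r$ovr_auc$class) {
      expect_equal(r$ovr_auc$auc[r$ovr_auc$class == cl],
                   brute_auc(probs[[cl]], probs$truth == cl),
                   tolerance = 1e-12)
    }
  })
})

test_that("hyperparameter search honors the grid and ties to simplicity", {
  tbl <- separable_table(n_per_class = 20, sep = 8, seed = 28)
  # single-point grid: that point is returned
  single <- list(list(n_estimators = 57L, max_depth = 3L,
                      min_samples_split = 2L, min_samples_leaf = 1L,
                      max_features = "sqrt", bootstrap = TRUE))
  tuned <- tune_hyperparameters(tbl, grid = single, K = 3, seed = 9,
                                feature_cols = fc4)
  expect_equal(tuned$best$n_estimators, 57L)
  expect_error(tune_hyperparameters(tbl, grid = list(), K = 3, seed = 9,
                                    feature_cols = fc4), "empty")
  # grid containing the defaults: best CV score >= the defaults' score
  cand <- list(rf_default_params(),
               list(n_estimators = 200L, max_depth = 20L,
                    min_samples_split = 5L, min_samples_leaf = 2L,
                    max_features = "sqrt", bootstrap = FALSE))
  tuned2 <- tune_hyperparameters(tbl, grid = cand, K = 3, seed = 10,
                                 feature_cols = fc4)
  default_row <- tuned2$results$mean_accuracy[1]
  expect_gte(tuned2$best_score, default_row)
  # the named preset carries the documented optimum
  expect_equal(paper_tuned_params()$n_estimators, 108L)
  expect_equal(paper_tuned_params()$max_depth, 50L)
  expect_false(paper_tuned_params()$bootstrap)
})

test_that("random search concentrates on shallow depths for a depth-2 task", {
  # one feature thresholded twice decides the class: depth 2 suffices
  withr::with_seed(29, {
    x <- runif(240)
    cls <- as.integer(cut(x, c(-Inf, 0.33, 0.66, Inf))) - 1L
    tbl <- tibble::tibble(f1 = x, f2 = rnorm(240), class = cls)
  })
  tuned <- tune_hyperparameters(tbl, method = "random", n_iter = 8, K = 3,
                                seed = 11, feature_cols = c("f1", "f2"))
  # the tie-break contract: among the top-accuracy candidates the returned
  # combination has the fewest trees, then the shallowest depth
  res <- tuned$results
  top <- res[res$mean_accuracy == max(res$mean_accuracy), ]
  expect_equal(tuned$best$n_estimators, min(top$n_estimators))
  top_trees <- top[top$n_estimators == min(top$n_estimators), ]
  expect_equal(tuned$best$max_depth, min(top_trees$max_depth))
})

test_that("modeling is deterministic under fixed seeds", {
  tbl <- separable_table(n_per_class = 20, sep = 2, seed = 30)
  cv1 <- crossvalidate_algorithms(tbl, K = 3, seed = 12, feature_cols = fc4)
  cv2 <- crossvalidate_algorithms(tbl, K = 3, seed = 12, feature_cols = fc4)
  expect_identical(cv1$scores, cv2$scores)
  sp <- split_train_test(tbl, 0.3, seed = 13)
  r1 <- evaluate_model(train_base_model(sp$train, seed = 14,
                                        feature_cols = fc4), sp$test)
  r2 <- evaluate_model(train_base_model(sp$train, seed = 14,
                                        feature_cols = fc4), sp$test)
  expect_identical(r1$confusion, r2$confusion)
  expect_identical(r1$ovr_auc, r2$ovr_auc)
})
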