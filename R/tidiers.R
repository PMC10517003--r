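# broom-style tidiers for the pipeline's result objects.

#' Tidy an ANOVA feature-selection report
#'
#' @param x an [anova_f_scores()] report.
#' @param ... unused.
#' @return tibble with `feature`, `f_score`, `flag`.
#' @export
tidy.anova_report <- function(x, ...) {
  as_tibble(x)
}

#' Tidy a cross-validation comparison
#'
#' @param x a [crossvalidate_algorithms()] result.
#' @param ... unused.
#' @return tibble with one row per algorithm: `algorithm`, `mean_accuracy`,
#'   `sd_accuracy`, `winner` flag.
#' @export
tidy.glioma_cv <- function(x, ...) {
  x$scores |> mutate(winner = .data$algorithm == x$winner)
}

#' @rdname tidy.glioma_cv
#' @export
glance.glioma_cv <- function(x, ...) {
  x$scores |> filter(.data$algorithm == x$winner) |>
    mutate(K = x$K) |>
    select("algorithm", "mean_accuracy", "sd_accuracy", "K")
}

#' Tidy a model evaluation report
#'
#' `tidy()` returns the per-class metrics rounded to 2 decimals (report
#' parity with the usual classification-report rendering); `glance()`
#' returns the one-row summary at full precision.
#'
#' @param x an [evaluate_model()] result.
#' @param digits rounding applied by `tidy()` (default 2).
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.model_report <- function(x, digits = 2, ...) {
  x$class_metrics |>
    mutate(across(c("precision", "recall", "f1"), ~ round(.x, digits)))
}

#' @rdname tidy.model_report
#' @export
glance.model_report <- function(x, ...) {
  aucs <- setNames(x$ovr_auc$auc, paste0("auc_", x$ovr_auc$class))
  bind_cols(tibble(accuracy = x$accuracy, accuracy_pct = x$accuracy_pct,
                   error_pct = x$error_pct),
            as_tibble(as.list(aucs)))
}

#' Tidy a hyperparameter search
#'
#' @param x a [tune_hyperparameters()] result.
#' @param ... unused.
#' @return `tidy()`: one row per candidate; `glance()`: the winning
#'   combination and its CV score.
#' @export
tidy.glioma_tuning <- function(x, ...) {
  x$results
}

#' @rdname tidy.glioma_tuning
#' @export
glance.glioma_tuning <- function(x, ...) {
  tibble(n_estimators = x$best$n_estimators,
         max_depth = x$best$max_depth %||% Inf,
         min_samples_split = x$best$min_samples_split,
         min_samples_leaf = x$best$min_samples_leaf,
         bootstrap = x$best$bootstrap,
         mean_accuracy = x$best_score, K = x$K, method = x$method)
}

#' Tidy a fitted glioma model
#'
#' @param x a [train_base_model()] result.
#' @param ... unused.
#' @return one-row tibble of the hyperparameters and training seed.
#' @export
glance.glioma_model <- function(x, ...) {
  tibble(n_estimators = x$params$n_estimators,
         max_depth = x$params$max_depth %||% Inf,
         min_samples_split = x$params$min_samples_split,
         min_samples_leaf = x$params$min_samples_leaf,
         max_features = x$params$max_features,
         bootstrap = x$params$bootstrap, seed = x$seed)
}
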