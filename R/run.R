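# End-to-end pipeline runner: simulate -> ADC -> features -> prepare ->
# model, with an optional on-disk manifest for reproducibility.

#' Run the full glioma-grading pipeline
#'
#' Executes the five stages in order on a synthetic cohort: cohort
#' generation, ADC map computation + feature extraction, preparation
#' (SMOTE, split, standardization, ANOVA selection), cross-validated
#' algorithm comparison, and random-forest training/evaluation (base model,
#' plus a tuned model when `tune = TRUE`). Every stochastic stage derives
#' its seed from the single `seed` argument, so a run is a deterministic
#' function of its configuration.
#'
#' When `out_dir` is given, the stage outputs (feature CSVs, ANOVA report,
#' CV scores, model reports, configuration) are written there together with
#' a `manifest.json` recording per-file MD5 hashes, the configuration
#' snapshot, package version and timing; re-running with an identical
#' configuration reproduces identical hashes.
#'
#' @param config a [cohort_config()].
#' @param mode preparation mode, `"paper"` or `"sound"`
#'   (see [prepare_features()]).
#' @param n_levels,symmetric GLCM extraction settings.
#' @param tune also run the hyperparameter search? Default `FALSE`.
#' @param tune_method,n_iter,cv_K search settings (see
#'   [tune_hyperparameters()]); `cv_K` is also the fold count of the
#'   algorithm comparison.
#' @param seed global pipeline seed; defaults to `config$seed`.
#' @param out_dir optional output directory.
#' @return object of class `glioma_run`: list with `features`, `prep`,
#'   `cv`, `base_model`, `base_report`, and (if tuned) `tuning`,
#'   `tuned_model`, `tuned_report`, plus `manifest` when written to disk.
#' @export
run_glioma_pipeline <- function(config = cohort_config(),
                                mode = c("paper", "sound"),
                                n_levels = 64L, symmetric = FALSE,
                                tune = FALSE, tune_method = "random",
                                n_iter = 20L, cv_K = 10L,
                                seed = config$seed, out_dir = NULL) {
  mode <- match.arg(mode)
  t0 <- Sys.time()
  config$seed <- as.integer(seed)
  cohort <- generate_cohort(config)
  features <- extract_features(cohort, n_levels = n_levels,
                               symmetric = symmetric)
  prep <- prepare_features(features, mode = mode, split_seed = 42L,
                           smote_seed = seed + 1L)
  cv <- crossvalidate_algorithms(prep$train, K = cv_K, seed = seed + 2L)
  base_model <- train_base_model(prep$train, seed = seed + 3L)
  base_report <- evaluate_model(base_model, prep$test)
  out <- list(features = features, prep = prep, cv = cv,
              base_model = base_model, base_report = base_report,
              config = config, mode = mode, seed = seed)
  if (tune) {
    out$tuning <- tune_hyperparameters(prep$train, method = tune_method,
                                       n_iter = n_iter, K = cv_K,
                                       seed = seed + 4L)
    out$tuned_model <- train_base_model(prep$train, seed = seed + 3L,
                                        params = out$tuning$best)
    out$tuned_report <- evaluate_model(out$tuned_model, prep$test)
  }
  if (!is.null(out_dir)) {
    out$manifest <- write_run_outputs(out, out_dir, t0)
  }
  class(out) <- "glioma_run"
  out
}

write_run_outputs <- function(run, out_dir, t0) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_features_csv(run$features, p("features.csv"))
  write_features_csv(run$prep$train, p("train.csv"))
  write_features_csv(run$prep$test, p("test.csv"))
  readr::write_csv(run$cv$scores, p("cv_scores.csv"))
  jsonlite::write_json(
    list(anova = run$prep$anova, dropped = run$prep$dropped,
         scaler = run$prep$standardizer$stats,
         scaler_mode = run$prep$standardizer$mode),
    p("preparation.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_model_report(run$base_report, p("base_report.json"))
  if (!is.null(run$tuned_report)) {
    write_model_report(run$tuned_report, p("tuned_report.json"))
    jsonlite::write_json(run$tuning$best, p("tuned_params.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  write_cohort_config(run$config, p("cohort_config.json"))
  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    config = unclass(run$config), mode = run$mode, seed = run$seed,
    version = as.character(utils::packageVersion("gliotex")),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    hashes = as.list(tools::md5sum(file.path(out_dir, files)) |>
                       setNames(files)))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest
}

#' @export
print.glioma_run <- function(x, ...) {
  cat("<glioma_run> mode=", x$mode, ", seed ", x$seed, "\n", sep = "")
  cat("CV winner: ", x$cv$winner, "\n", sep = "")
  cat("base accuracy: ", sprintf("%.2f%%", x$base_report$accuracy_pct),
      "\n", sep = "")
  if (!is.null(x$tuned_report)) {
    cat("tuned accuracy: ", sprintf("%.2f%%", x$tuned_report$accuracy_pct),
        "\n", sep = "")
  }
  invisible(x)
}
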