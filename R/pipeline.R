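# Feature-table preparation: SMOTE class balancing, stratified train/test
# split, standardization, and ANOVA F-test feature selection.

#' SMOTE minority oversampling
#'
#' Balances the class sizes of a feature table by synthetic minority
#' oversampling: for each synthetic point, a random minority-class row `x` is
#' chosen, its `k` nearest same-class neighbors (Euclidean distance in
#' feature space) are found, one neighbor `z` is picked uniformly, and the
#' new point is `x + u * (z - x)` with `u ~ Uniform(0, 1)`. Original rows are
#' preserved unchanged; synthetic rows copy the parent's non-feature columns,
#' get a `synt_` slice id (when a `slice_id` column exists) and are marked in
#' a logical `synthetic` column.
#'
#' @param data feature tibble with a `class` column.
#' @param k number of nearest neighbors (default 5); every class that needs
#'   oversampling must have more than `k` members.
#' @param target `"max-class"` (default: equalize to the largest class) or an
#'   integer target size per class.
#' @param feature_cols feature columns used for the neighbor geometry;
#'   default the canonical names present in `data`.
#' @param class_col name of the class column.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return tibble with every class at the target size and a `synthetic`
#'   column; an already-balanced table is returned unchanged apart from that
#'   column.
#' @export
smote_oversample <- function(data, k = 5L, target = "max-class",
                             feature_cols = NULL, class_col = "class",
                             seed = NULL) {
  feature_cols <- feature_columns(data, feature_cols)
  y <- data[[class_col]]
  counts <- table(y)
  target_n <- if (identical(target, "max-class")) max(counts)
              else as.integer(target)
  run <- function() {
    out <- data |> mutate(synthetic = FALSE)
    for (cl in names(counts)) {
      need <- target_n - counts[[cl]]
      if (need <= 0) next
      rows <- data[y == cl, , drop = FALSE]
      n_cl <- nrow(rows)
      if (n_cl <= k) {
        abort(paste0("class ", cl, " has ", n_cl,
                     " rows; SMOTE needs more than k = ", k))
      }
      X <- as.matrix(rows[, feature_cols])
      dm <- as.matrix(stats::dist(X))
      diag(dm) <- Inf
      nb <- t(apply(dm, 1, function(d) order(d)[seq_len(k)]))
      parent <- sample.int(n_cl, need, replace = TRUE)
      pick <- sample.int(k, need, replace = TRUE)
      u <- runif(need)
      neigh <- nb[cbind(parent, pick)]
      synth_X <- X[parent, , drop = FALSE] +
        u * (X[neigh, , drop = FALSE] - X[parent, , drop = FALSE])
      synth <- rows[parent, , drop = FALSE]
      synth[, feature_cols] <- as_tibble(synth_X)
      synth$synthetic <- TRUE
      if ("slice_id" %in% names(synth)) {
        synth$slice_id <- sprintf("synt_%s_%04d", cl, seq_len(need))
      }
      out <- bind_rows(out, synth)
    }
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Stratified train/test split
#'
#' Splits the rows of a feature table into disjoint, exhaustive train and
#' test sets, stratified by class. The total test size is
#' `ceiling(test_fraction * n)`; it is apportioned over the classes by
#' floors plus largest fractional remainders (ties broken by class order),
#' so a balanced 431 x 3 table at 30% yields per-class test supports
#' 130/129/129.
#'
#' @param data feature tibble with a class column.
#' @param test_fraction fraction of rows held out (default 0.30).
#' @param seed integer seed for the within-class row sampling (default 42).
#' @param class_col name of the class column.
#' @return list with tibbles `train` and `test`.
#' @export
split_train_test <- function(data, test_fraction = 0.30, seed = 42L,
                             class_col = "class") {
  stopifnot(test_fraction >= 0, test_fraction < 1)
  y <- data[[class_col]]
  classes <- sort(unique(y))
  n_k <- as.numeric(table(factor(y, levels = classes)))
  if (any(n_k < 2)) abort("every class needs at least 2 rows to split")
  n_test <- ceiling(test_fraction * nrow(data))
  raw <- test_fraction * n_k
  quota <- floor(raw)
  left <- n_test - sum(quota)
  if (left > 0) {
    extra <- order(raw - quota, decreasing = TRUE)[seq_len(left)]
    quota[extra] <- quota[extra] + 1
  }
  test_idx <- withr::with_seed(seed, {
    unlist(purrr::map2(classes, quota, function(cl, q) {
      idx <- which(y == cl)
      if (q == 0) integer(0) else sample(idx, q)
    }))
  })
  list(train = data[setdiff(seq_len(nrow(data)), test_idx), , drop = FALSE],
       test = data[sort(test_idx), , drop = FALSE])
}

#' Fit a feature standardizer on training data
#'
#' Learns per-feature scaling statistics from the training rows only.
#' `zscore` mode centers to zero mean and scales to unit variance using the
#' population standard deviation; `minmax` mode rescales to `[0, 1]` by the
#' feature minimum and maximum. Constant features are flagged and emitted as
#' all-zero when the standardizer is applied.
#'
#' @param train training feature tibble.
#' @param mode `"zscore"` (default) or `"minmax"`.
#' @param feature_cols feature columns; default the canonical names present.
#' @return object of class `standardizer`: list with the `mode` and a
#'   `stats` tibble (`feature`, `mean`, `sd`, `min`, `max`, `constant`).
#' @export
fit_standardizer <- function(train, mode = c("zscore", "minmax"),
                             feature_cols = NULL) {
  mode <- match.arg(mode)
  feature_cols <- feature_columns(train, feature_cols)
  stats_tbl <- purrr::map(feature_cols, function(f) {
    x <- train[[f]]
    tibble(feature = f, mean = mean(x),
           sd = sqrt(mean((x - mean(x))^2)), # population sd
           min = min(x), max = max(x),
           constant = diff(range(x)) == 0)
  }) |> purrr::list_rbind()
  structure(list(mode = mode, stats = stats_tbl), class = "standardizer")
}

#' Apply a fitted standardizer
#'
#' Rescales the feature columns of `data` using the immutable statistics
#' learned by [fit_standardizer()]; the parameters are never re-fitted, so
#' applying to a test set cannot leak test information.
#'
#' @param params a `standardizer`.
#' @param data feature tibble containing all fitted features.
#' @return `data` with standardized feature columns.
#' @export
apply_standardizer <- function(params, data) {
  stopifnot(inherits(params, "standardizer"))
  for (i in seq_len(nrow(params$stats))) {
    s <- params$stats[i, ]
    x <- data[[s$feature]]
    data[[s$feature]] <- if (s$constant) {
      rep(0, length(x))
    } else if (params$mode == "zscore") {
      (x - s$mean) / s$sd
    } else {
      (x - s$min) / (s$max - s$min)
    }
  }
  data
}

#' One-way ANOVA F scores of every feature
#'
#' For each feature, the one-way analysis-of-variance F statistic of the
#' class grouping, computed from scratch as the ratio of the between-group
#' mean square (`df = k - 1`) to the within-group mean square
#' (`df = n - k`). A feature with zero within-group variance but non-zero
#' between-group spread (a perfect separator) scores `Inf`; a globally
#' constant feature scores 0; both are flagged.
#'
#' @param data feature tibble with a class column.
#' @param class_col name of the class column.
#' @param feature_cols feature columns; default the canonical names present.
#' @return object of class `anova_report`: tibble with `feature`, `f_score`,
#'   `flag` (`"ok"`, `"constant"` or `"zero_within"`), ordered as the input
#'   features.
#' @export
anova_f_scores <- function(data, class_col = "class", feature_cols = NULL) {
  feature_cols <- feature_columns(data, feature_cols)
  g <- factor(data[[class_col]])
  k <- nlevels(g)
  n <- nrow(data)
  if (k < 2) abort("need at least 2 classes")
  if (any(table(g) < 2)) abort("every class needs at least 2 rows")
  scores <- purrr::map(feature_cols, function(f) {
    x <- data[[f]]
    grand <- mean(x)
    means <- tapply(x, g, mean)
    ns <- tapply(x, g, length)
    ssb <- sum(ns * (means - grand)^2)
    ssw <- sum((x - means[g])^2)
    msb <- ssb / (k - 1)
    msw <- ssw / (n - k)
    if (msw == 0) {
      if (msb == 0) tibble(feature = f, f_score = 0, flag = "constant")
      else tibble(feature = f, f_score = Inf, flag = "zero_within")
    } else {
      tibble(feature = f, f_score = msb / msw, flag = "ok")
    }
  }) |> purrr::list_rbind()
  structure(scores, class = c("anova_report", class(scores)))
}

#' Drop the lowest-scoring features
#'
#' Removes the `drop_count` features with the smallest ANOVA F scores from
#' the table (ties broken by feature order in the report). With the default
#' 16-feature table and `drop_count = 3` this leaves 13 features.
#'
#' @param data feature tibble.
#' @param report an [anova_f_scores()] report.
#' @param drop_count number of features to drop (default 3; must be smaller
#'   than the feature count).
#' @return `data` without the dropped columns; the dropped names are stored
#'   in the `"dropped"` attribute.
#' @export
select_features <- function(data, report, drop_count = 3L) {
  stopifnot(inherits(report, "anova_report"))
  if (drop_count >= nrow(report)) abort("drop_count must be < feature count")
  if (drop_count == 0) {
    attr(data, "dropped") <- character(0)
    return(data)
  }
  ord <- order(report$f_score, seq_len(nrow(report)))
  dropped <- report$feature[ord[seq_len(drop_count)]]
  out <- data[, setdiff(names(data), dropped), drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}

#' Prepare a feature table for modeling
#'
#' Runs the full preparation protocol and returns ready-to-model train and
#' test tables. Two orderings are supported:
#' * `mode = "paper"` (default): SMOTE-balance the *whole* table first, then
#'   split 70:30 stratified. This matches the original protocol but lets
#'   synthetic points share parents across the split (an acknowledged
#'   leakage).
#' * `mode = "sound"`: split first, then SMOTE the training fold only.
#'
#' In both modes the standardizer is fitted on the training rows only and
#' applied to both folds, ANOVA F scores are computed on the standardized
#' training rows, and the `drop_count` lowest-F features are removed from
#' both folds.
#'
#' @param features feature tibble (see [extract_features()]).
#' @param mode `"paper"` or `"sound"`.
#' @param test_fraction held-out fraction (default 0.30).
#' @param split_seed seed of the stratified split (default 42).
#' @param smote_k,smote_seed SMOTE neighbor count and seed.
#' @param scaler `"zscore"` or `"minmax"`.
#' @param drop_count features to drop by lowest F (default 3).
#' @return object of class `glioma_prep`: list with `train`, `test`,
#'   `standardizer`, `anova`, `dropped`, `mode`.
#' @export
prepare_features <- function(features, mode = c("paper", "sound"),
                             test_fraction = 0.30, split_seed = 42L,
                             smote_k = 5L, smote_seed = 1L,
                             scaler = c("zscore", "minmax"),
                             drop_count = 3L) {
  mode <- match.arg(mode)
  scaler <- match.arg(scaler)
  if (mode == "paper") {
    balanced <- smote_oversample(features, k = smote_k, seed = smote_seed)
    sp <- split_train_test(balanced, test_fraction, seed = split_seed)
  } else {
    sp <- split_train_test(features, test_fraction, seed = split_seed)
    sp$train <- smote_oversample(sp$train, k = smote_k, seed = smote_seed)
  }
  std <- fit_standardizer(sp$train, mode = scaler)
  train_s <- apply_standardizer(std, sp$train)
  test_s <- apply_standardizer(std, sp$test)
  report <- anova_f_scores(train_s)
  train_sel <- select_features(train_s, report, drop_count)
  dropped <- attr(train_sel, "dropped")
  test_sel <- test_s[, setdiff(names(test_s), dropped), drop = FALSE]
  structure(list(train = train_sel, test = test_sel, standardizer = std,
                 anova = report, dropped = dropped, mode = mode),
            class = "glioma_prep")
}

#' @export
print.glioma_prep <- function(x, ...) {
  cat("<glioma_prep> mode=", x$mode, ", train ", nrow(x$train),
      " rows, test ", nrow(x$test), " rows, dropped: ",
      paste(x$dropped, collapse = ", "), "\n", sep = "")
  invisible(x)
}
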