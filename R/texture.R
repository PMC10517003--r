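# ROI intensity moments and grey-level co-occurrence (GLCM) texture
# statistics: the 14 image-derived features of the pipeline.

#' Higher-order intensity moments of an ROI
#'
#' Computes the ROI mean ADC and the central sample moments with equal pixel
#' weight 1/N: variance (m2), standardized skewness `m3 / m2^1.5` and
#' non-excess standardized kurtosis `m4 / m2^2` (a normal population scores
#' 3). A zero-variance (constant) ROI returns skewness and kurtosis 0 with
#' `degenerate = TRUE` rather than failing, so constant phantoms pass
#' through the pipeline.
#'
#' @param adc an `adc_map` or matrix.
#' @param roi logical mask matrix; at least 3 valid pixels.
#' @return object of class `moment_set`: list with `mean_adc`, `variance`,
#'   `skewness`, `kurtosis`, `n`, `degenerate`.
#' @examples
#' m <- roi_moments(matrix(c(1, 2, 3, 4, 5, 9), 2, 3),
#'                  matrix(TRUE, 2, 3))
#' m$mean_adc
#' @export
roi_moments <- function(adc, roi) {
  adc <- as_adc_map(adc)
  if (!identical(dim(roi), dim(adc$values))) abort("roi shape mismatch")
  x <- adc$values[roi & adc$valid]
  n <- length(x)
  if (n < 3) abort("ROI must contain at least 3 valid pixels")
  mu <- mean(x)
  d <- x - mu
  m2 <- mean(d^2)
  degenerate <- diff(range(x)) == 0 || m2 == 0
  if (degenerate) {
    skew <- 0; kurt <- 0
  } else {
    skew <- mean(d^3) / m2^1.5
    kurt <- mean(d^4) / m2^2
  }
  structure(list(mean_adc = mu, variance = m2, skewness = skew,
                 kurtosis = kurt, n = n, degenerate = degenerate),
            class = "moment_set")
}

#' Default GLCM offsets
#'
#' The four unit-distance pixel offsets `(drow, dcol)` corresponding to the
#' 0, 45, 90 and 135 degree orientations whose co-occurrence counts are
#' summed into one matrix.
#'
#' @return list of 4 integer vectors.
#' @export
glcm_offsets <- function() {
  list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
}

#' Accumulate a grey-level co-occurrence matrix over an ROI
#'
#' Counts, for every offset, the ordered pairs of grey levels at pixel
#' positions `p` and `p + offset` where both pixels are valid and inside the
#' ROI, sums the counts over the offsets, and normalizes by the total pair
#' count to a joint probability matrix `P(i, j)`. Accumulation is
#' *asymmetric* by default (each pair counted once in its offset direction);
#' with `symmetric = TRUE` each pair is also counted reversed, making `P`
#' equal to its transpose.
#'
#' @param q a [quantize_roi()] result.
#' @param offsets list of `(drow, dcol)` integer offsets; default the four
#'   unit-distance orientations of [glcm_offsets()].
#' @param symmetric count each pair in both directions? Default `FALSE`.
#' @return object of class `glcm`: list with `probabilities`
#'   (`n_levels` x `n_levels` matrix), `n_levels`, `offsets`, `pair_count`,
#'   `symmetric`.
#' @export
build_glcm <- function(q, offsets = glcm_offsets(), symmetric = FALSE) {
  stopifnot(inherits(q, "quantized_roi"))
  lv <- q$levels
  n <- q$n_levels
  nr <- nrow(lv); nc <- ncol(lv)
  counts <- numeric(n * n)
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    if (length(r1) < 1 || length(c1) < 1) next
    a <- lv[r1, c1, drop = FALSE]
    b <- lv[r1 + dr, c1 + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    idx <- a[ok] * n + b[ok] + 1L
    counts <- counts + tabulate(idx, nbins = n * n)
    if (symmetric) {
      idx_t <- b[ok] * n + a[ok] + 1L
      counts <- counts + tabulate(idx_t, nbins = n * n)
    }
  }
  pair_count <- sum(counts)
  if (pair_count < 1) {
    abort("degenerate ROI: no valid in-ROI pixel pairs for the given offsets")
  }
  # counts index k = i*n + j + 1 -> row i+1, column j+1
  probs <- matrix(counts / pair_count, n, n, byrow = TRUE)
  structure(list(probabilities = probs, n_levels = n, offsets = offsets,
                 pair_count = pair_count, symmetric = symmetric),
            class = "glcm")
}

#' GLCM texture statistics
#'
#' Computes the eleven co-occurrence statistics from a normalized GLCM with
#' levels indexed `0 .. N-1`: the row and column marginal means
#' (`mean_i = sum i P(i,j)`, `mean_j = sum j P(i,j)`) and variances, energy
#' (sum of squared probabilities), entropy (`-sum P ln P` in nats, with
#' `0 ln 0 := 0`), contrast (`sum P (i-j)^2`), homogeneity
#' (`sum P / (1 + (i-j)^2)`), correlation
#' (`sum P (i-mean_i)(j-mean_j) / sqrt(var_i var_j)`, returned 0 and flagged
#' when either marginal variance is 0), cluster shade
#' (`sum (i+j-mean_i-mean_j)^3 P`) and cluster prominence (same, 4th power).
#'
#' @param glcm a [build_glcm()] result.
#' @return object of class `glcm_features`: named list of the 11 statistics
#'   plus `degenerate_correlation`.
#' @export
glcm_features <- function(glcm) {
  stopifnot(inherits(glcm, "glcm"))
  P <- glcm$probabilities
  if (any(P < 0) || abs(sum(P) - 1) > 1e-8) {
    abort("GLCM is not a normalized probability matrix")
  }
  n <- glcm$n_levels
  iv <- 0:(n - 1)
  pi_m <- rowSums(P) # marginal over i
  pj_m <- colSums(P)
  mean_i <- sum(iv * pi_m)
  mean_j <- sum(iv * pj_m)
  var_i <- sum((iv - mean_i)^2 * pi_m)
  var_j <- sum((iv - mean_j)^2 * pj_m)
  dmat <- outer(iv, iv, "-")
  smat <- outer(iv, iv, "+") - mean_i - mean_j
  energy <- sum(P^2)
  entropy <- -sum(P[P > 0] * log(P[P > 0]))
  contrast <- sum(P * dmat^2)
  homogeneity <- sum(P / (1 + dmat^2))
  degenerate_correlation <- (var_i * var_j) == 0
  correlation <- if (degenerate_correlation) 0 else {
    sum(P * outer(iv - mean_i, iv - mean_j)) / sqrt(var_i * var_j)
  }
  structure(list(mean_i = mean_i, mean_j = mean_j,
                 variance_i = var_i, variance_j = var_j,
                 energy = energy, entropy = entropy, contrast = contrast,
                 homogeneity = homogeneity, correlation = correlation,
                 cluster_shade = sum(P * smat^3),
                 cluster_prominence = sum(P * smat^4),
                 degenerate_correlation = degenerate_correlation),
            class = "glcm_features")
}

#' Extract the 16-feature vector of one slice ROI
#'
#' Composes the moment and GLCM operations into the ordered per-ROI feature
#' row used throughout the pipeline (see [glioma_feature_names()]): mean
#' ADC, skewness, kurtosis, the nine GLCM statistics, age and gender.
#'
#' @param adc an `adc_map` or matrix.
#' @param roi logical mask matrix.
#' @param age subject age in years.
#' @param gender subject gender, coded male = 1 / female = 0.
#' @param n_levels grey levels for quantization (default 64).
#' @param offsets GLCM offsets, default [glcm_offsets()].
#' @param symmetric symmetric GLCM accumulation? Default `FALSE`.
#' @return one-row tibble with the 16 feature columns.
#' @export
extract_feature_vector <- function(adc, roi, age, gender, n_levels = 64L,
                                   offsets = glcm_offsets(),
                                   symmetric = FALSE) {
  if (is.null(age) || is.null(gender) || is.na(age) || is.na(gender)) {
    abort("missing demographics (age/gender)")
  }
  mom <- roi_moments(adc, roi)
  q <- quantize_roi(adc, roi, n_levels = n_levels)
  g <- glcm_features(build_glcm(q, offsets = offsets, symmetric = symmetric))
  tibble(mean_adc = mom$mean_adc, skewness = mom$skewness,
         kurtosis = mom$kurtosis,
         glcm_mean_1 = g$mean_i, glcm_mean_2 = g$mean_j,
         glcm_variance_1 = g$variance_i, glcm_variance_2 = g$variance_j,
         energy = g$energy, entropy = g$entropy, contrast = g$contrast,
         homogeneity = g$homogeneity, correlation = g$correlation,
         prominence = g$cluster_prominence, shade = g$cluster_shade,
         age = as.numeric(age), gender = as.numeric(gender))
}

#' Extract the feature table of a whole cohort
#'
#' For every slice ROI of a synthetic cohort: computes the ADC map from the
#' noisy DWI pair (not from the ground-truth field), restricts to the ROI,
#' and extracts the 16-feature vector plus identifiers and class label.
#'
#' @param cohort a [generate_cohort()] result.
#' @inheritParams extract_feature_vector
#' @return tibble with columns `slice_id`, `subject_id`, `who_class`,
#'   `class` (0 = GBM, 1 = HGG, 2 = LGG), and the 16 features.
#' @export
extract_features <- function(cohort, n_levels = 64L,
                             offsets = glcm_offsets(), symmetric = FALSE) {
  stopifnot(inherits(cohort, "glioma_cohort"))
  sl <- cohort$slices
  rows <- purrr::map(seq_len(nrow(sl)), function(i) {
    adc <- compute_adc_map(sl$dwi[[i]])
    extract_feature_vector(adc, sl$roi[[i]], sl$age[i], sl$gender[i],
                           n_levels = n_levels, offsets = offsets,
                           symmetric = symmetric)
  }) |> purrr::list_rbind()
  bind_cols(sl |> select("slice_id", "subject_id", "who_class", "class"),
            rows)
}
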