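as_map <- function(x) matrix(x, 1, length(x))
all_roi <- function(x) matrix(TRUE, 1, length(x))

test_that("moments reproduce hand-worked and textbook values", {
  # symmetric sample: zero skewness; uniform 1..5 kurtosis from the oracle
  m <- roi_moments(as_map(1:5), all_roi(1:5))
  expect_equal(m$mean_adc, 3)
  expect_equal(m$skewness, 0)
  o <- oracle_moments(1:5)
  expect_equal(m$kurtosis, o$kurtosis, tolerance = 1e-12)
  # {0,0,0,1}: worked example
  m2 <- roi_moments(as_map(c(0, 0, 0, 1)), all_roi(1:4))
  expect_equal(m2$mean_adc, 0.25)
  expect_equal(m2$variance, 0.1875)
  expect_equal(m2$skewness, 1.1547, tolerance = 1e-4)
  expect_equal(m2$kurtosis, 2.3333, tolerance = 1e-4)
  o2 <- oracle_moments(c(0, 0, 0, 1))
  expect_equal(m2$skewness, o2$skewness, tolerance = 1e-12)
  expect_equal(m2$kurtosis, o2$kurtosis, tolerance = 1e-12)
})

test_that("moments agree with the brute-force oracle on random samples", {
  withr::with_seed(3, {
    for (rep in 1:25) {
      x <- rnorm(sample(10:200, 1), mean = runif(1, -5, 5),
                 sd = runif(1, 0.1, 3))
      m <- roi_moments(as_map(x), all_roi(x))
      o <- oracle_moments(x)
      expect_equal(m$mean_adc, o$mean, tolerance = 1e-12)
      expect_equal(m$skewness, o$skewness, tolerance = 1e-12)
      expect_equal(m$kurtosis, o$kurtosis, tolerance = 1e-12)
      # Pearson inequality: kurtosis >= skewness^2 + 1
      expect_gte(m$kurtosis, m$skewness^2 + 1 - 1e-10)
    }
  })
})

test_that("constant ROI moments are flagged degenerate, not NaN", {
  m <- roi_moments(matrix(2, 3, 3), matrix(TRUE, 3, 3))
  expect_true(m$degenerate)
  expect_equal(m$skewness, 0)
  expect_equal(m$kurtosis, 0)
  expect_error(roi_moments(matrix(1, 2, 2), matrix(c(TRUE, TRUE, FALSE,
                                                     FALSE), 2, 2)),
               "at least 3")
})

test_that("GLCM of a constant region is a single unit entry", {
  q <- quantize_roi(matrix(1, 3, 3), matrix(TRUE, 3, 3), n_levels = 4)
  g <- build_glcm(q)
  expect_equal(g$probabilities[1, 1], 1)
  expect_equal(sum(g$probabilities), 1)
  expect_equal(sum(g$probabilities != 0), 1)
  # 3x3 grid, 4 unit offsets: 6 + 4 + 6 + 4 ordered pairs
  expect_equal(g$pair_count, 20)
})

test_that("GLCM accumulation matches exhaustive enumeration", {
  # the 2x2 checkerboard-ish worked example
  lv <- matrix(c(0L, 0L, 1L, 1L), 2, 2) # levels [[0,1],[0,1]] by row
  q <- structure(list(levels = lv, n_levels = 2L,
                      quantization_range = c(0, 1), n_valid = 4L),
                 class = "quantized_roi")
  g <- build_glcm(q)
  expect_equal(g$probabilities, naive_glcm(lv, 2), tolerance = 1e-15)
  # random masked ROIs, asymmetric and symmetric
  withr::with_seed(4, {
    for (rep in 1:30) {
      q <- random_quantized()
      for (sym in c(FALSE, TRUE)) {
        g <- build_glcm(q, symmetric = sym)
        expect_equal(g$probabilities, naive_glcm(q$levels, q$n_levels,
                                                 symmetric = sym),
                     tolerance = 1e-14)
        if (sym) expect_equal(g$probabilities, t(g$probabilities))
      }
    }
  })
})

test_that("a one-pixel ROI has no co-occurring pairs and errors", {
  lv <- matrix(NA_integer_, 3, 3); lv[2, 2] <- 1L
  q <- structure(list(levels = lv, n_levels = 4L,
                      quantization_range = c(0, 1), n_valid = 1L),
                 class = "quantized_roi")
  expect_error(build_glcm(q), "degenerate")
})

test_that("GLCM features hit the analytic fixed points", {
  # constant image: single entry at (g, g)
  q <- quantize_roi(matrix(5, 4, 4), matrix(TRUE, 4, 4), n_levels = 8)
  f <- glcm_features(build_glcm(q))
  expect_equal(f$energy, 1)
  expect_equal(f$entropy, 0)
  expect_equal(f$contrast, 0)
  expect_equal(f$homogeneity, 1)
  expect_equal(f$variance_i, 0)
  expect_equal(f$variance_j, 0)
  expect_equal(f$cluster_shade, 0)
  expect_equal(f$cluster_prominence, 0)
  expect_equal(f$mean_i, 0) # constant ROI quantizes to level 0
  expect_equal(f$correlation, 0)
  expect_true(f$degenerate_correlation)
  # uniform 2-level GLCM: closed forms
  g <- structure(list(probabilities = matrix(0.25, 2, 2), n_levels = 2L,
                      offsets = glcm_offsets(), pair_count = 4L,
                      symmetric = TRUE), class = "glcm")
  fu <- glcm_features(g)
  expect_equal(fu$energy, 0.25)
  expect_equal(fu$entropy, log(4))
  expect_equal(fu$contrast, 0.5)
  expect_equal(fu$correlation, 0)
})

test_that("vectorized features equal the naive reference on random GLCMs", {
  withr::with_seed(5, {
    for (rep in 1:50) {
      n <- sample(2:10, 1)
      P <- matrix(stats::rexp(n * n), n, n)
      P <- P / sum(P)
      g <- structure(list(probabilities = P, n_levels = n,
                          offsets = glcm_offsets(), pair_count = 100L,
                          symmetric = FALSE), class = "glcm")
      f <- glcm_features(g)
      o <- naive_glcm_features(P)
      for (nm in names(o)) {
        expect_equal(f[[nm]], o[[nm]], tolerance = 1e-12)
      }
      # ranges
      expect_true(f$energy > 0 && f$energy <= 1)
      expect_true(f$entropy >= 0 && f$entropy <= 2 * log(n) + 1e-12)
      expect_lte(abs(f$correlation), 1 + 1e-12)
      expect_gte(f$contrast, 0)
      expect_gte(f$cluster_prominence, 0)
      expect_true(f$homogeneity > 0 && f$homogeneity <= 1)
    }
  })
  g_bad <- structure(list(probabilities = matrix(0.5, 2, 2), n_levels = 2L,
                          offsets = list(), pair_count = 1L,
                          symmetric = FALSE), class = "glcm")
  expect_error(glcm_features(g_bad), "normalized")
})

test_that("GLCM features are invariant to monotone affine ADC rescaling", {
  withr::with_seed(6, {
    adc <- matrix(runif(400, 0.5e-3, 1.5e-3), 20, 20)
    roi <- matrix(runif(400) < 0.6, 20, 20)
    f1 <- glcm_features(build_glcm(quantize_roi(adc, roi, 16)))
    f2 <- glcm_features(build_glcm(quantize_roi(1e4 * adc + 2, roi, 16)))
    expect_equal(unclass(f1), unclass(f2), tolerance = 1e-12)
  })
})

test_that("feature vectors have the 16 canonical columns and symmetry ties", {
  withr::with_seed(7, {
    adc <- matrix(runif(400, 0.5e-3, 1.5e-3), 20, 20)
    roi <- matrix(runif(400) < 0.6, 20, 20)
    v <- extract_feature_vector(adc, roi, age = 40, gender = 1)
    expect_equal(names(v), glioma_feature_names())
    expect_equal(nrow(v), 1)
    # symmetric accumulation ties the two means and variances
    vs <- extract_feature_vector(adc, roi, age = 40, gender = 1,
                                 symmetric = TRUE)
    expect_equal(vs$glcm_mean_1, vs$glcm_mean_2, tolerance = 1e-12)
    expect_equal(vs$glcm_variance_1, vs$glcm_variance_2, tolerance = 1e-12)
    # constant ROI: composed degenerate conventions
    vc <- extract_feature_vector(matrix(1e-3, 10, 10), matrix(TRUE, 10, 10),
                                 age = 40, gender = 0)
    expect_equal(vc$skewness, 0)
    expect_equal(vc$kurtosis, 0)
    expect_equal(vc$energy, 1)
    expect_equal(vc$contrast, 0)
    expect_error(extract_feature_vector(adc, roi, age = NA, gender = 1),
                 "demographics")
  })
})
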