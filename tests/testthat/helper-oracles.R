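# Independent reference implementations (deliberately naive) and small
# fixture builders shared across the test files.

# Naive GLCM accumulation: explicit double loop over every pixel and offset.
naive_glcm <- function(levels, n_levels, offsets = gliotex::glcm_offsets(),
                       symmetric = FALSE) {
  counts <- matrix(0, n_levels, n_levels)
  nr <- nrow(levels); nc <- ncol(levels)
  for (off in offsets) {
    for (r in seq_len(nr)) {
      for (c in seq_len(nc)) {
        r2 <- r + off[1]; c2 <- c + off[2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        a <- levels[r, c]; b <- levels[r2, c2]
        if (is.na(a) || is.na(b)) next
        counts[a + 1, b + 1] <- counts[a + 1, b + 1] + 1
        if (symmetric) counts[b + 1, a + 1] <- counts[b + 1, a + 1] + 1
      }
    }
  }
  counts / sum(counts)
}

# Naive per-cell evaluation of all eleven GLCM statistics.
naive_glcm_features <- function(P) {
  n <- nrow(P)
  mu_i <- 0; mu_j <- 0
  for (i in 0:(n - 1)) for (j in 0:(n - 1)) {
    mu_i <- mu_i + i * P[i + 1, j + 1]
    mu_j <- mu_j + j * P[i + 1, j + 1]
  }
  var_i <- 0; var_j <- 0; enr <- 0; ent <- 0; cnt <- 0; hom <- 0
  corr_num <- 0; cs <- 0; cp <- 0
  for (i in 0:(n - 1)) for (j in 0:(n - 1)) {
    p <- P[i + 1, j + 1]
    var_i <- var_i + p * (i - mu_i)^2
    var_j <- var_j + p * (j - mu_j)^2
    enr <- enr + p^2
    if (p > 0) ent <- ent - p * log(p)
    cnt <- cnt + p * (i - j)^2
    hom <- hom + p / (1 + (i - j)^2)
    corr_num <- corr_num + p * (i - mu_i) * (j - mu_j)
    cs <- cs + p * (i + j - mu_i - mu_j)^3
    cp <- cp + p * (i + j - mu_i - mu_j)^4
  }
  corr <- if (var_i * var_j == 0) 0 else corr_num / sqrt(var_i * var_j)
  list(mean_i = mu_i, mean_j = mu_j, variance_i = var_i, variance_j = var_j,
       energy = enr, entropy = ent, contrast = cnt, homogeneity = hom,
       correlation = corr, cluster_shade = cs, cluster_prominence = cp)
}

# Direct textbook standardized moments.
oracle_moments <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  list(mean = mu, variance = m2, skewness = m3 / m2^1.5,
       kurtosis = m4 / m2^2)
}

# One-way F via R's own linear-model machinery.
oracle_anova_f <- function(x, g) {
  tab <- anova(stats::aov(x ~ factor(g)))
  tab$`F value`[1]
}

# AUC by exhaustive pairwise comparison (ties count 1/2).
brute_auc <- function(score, positive) {
  pos <- score[positive]; neg <- score[!positive]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Small random quantized-ROI object built directly (bypasses quantize_roi).
random_quantized <- function(nr = 12, nc = 12, n_levels = 8, p_roi = 0.8) {
  lv <- matrix(sample(0:(n_levels - 1), nr * nc, replace = TRUE), nr, nc)
  lv[matrix(runif(nr * nc) > p_roi, nr, nc)] <- NA
  structure(list(levels = lv, n_levels = as.integer(n_levels),
                 quantization_range = c(0, 1), n_valid = sum(!is.na(lv))),
            class = "quantized_roi")
}

# Tiny but complete cohort configuration for fast end-to-end tests
# (any default can be overridden through ...).
tiny_config <- function(seed = 42L, ...) {
  args <- utils::modifyList(
    list(n_subjects = 6L, n_male = 4L, n_female = 2L,
         slices_per_class = c(GBM = 30L, HGG = 20L, LGG = 15L),
         image_shape = c(48L, 48L), roi_area_range = c(60, 300),
         seed = seed),
    list(...))
  do.call(gliotex::cohort_config, args)
}

# Separable three-class Gaussian feature table for modeling tests.
separable_table <- function(n_per_class = 50, sep = 6, seed = 1,
                            n_features = 4) {
  withr::with_seed(seed, {
    purrr::map(0:2, function(cl) {
      X <- matrix(rnorm(n_per_class * n_features, mean = sep * cl),
                  n_per_class, n_features)
      colnames(X) <- paste0("f", seq_len(n_features))
      dplyr::mutate(tibble::as_tibble(X), class = cl)
    }) |> purrr::list_rbind()
  })
}
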