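# Synthetic phantom cohort: class-dependent diffusivity and texture so the
# full feature/modeling pipeline is exercisable without patient data.

#' Configuration of a synthetic diffusion-MRI glioma cohort
#'
#' Describes the phantom study: cohort demographics, per-class slice counts,
#' acquisition geometry (image matrix, b-values), and the class-dependent
#' diffusivity/texture parameters of the generative model. Defaults mirror a
#' 722-slice three-class study (431 GBM / 182 HGG / 109 LGG slices from 88
#' subjects, 57 male and 31 female, ages 8-90, 124x124 matrix, b = 0 and
#' 1000 s/mm^2).
#'
#' Each slice is a smooth Gaussian-random-field ADC texture with class mean
#' `class_adc_mean`, marginal standard deviation `class_adc_sd`, spatial
#' correlation length `class_corr_length`, and a per-slice mean offset of sd
#' `between_slice_sd`; an elliptical tumor ROI restricts all feature
#' computation. DWI signal pairs are synthesized from the field by
#' mono-exponential attenuation plus additive Gaussian noise.
#'
#' @param n_subjects,n_male,n_female cohort size and gender split
#'   (`n_male + n_female` must equal `n_subjects`).
#' @param age_range inclusive age range in years.
#' @param slices_per_class named integer vector of slice counts per class
#'   (names `GBM`, `HGG`, `LGG`).
#' @param image_shape image matrix size in pixels, `c(rows, cols)`.
#' @param b_values diffusion sensitizations in s/mm^2; must include 0 and at
#'   least one positive value.
#' @param class_adc_mean,class_adc_sd per-class mean and marginal sd of the
#'   ADC field, mm^2/s.
#' @param class_corr_length per-class spatial correlation length of the
#'   texture field, pixels.
#' @param between_slice_sd sd of the per-slice offset of the field mean,
#'   mm^2/s (slice-to-slice biological variability).
#' @param noise_sd additive Gaussian noise sd on the synthesized DWI signal,
#'   signal units.
#' @param s0_mean noise-free b = 0 signal level, signal units.
#' @param roi_area_range admissible ROI area range in pixels.
#' @param rois_per_slice number of ROIs drawn per slice (each yields its own
#'   feature row).
#' @param age_class_shift optional deterministic age shift (years per class
#'   code) for power studies; 0 = demographics carry no class signal.
#' @param seed integer seed fixing the whole cohort.
#' @return an object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_subjects = 88L, n_male = 57L, n_female = 31L,
                          age_range = c(8, 90),
                          slices_per_class = c(GBM = 431L, HGG = 182L, LGG = 109L),
                          image_shape = c(124L, 124L),
                          b_values = c(0, 1000),
                          class_adc_mean = c(GBM = 0.80e-3, HGG = 1.00e-3, LGG = 1.30e-3),
                          class_adc_sd = c(GBM = 0.22e-3, HGG = 0.18e-3, LGG = 0.12e-3),
                          class_corr_length = c(GBM = 2, HGG = 3.5, LGG = 5),
                          between_slice_sd = 0.10e-3,
                          noise_sd = 5,
                          s0_mean = 1000,
                          roi_area_range = c(80, 600),
                          rois_per_slice = 1L,
                          age_class_shift = 0,
                          seed = 42L) {
  cls <- glioma_classes()
  stopifnot(length(image_shape) == 2, length(age_range) == 2)
  if (n_male + n_female != n_subjects) {
    abort("n_male + n_female must equal n_subjects")
  }
  if (!all(cls %in% names(slices_per_class))) {
    abort("slices_per_class must be named GBM, HGG, LGG")
  }
  slices_per_class <- slices_per_class[cls]
  if (any(slices_per_class < 1)) abort("all slice counts must be >= 1")
  if (n_subjects < length(cls)) abort("need at least one subject per class")
  if (age_range[1] >= age_range[2]) abort("age_range low must be < high")
  for (nm in c("class_adc_mean", "class_adc_sd", "class_corr_length")) {
    v <- get(nm)
    if (!all(cls %in% names(v))) abort(paste(nm, "must be named GBM, HGG, LGG"))
  }
  if (any(class_adc_mean <= 0)) abort("class_adc_mean values must be positive")
  if (any(class_adc_sd < 0) || any(class_corr_length < 0)) {
    abort("sd and correlation length must be non-negative")
  }
  if (!any(b_values == 0) || !any(b_values > 0)) {
    abort("b_values must include 0 and at least one positive value")
  }
  if (roi_area_range[1] < 1 || roi_area_range[1] > roi_area_range[2]) {
    abort("invalid roi_area_range")
  }
  if (roi_area_range[2] > prod(image_shape)) {
    abort("roi_area_range exceeds the image area")
  }
  structure(
    list(n_subjects = as.integer(n_subjects), n_male = as.integer(n_male),
         n_female = as.integer(n_female), age_range = age_range,
         slices_per_class = slices_per_class,
         image_shape = as.integer(image_shape), b_values = b_values,
         class_adc_mean = class_adc_mean[cls], class_adc_sd = class_adc_sd[cls],
         class_corr_length = class_corr_length[cls],
         between_slice_sd = between_slice_sd, noise_sd = noise_sd,
         s0_mean = s0_mean, roi_area_range = roi_area_range,
         rois_per_slice = as.integer(rois_per_slice),
         age_class_shift = age_class_shift, seed = as.integer(seed)),
    class = "cohort_config")
}

# Largest-remainder apportionment of `total` over weights `w` (all parts >= 1).
apportion <- function(total, w) {
  raw <- total * w / sum(w)
  base <- pmax(1L, floor(raw))
  left <- total - sum(base)
  if (left > 0) {
    extra <- order(raw - floor(raw), decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1L
  } else if (left < 0) {
    # over-allocation can only come from the pmax floor; shave largest parts
    for (k in seq_len(-left)) {
      i <- which.max(base)
      base[i] <- base[i] - 1L
    }
  }
  as.integer(base)
}

#' Sample phantom cohort demographics
#'
#' Draws the subject table: ids, ages uniform over the configured range,
#' genders with the exact configured male/female split, and a WHO class per
#' subject. Subjects are apportioned across classes proportionally to the
#' configured slice counts (largest-remainder rounding, at least one subject
#' per class).
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; `NULL` uses the current RNG state (as when called
#'   from [generate_cohort()]).
#' @return tibble with columns `subject_id`, `age`, `gender` (1 = male,
#'   0 = female), `who_class`, `class`.
#' @export
sample_demographics <- function(config, seed = config$seed) {
  run <- function() {
    n <- config$n_subjects
    cls <- glioma_classes()
    per_class <- apportion(n, as.numeric(config$slices_per_class))
    who <- rep(cls, per_class)
    age <- sample(seq(config$age_range[1], config$age_range[2]), n, replace = TRUE)
    if (config$age_class_shift != 0) {
      age <- pmin(config$age_range[2], pmax(
        config$age_range[1],
        age + round(config$age_class_shift * (glioma_class_code(who)))))
    }
    gender <- rep(0L, n)
    gender[sample.int(n, config$n_male)] <- 1L
    tibble(subject_id = sprintf("sub%03d", seq_len(n)),
           age = as.integer(age), gender = gender,
           who_class = who, class = glioma_class_code(who))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Stationary Gaussian random field with unit ensemble marginal sd and zero
# mean, via FFT convolution of white noise with an isotropic Gaussian
# kernel. Normalization uses the kernel's analytic output variance (not the
# per-field empirical sd), so long correlation lengths legitimately shift
# variance from within-field to between-field.
gaussian_random_field <- function(shape, corr_length) {
  nr <- shape[1]; nc <- shape[2]
  white <- matrix(rnorm(nr * nc), nr, nc)
  if (corr_length <= 0) return(white)
  dr <- 0:(nr - 1); dr <- pmin(dr, nr - dr)
  dc <- 0:(nc - 1); dc <- pmin(dc, nc - dc)
  kern <- exp(-outer(dr^2, dc^2, "+") / (2 * corr_length^2))
  kern <- kern / sum(kern)
  f <- Re(fft(fft(white) * fft(kern), inverse = TRUE)) / (nr * nc)
  f <- f - mean(f)
  # pixel variance of the mean-removed convolved field
  sd_theory <- sqrt(max(sum(kern^2) - 1 / (nr * nc), .Machine$double.eps))
  f / sd_theory
}

# One elliptical ROI with pixel area inside `area_range`; bounded retries.
sample_ellipse_roi <- function(shape, area_range, max_tries = 25L) {
  nr <- shape[1]; nc <- shape[2]
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (k in seq_len(max_tries)) {
    area <- runif(1, area_range[1], area_range[2])
    ratio <- runif(1, 0.4, 1)
    theta <- runif(1, 0, pi)
    a <- sqrt(area / (pi * ratio))
    b <- a * ratio
    cy <- runif(1, 0.30, 0.70) * nr
    cx <- runif(1, 0.30, 0.70) * nc
    dy <- rows - cy; dx <- cols - cx
    u <- (dx * cos(theta) + dy * sin(theta)) / a
    v <- (-dx * sin(theta) + dy * cos(theta)) / b
    mask <- (u^2 + v^2) <= 1
    npix <- sum(mask)
    if (npix >= area_range[1] && npix <= area_range[2]) return(mask)
  }
  abort("could not draw an ROI within the configured area range")
}

#' Simulate one class-conditional ADC texture field with a tumor ROI
#'
#' Draws a smooth Gaussian-random-field ADC texture for the given WHO class
#' (class mean plus a per-slice mean offset, class marginal sd, class
#' correlation length), clipped positive, together with one elliptical ROI
#' whose area falls in the configured range.
#'
#' @param who_class `"GBM"`, `"HGG"` or `"LGG"`.
#' @param config a [cohort_config()].
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return list with `adc` (matrix, mm^2/s) and `roi` (logical matrix).
#' @export
simulate_adc_field <- function(who_class, config, seed = NULL) {
  who_class <- match.arg(who_class, glioma_classes())
  run <- function() {
    mu <- config$class_adc_mean[[who_class]] +
      rnorm(1, 0, config$between_slice_sd)
    s <- config$class_adc_sd[[who_class]]
    field <- if (s > 0) {
      gaussian_random_field(config$image_shape,
                            config$class_corr_length[[who_class]])
    } else {
      matrix(0, config$image_shape[1], config$image_shape[2])
    }
    adc <- pmax(mu + s * field, 1e-6)
    roi <- sample_ellipse_roi(config$image_shape, config$roi_area_range)
    list(adc = adc, roi = roi)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Construct a DWI slice pair object
#'
#' Bundles a b = 0 image with one or more diffusion-weighted images of the
#' same slice.
#'
#' @param s0 b = 0 image matrix (signal units).
#' @param sb a matrix (single DWI) or list of matrices.
#' @param b positive b-value(s) in s/mm^2, one per element of `sb`.
#' @return object of class `dwi_pair`.
#' @export
dwi_pair <- function(s0, sb, b) {
  if (is.matrix(sb)) sb <- list(sb)
  if (length(sb) != length(b)) abort("need one b-value per DWI image")
  if (length(b) == 0) abort("at least one diffusion-weighted image required")
  if (any(b <= 0)) abort("all diffusion b-values must be positive")
  shp <- dim(s0)
  for (img in sb) {
    if (!identical(dim(img), shp)) abort("all images must share one shape")
  }
  structure(list(s0 = s0, sb = sb, b = as.numeric(b), shape = shp),
            class = "dwi_pair")
}

#' Synthesize a DWI pair from an ADC field
#'
#' Forward model of the diffusion experiment: per pixel,
#' `S_b = S_0 * exp(-b * ADC)` with `S_0 = s0_mean`, plus additive Gaussian
#' noise of sd `noise_sd` on every image (including b = 0).
#'
#' @param adc positive ADC field matrix, mm^2/s.
#' @param config a [cohort_config()] supplying `b_values`, `s0_mean`,
#'   `noise_sd`.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return a [dwi_pair()].
#' @export
synthesize_dwi_pair <- function(adc, config, seed = NULL) {
  if (any(adc <= 0)) abort("adc field must be positive")
  if (any(config$b_values < 0)) abort("negative b-value")
  run <- function() {
    noisy <- function(img) {
      if (config$noise_sd > 0) img + rnorm(length(img), 0, config$noise_sd)
      else img
    }
    s0 <- noisy(matrix(config$s0_mean, nrow(adc), ncol(adc)))
    bpos <- config$b_values[config$b_values > 0]
    sb <- lapply(bpos, function(b) noisy(config$s0_mean * exp(-b * adc)))
    dwi_pair(s0, sb, bpos)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate a full synthetic cohort
#'
#' Draws demographics, then for every configured slice simulates the
#' ground-truth ADC texture field, its tumor ROI(s), and the corresponding
#' noisy DWI pair. Slices are linked to subjects of the same WHO class
#' (round-robin over a shuffled subject order). The whole cohort is a
#' deterministic function of `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return object of class `glioma_cohort`: list with `subjects` (tibble),
#'   `slices` (tibble with list-columns `dwi`, `adc_true`, `roi`), and
#'   `config`.
#' @examples
#' cfg <- cohort_config(n_subjects = 3, n_male = 2, n_female = 1,
#'                      slices_per_class = c(GBM = 2, HGG = 2, LGG = 2),
#'                      image_shape = c(32, 32), roi_area_range = c(40, 120))
#' cohort <- generate_cohort(cfg)
#' cohort$slices
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, {
    subjects <- sample_demographics(config, seed = NULL)
    slices <- purrr::map(glioma_classes(), function(cl) {
      n_sl <- config$slices_per_class[[cl]]
      subj <- subjects$subject_id[subjects$who_class == cl]
      owner <- rep_len(sample(subj), n_sl)
      purrr::map(seq_len(n_sl), function(i) {
        rois <- purrr::map(seq_len(config$rois_per_slice), function(r) {
          simulate_adc_field(cl, config, seed = NULL)
        })
        # one texture field per slice; extra ROIs (if configured) reuse it
        field <- rois[[1]]$adc
        dwi <- synthesize_dwi_pair(field, config, seed = NULL)
        tibble(subject_id = owner[i], who_class = cl,
               roi_index = seq_len(config$rois_per_slice),
               dwi = list(dwi), adc_true = list(field),
               roi = purrr::map(rois, "roi"))
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
    slice_no <- rep(seq_len(nrow(slices) / config$rois_per_slice),
                    each = config$rois_per_slice)
    slices <- slices |>
      mutate(slice_id = sprintf("sl%04d_%d", slice_no, .data$roi_index),
             class = glioma_class_code(.data$who_class)) |>
      left_join(subjects |> select("subject_id", "age", "gender"),
                by = "subject_id") |>
      select("slice_id", "subject_id", "who_class", "class", "age",
             "gender", "roi_index", "dwi", "adc_true", "roi")
    structure(list(subjects = subjects, slices = slices, config = config),
              class = "glioma_cohort")
  })
}

#' @export
print.glioma_cohort <- function(x, ...) {
  counts <- table(x$slices$who_class)[glioma_classes()]
  cat("<glioma_cohort> ", nrow(x$subjects), " subjects, ",
      nrow(x$slices), " slice ROIs (",
      paste(glioma_classes(), counts, sep = "=", collapse = ", "),
      "), ", x$config$image_shape[1], "x", x$config$image_shape[2],
      " px, seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config> ", x$n_subjects, " subjects (",
      x$n_male, "M/", x$n_female, "F), slices ",
      paste(names(x$slices_per_class), x$slices_per_class,
            sep = "=", collapse = ", "),
      ", b = {", paste(x$b_values, collapse = ", "), "} s/mm^2, seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}
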