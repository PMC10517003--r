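test_that("default demographics match the study composition", {
  demo <- sample_demographics(cohort_config())
  expect_equal(nrow(demo), 88)
  expect_equal(sum(demo$gender == 1), 57)
  expect_equal(sum(demo$gender == 0), 31)
  expect_true(all(demo$age >= 8 & demo$age <= 90))
  expect_true(all(glioma_classes() %in% demo$who_class))
})

test_that("degenerate and infeasible configurations are handled", {
  cfg <- cohort_config(n_subjects = 3, n_male = 3, n_female = 0,
                       slices_per_class = c(GBM = 1, HGG = 1, LGG = 1),
                       image_shape = c(32, 32), roi_area_range = c(40, 120))
  demo <- sample_demographics(cfg)
  expect_equal(nrow(demo), 3)
  expect_true(all(demo$gender == 1))
  expect_error(cohort_config(n_subjects = 5, n_male = 3, n_female = 1),
               "n_male")
  expect_error(cohort_config(n_subjects = 2, n_male = 1, n_female = 1),
               "one subject per class")
  expect_error(cohort_config(age_range = c(90, 8)), "age_range")
  expect_error(cohort_config(slices_per_class = c(GBM = 0, HGG = 1, LGG = 1)),
               "slice counts")
})

test_that("cohort generation is deterministic and hits configured counts", {
  cfg <- tiny_config()
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$slices, b$slices)
  expect_identical(a$subjects, b$subjects)
  counts <- table(a$slices$who_class)
  expect_equal(as.integer(counts[glioma_classes()]), c(30L, 20L, 15L))
  # every slice belongs to a subject of the same class
  joined <- merge(a$slices[, c("subject_id", "who_class")],
                  a$subjects[, c("subject_id", "who_class")],
                  by = "subject_id")
  expect_true(all(joined$who_class.x == joined$who_class.y))
  # slice arithmetic with uniform counts
  cfg2 <- cohort_config(n_subjects = 3, n_male = 2, n_female = 1,
                        slices_per_class = c(GBM = 2, HGG = 2, LGG = 2),
                        image_shape = c(32, 32), roi_area_range = c(40, 120))
  expect_equal(nrow(generate_cohort(cfg2)$slices), 6)
})

test_that("zero-variance class parameters yield a constant ADC field", {
  cfg <- tiny_config(class_adc_sd = c(GBM = 0, HGG = 0, LGG = 0),
                     between_slice_sd = 0)
  f <- simulate_adc_field("GBM", cfg, seed = 7)
  expect_equal(diff(range(f$adc[f$roi])), 0)
  expect_equal(mean(f$adc), cfg$class_adc_mean[["GBM"]])
  expect_true(sum(f$roi) >= cfg$roi_area_range[1])
  expect_true(sum(f$roi) <= cfg$roi_area_range[2])
})

test_that("ROI-mean ADC of GBM fields is below LGG at every matched percentile", {
  cfg <- tiny_config()
  means <- withr::with_seed(11, {
    lapply(c("GBM", "LGG"), function(cl) {
      vapply(1:200, function(i) {
        f <- simulate_adc_field(cl, cfg)
        mean(f$adc[f$roi])
      }, numeric(1))
    })
  })
  expect_true(all(sort(means[[1]]) < sort(means[[2]])))
})

test_that("field variance shrinks as the correlation length grows", {
  # long-range fields are smooth: within-ROI spread falls well below the
  # marginal sd while short-range fields retain it
  cfg_short <- tiny_config(class_corr_length = c(GBM = 1, HGG = 1, LGG = 1))
  cfg_long <- tiny_config(class_corr_length = c(GBM = 16, HGG = 16, LGG = 16))
  sds <- withr::with_seed(5, {
    vapply(list(cfg_short, cfg_long), function(cfg) {
      mean(vapply(1:40, function(i) {
        f <- simulate_adc_field("GBM", cfg)
        sd(f$adc[f$roi])
      }, numeric(1)))
    }, numeric(1))
  })
  expect_lt(sds[2], 0.5 * sds[1])
})

test_that("DWI synthesis follows the closed-form attenuation", {
  cfg <- tiny_config(noise_sd = 0, image_shape = c(8L, 8L),
                     roi_area_range = c(4, 40))
  adc <- matrix(1.0e-3, 8, 8)
  pair <- synthesize_dwi_pair(adc, cfg)
  expect_equal(pair$s0, matrix(1000, 8, 8)) # b = 0: S = S0 exactly
  expect_equal(pair$sb[[1]], matrix(1000 * exp(-1), 8, 8))
  expect_equal(pair$sb[[1]][1, 1], 367.8794, tolerance = 1e-6)
  expect_error(synthesize_dwi_pair(matrix(-1, 8, 8), cfg), "positive")
})

test_that("noise-free synthesis and ADC computation are inverse operations", {
  cfg <- tiny_config(noise_sd = 0)
  f <- simulate_adc_field("HGG", cfg, seed = 3)
  pair <- synthesize_dwi_pair(f$adc, cfg, seed = 4)
  rec <- compute_adc_map(pair)
  expect_true(all(rec$valid))
  expect_lt(max(abs(rec$values - f$adc) / f$adc), 1e-10)
  # also with two positive b-values
  cfg2 <- tiny_config(noise_sd = 0, b_values = c(0, 500, 1000))
  pair2 <- synthesize_dwi_pair(f$adc, cfg2)
  rec2 <- compute_adc_map(pair2)
  expect_lt(max(abs(rec2$values - f$adc) / f$adc), 1e-10)
})
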