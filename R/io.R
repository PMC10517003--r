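# Standard-format I/O: NIfTI and 16-bit PNG images, CSV tables, JSON
# configuration and reports.

#' Read and write ADC maps and masks as NIfTI
#'
#' Images are stored as plain 2D NIfTI volumes; ADC values are written in
#' mm^2/s, never rescaled, with the unit recorded in the NIfTI description
#' field. Masks round-trip as 0/1 volumes.
#'
#' @param img numeric matrix (or `adc_map`, whose values are written).
#' @param path output file (`.nii` or `.nii.gz`).
#' @param units free-text units tag stored in the header description.
#' @return `write_nifti_image()` returns `path` invisibly;
#'   `read_nifti_image()` returns a numeric matrix.
#' @export
write_nifti_image <- function(img, path, units = "mm^2/s") {
  if (inherits(img, "adc_map")) img <- img$values
  nim <- RNifti::asNifti(img)
  nim$descrip <- units
  RNifti::writeNifti(nim, path)
  invisible(path)
}

#' @rdname write_nifti_image
#' @export
read_nifti_image <- function(path) {
  img <- RNifti::readNifti(path)
  matrix(as.numeric(img), dim(img)[1], dim(img)[2])
}

# CRC-32 (PNG chunk checksum), table-driven.
crc32_table <- local({
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) {
        bitwXor(-306674912L, bitwShiftR(c, 1L)) # 0xEDB88320
      } else {
        bitwShiftR(c, 1L)
      }
    }
    tab[n + 1] <- c
  }
  tab
})

crc32 <- function(bytes) {
  c <- -1L
  for (b in as.integer(bytes)) {
    c <- bitwXor(crc32_table[bitwAnd(bitwXor(c, b), 255L) + 1L],
                 bitwShiftR(c, 8L))
  }
  bitwXor(c, -1L)
}

int_be <- function(x) {
  # 32-bit big-endian byte representation (x may exceed .Machine$integer.max
  # range as a double; handled with modular arithmetic)
  x <- as.numeric(x) %% 4294967296
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256,
           x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(int_be(length(data)), body, int_be(crc32(body)))
}

#' Read and write 16-bit PNG images and binary masks
#'
#' `write_png_image()` stores an integer-valued image (0..65535) as 16-bit
#' greyscale PNG (an encoder is built in because the available PNG bindings
#' only write 8-bit); `read_png_image()` reads it back losslessly through
#' `png::readPNG`. `write_png_mask()`/`read_png_mask()` round-trip a logical
#' mask as an 8-bit 0/1 PNG.
#'
#' @param img integer-valued matrix in 0..65535.
#' @param mask logical matrix.
#' @param path file path.
#' @return readers return a matrix (integer image or logical mask).
#' @export
write_png_image <- function(img, path) {
  if (any(img < 0 | img > 65535)) abort("16-bit PNG range is 0..65535")
  img <- round(img)
  nr <- nrow(img); nc <- ncol(img)
  # scanlines: filter byte 0 + big-endian 16-bit samples, row-major
  rows <- t(img)
  scan <- vapply(seq_len(nr), function(r) {
    v <- rows[, r]
    bytes <- as.raw(rbind(v %/% 256, v %% 256))
    c(as.raw(0), bytes)
  }, raw(1 + 2 * nc))
  ihdr <- c(int_be(nc), int_be(nr),
            as.raw(c(16, 0, 0, 0, 0))) # depth 16, greyscale
  stream <- c(
    as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
    png_chunk("IHDR", ihdr),
    png_chunk("IDAT", memCompress(as.vector(scan), "gzip")),
    png_chunk("IEND", raw(0)))
  writeBin(stream, path)
  invisible(path)
}

#' @rdname write_png_image
#' @export
read_png_image <- function(path) {
  round(png::readPNG(path) * 65535)
}

#' @rdname write_png_image
#' @export
write_png_mask <- function(mask, path) {
  png::writePNG(mask * 1.0, target = path)
  invisible(path)
}

#' @rdname write_png_image
#' @export
read_png_mask <- function(path) {
  png::readPNG(path) > 0.5
}

#' Read and write feature tables as CSV
#'
#' The canonical tabular interchange format of the pipeline: one row per
#' slice ROI, identifier/label columns plus the 16 named feature columns
#' (see [glioma_feature_names()]). Values round-trip at full double
#' precision.
#'
#' @param features feature tibble.
#' @param path CSV file path.
#' @return `read_features_csv()` returns a tibble.
#' @export
write_features_csv <- function(features, path) {
  out <- features |>
    mutate(across(where(is.double), ~ sprintf("%.17g", .x)))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  # columns come back as text and are converted through R's own
  # correctly-rounded numeric parser, so doubles round-trip exactly
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           .default = readr::col_character()))
  raw |> mutate(across(everything(),
                       ~ utils::type.convert(.x, as.is = TRUE)))
}

#' Serialize a cohort configuration to JSON (and back)
#'
#' @param config a [cohort_config()].
#' @param path JSON file path.
#' @return `read_cohort_config()` returns a validated [cohort_config()].
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  out <- unclass(config)
  # named vectors serialize as JSON objects so class names survive
  for (nm in c("slices_per_class", "class_adc_mean", "class_adc_sd",
               "class_corr_length")) {
    out[[nm]] <- as.list(out[[nm]])
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("slices_per_class", "class_adc_mean", "class_adc_sd",
               "class_corr_length")) {
    raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(cohort_config, raw)
}

#' Write a synthetic cohort to disk
#'
#' Emits, per slice ROI: the b = 0 and diffusion-weighted images, the
#' ground-truth ADC field and the ROI mask (NIfTI by default, 16-bit PNG
#' with masks as binary PNG on request), plus a `demographics.csv`
#' (slice_id, subject_id, age, gender, who_class) and the generating
#' configuration as JSON.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param format `"nifti"` (default) or `"png"`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("nifti", "png")) {
  format <- match.arg(format)
  stopifnot(inherits(cohort, "glioma_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sl <- cohort$slices
  for (i in seq_len(nrow(sl))) {
    id <- sl$slice_id[i]
    dwi <- sl$dwi[[i]]
    if (format == "nifti") {
      write_nifti_image(dwi$s0, file.path(dir, paste0(id, "_b0.nii.gz")),
                        units = "signal")
      for (j in seq_along(dwi$b)) {
        write_nifti_image(dwi$sb[[j]],
                          file.path(dir, sprintf("%s_b%d.nii.gz", id,
                                                 round(dwi$b[j]))),
                          units = "signal")
      }
      write_nifti_image(sl$adc_true[[i]],
                        file.path(dir, paste0(id, "_adc.nii.gz")))
      write_nifti_image(sl$roi[[i]] * 1.0,
                        file.path(dir, paste0(id, "_mask.nii.gz")),
                        units = "binary")
    } else {
      to16 <- function(img) pmax(0, pmin(65535, round(img * 32)))
      write_png_image(to16(dwi$s0), file.path(dir, paste0(id, "_b0.png")))
      for (j in seq_along(dwi$b)) {
        write_png_image(to16(dwi$sb[[j]]),
                        file.path(dir, sprintf("%s_b%d.png", id,
                                               round(dwi$b[j]))))
      }
      write_png_mask(sl$roi[[i]], file.path(dir, paste0(id, "_mask.png")))
    }
  }
  readr::write_csv(
    sl |> select("slice_id", "subject_id", "age", "gender", "who_class"),
    file.path(dir, "demographics.csv"))
  write_cohort_config(cohort$config, file.path(dir, "cohort_config.json"))
  invisible(dir)
}

#' Serialize a model report to JSON
#'
#' @param report a [evaluate_model()] result.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_model_report <- function(report, path) {
  stopifnot(inherits(report, "model_report"))
  out <- list(
    accuracy_pct = report$accuracy_pct,
    error_pct = report$error_pct,
    confusion = as.data.frame.matrix(report$confusion),
    class_metrics = report$class_metrics,
    ovr_auc = report$ovr_auc)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
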