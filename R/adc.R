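# ADC parametric maps from DWI pairs, and grey-level quantization of ROI
# values for co-occurrence analysis.

#' Compute an ADC parametric map from a DWI slice pair
#'
#' Per pixel, the apparent diffusion coefficient is estimated from the signal
#' attenuation between the b = 0 image and each diffusion-weighted image:
#' \deqn{ADC = \frac{1}{n}\sum_{i=1}^{n} \frac{-\ln(S_i/S_0)}{b_i}}
#' i.e. the per-b estimates are averaged, so the result stays in mm^2/s for
#' any number of b-values. The sign convention makes ADC positive for
#' attenuating signal (high diffusivity = high ADC). Pixels where `S_0 <= 0`
#' or any `S_i <= 0` cannot be log-transformed; they are set to 0 and flagged
#' invalid.
#'
#' @param pair a [dwi_pair()].
#' @return object of class `adc_map`: list with `values` (matrix, mm^2/s)
#'   and `valid` (logical matrix).
#' @examples
#' s0 <- matrix(1000, 4, 4)
#' sb <- matrix(1000 * exp(-1), 4, 4)
#' m <- compute_adc_map(dwi_pair(s0, sb, b = 1000))
#' m$values[1, 1] # ~1e-3 mm^2/s
#' @export
compute_adc_map <- function(pair) {
  stopifnot(inherits(pair, "dwi_pair"))
  valid <- pair$s0 > 0
  acc <- matrix(0, nrow(pair$s0), ncol(pair$s0))
  for (i in seq_along(pair$b)) {
    si <- pair$sb[[i]]
    valid <- valid & (si > 0)
    ratio <- si / pair$s0
    ratio[!valid | ratio <= 0] <- 1 # placeholder; masked below
    acc <- acc - log(ratio) / pair$b[i]
  }
  values <- acc / length(pair$b)
  values[!valid] <- 0
  structure(list(values = values, valid = valid), class = "adc_map")
}

# Accept either an adc_map or a bare matrix wherever a map is expected.
as_adc_map <- function(adc) {
  if (inherits(adc, "adc_map")) return(adc)
  if (is.matrix(adc)) {
    return(structure(list(values = adc, valid = is.finite(adc)),
                     class = "adc_map"))
  }
  abort("expected an adc_map or a matrix")
}

#' Quantize ROI ADC values to grey levels
#'
#' Linear min-max binning of the valid in-ROI ADC values into `n_levels`
#' equal-width bins: level `floor((x - min) / width)` with
#' `width = (max - min) / n_levels`; the ROI maximum maps to level
#' `n_levels - 1`, and a constant ROI maps entirely to level 0. Because the
#' binning is per-ROI min-max, the levels (and hence all GLCM features) are
#' invariant to any monotone affine rescaling of the ADC values.
#'
#' @param adc an `adc_map` or matrix.
#' @param roi logical mask matrix, same shape.
#' @param n_levels number of grey levels (>= 2, default 64).
#' @return object of class `quantized_roi`: list with `levels` (integer
#'   matrix, `NA` outside the valid ROI), `n_levels`, `quantization_range`,
#'   `n_valid`.
#' @export
quantize_roi <- function(adc, roi, n_levels = 64L) {
  adc <- as_adc_map(adc)
  n_levels <- as.integer(n_levels)
  if (n_levels < 2) abort("n_levels must be >= 2")
  if (!identical(dim(roi), dim(adc$values))) abort("roi shape mismatch")
  sel <- roi & adc$valid
  if (!any(sel)) abort("ROI is empty after excluding invalid pixels")
  x <- adc$values[sel]
  rng <- range(x)
  lev <- matrix(NA_integer_, nrow(roi), ncol(roi))
  if (rng[1] == rng[2]) {
    lev[sel] <- 0L
  } else {
    width <- (rng[2] - rng[1]) / n_levels
    q <- pmin(floor((x - rng[1]) / width), n_levels - 1L)
    lev[sel] <- as.integer(q)
  }
  structure(list(levels = lev, n_levels = n_levels,
                 quantization_range = rng, n_valid = sum(sel)),
            class = "quantized_roi")
}
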