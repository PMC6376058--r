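#' Compute an ADC map from two diffusion weightings
#'
#' The apparent diffusion coefficient is computed voxelwise as the linear
#' slope of log-signal decrease between the low and high b-value
#' acquisitions: `ADC = ln(S_low / S_high) / (b_high - b_low)`, in mm^2/s.
#' Pixels where either signal is non-positive are flagged missing (`NA`);
#' negative ADC values (signal increase) are preserved, not clipped.
#'
#' For feature extraction the package carries ADC maps rescaled by
#' `scale` (default 1e6, i.e. units of 1e-6 mm^2/s) so that tissue-range
#' values (~0.5e-3 to 2e-3 mm^2/s) span a usable number of grey-level bins
#' under the absolute bin width of 20. Set `scale = 1` to obtain plain
#' mm^2/s. The scale is recorded in the result's provenance attribute.
#'
#' @param b_low_img,b_high_img `seq_image`-like objects (or plain matrices)
#'   holding the signal at the low and high b-value, on congruent grids.
#' @param b_low,b_high b-values in s/mm^2, `b_high > b_low`.
#' @param scale multiplicative rescaling applied to the returned map.
#' @param spacing_mm pixel spacing, required when the inputs are plain
#'   matrices (taken from `b_low_img` otherwise).
#' @param patient_id,side carried through to the result.
#' @return A [seq_image()] with `sequence_label = "ADC"`.
#' @export
#' @examples
#' b0 <- matrix(1000, 4, 4)
#' b1000 <- b0 * exp(-1)
#' adc <- compute_adc(b0, b1000, spacing_mm = c(1, 1), scale = 1)
#' adc$pixels[1, 1]  # 1e-3 mm^2/s
compute_adc <- function(b_low_img, b_high_img, b_low = 0, b_high = 1000,
                        scale = 1e6, spacing_mm = NULL,
                        patient_id = NA_character_, side = NA_character_) {
  get_px <- function(x) if (inherits(x, "seq_image")) x$pixels else as.matrix(x)
  s_low <- get_px(b_low_img)
  s_high <- get_px(b_high_img)
  if (!identical(dim(s_low), dim(s_high))) {
    abort("compute_adc: grid mismatch between b-value images")
  }
  if (b_high <= b_low) abort("compute_adc: b_high must exceed b_low")
  if (is.null(spacing_mm)) {
    if (!inherits(b_low_img, "seq_image")) {
      abort("compute_adc: spacing_mm required for plain-matrix input")
    }
    spacing_mm <- b_low_img$spacing_mm
    if (is.na(patient_id)) patient_id <- b_low_img$patient_id
    if (is.na(side)) side <- b_low_img$side
  }
  adc <- matrix(NA_real_, nrow(s_low), ncol(s_low))
  ok <- s_low > 0 & s_high > 0
  adc[ok] <- log(s_low[ok] / s_high[ok]) / (b_high - b_low) * scale
  out <- seq_image(ifelse(is.na(adc), 0, adc), spacing_mm, "ADC",
                   patient_id = patient_id, side = side)
  out$pixels[!ok] <- NA_real_
  attr(out, "provenance") <- list(b_low = b_low, b_high = b_high,
                                  adc_scale = scale)
  out
}

#' Absolute grey-level discretization with a fixed bin width
#'
#' Maps non-negative intensities to integer grey levels with a constant bin
#' width anchored at zero: values in `[0, w)` become level 1, `[w, 2w)`
#' level 2, and so on (`level = floor(x / w) + 1`). This is fixed-bin-size
#' absolute discretization; the number of levels is the maximum occupied
#' level in the ROI, with no global cap.
#'
#' @param roi_values numeric vector of ROI pixel intensities (>= 0).
#' @param bin_width bin width in signal units (> 0). Default 20.
#' @return A list of class `discretized_roi` with elements `levels`
#'   (integer vector), `n_levels`, `bin_width` and `raw_values`.
#' @export
#' @examples
#' discretize(c(0, 19.9, 20, 45))$levels  # 1 1 2 3
discretize <- function(roi_values, bin_width = 20) {
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0) {
    abort("discretize: bin_width must be a single value > 0")
  }
  x <- as.numeric(roi_values)
  if (anyNA(x)) abort("discretize: missing intensities in ROI")
  if (any(x < 0)) {
    abort(paste("discretize: negative intensities found; absolute",
                "discretization is anchored at 0 - shift or rescale the",
                "image to non-negative values first"))
  }
  lev <- as.integer(floor(x / bin_width)) + 1L
  structure(list(levels = lev, n_levels = max(lev),
                 bin_width = bin_width, raw_values = x),
            class = "discretized_roi")
}
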