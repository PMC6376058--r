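#' First-order intensity statistics of a ROI
#'
#' Computes the 15 first-order features from the raw ROI intensities plus
#' the discretized grey levels. `Entropy` and `Uniformity` are computed on
#' the discretized-level histogram; all other statistics use raw values.
#' `STD`, `Skewness` and `Kurtosis` use population moments (divisor `N`;
#' kurtosis is not excess-corrected). `Inter1090` is the difference between
#' the 90th and 10th percentiles. A single-pixel ROI yields `NA` skewness
#' and kurtosis.
#'
#' @param roi_values numeric vector of raw ROI intensities (length >= 1).
#' @param discretized the matching [discretize()] result.
#' @return Named numeric vector of the 15 `fo_*` features.
#' @export
compute_first_order <- function(roi_values, discretized) {
  x <- as.numeric(roi_values)
  n <- length(x)
  if (n == 0L) abort("compute_first_order: empty ROI")
  if (anyNA(x)) abort("compute_first_order: missing intensities in ROI")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  skew <- if (n > 1L && m2 > 0) mean((x - m)^3) / m2^1.5 else NA_real_
  kurt <- if (n > 1L && m2 > 0) mean((x - m)^4) / m2^2 else NA_real_
  if (n == 1L) skew <- kurt <- NA_real_
  # constant multi-pixel ROI: distribution is degenerate, flag moments
  q <- quantile(x, c(0.1, 0.9), names = FALSE, type = 7)
  pr <- tabulate(discretized$levels, discretized$n_levels) / n
  pr <- pr[pr > 0]
  out <- c(
    sum(x^2),                       # energy
    -sum(pr * log2(pr)),            # entropy (discretized histogram)
    q[2] - q[1],                    # inter1090
    kurt,
    max(x),
    m,
    mean(abs(x - m)),               # mean absolute deviation
    median(x),
    min(x),
    n,                              # npix
    max(x) - min(x),
    sqrt(mean(x^2)),                # rms
    skew,
    sqrt(m2),                       # population std
    sum(pr^2)                       # uniformity
  )
  names(out) <- .fo_names()
  out
}
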