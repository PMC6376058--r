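#' Extract all 85 radiomics features for one ROI
#'
#' Runs the full per-ROI extraction: shape features from the mask and
#' spacing, absolute grey-level discretization of the ROI intensities, then
#' first-order, GLCM, GLSZM, GLRLM and NGTDM features. Degenerate
#' computations (single-pixel ROI, flat matrices) propagate as `NA` values,
#' never as dropped columns, so the result always has exactly 85 entries in
#' the frozen schema order.
#'
#' @param image a [seq_image()].
#' @param delin a [delineation()] on the same grid.
#' @param config a [run_config()] (only `bin_width` is used here).
#' @return Named numeric vector of length 85 with attribute `provenance`
#'   (bin width, directions, connectivity).
#' @export
#' @examples
#' img <- seq_image(matrix(runif(64, 0, 100), 8, 8), c(1, 1), "T1")
#' m <- matrix(FALSE, 8, 8); m[3:6, 3:6] <- TRUE
#' fv <- extract_all(img, delineation(m, "L1"), run_config())
#' length(fv)  # 85
extract_all <- function(image, delin, config = run_config()) {
  stopifnot(inherits(image, "seq_image"), inherits(delin, "delineation"))
  .check_congruent(image, delin)
  mask <- delin$mask
  vals <- image$pixels[mask]
  if (anyNA(vals)) {
    abort("extract_all: missing pixel values inside the ROI")
  }
  # crop to the mask bounding box: texture matrices and geodesic paths
  # only depend on the ROI neighbourhood
  bb <- mask_bbox(mask, margin = 1L)
  cmask <- mask[bb$r1:bb$r2, bb$c1:bb$c2, drop = FALSE]

  shp <- compute_shape(cmask, image$spacing_mm)
  disc <- discretize(image$pixels[bb$r1:bb$r2, bb$c1:bb$c2][cmask],
                     config$bin_width)
  fo <- compute_first_order(disc$raw_values, disc)
  glcm <- glcm_features(build_glcm(disc, cmask))
  glszm <- glszm_features(build_glszm(disc, cmask))
  glrlm <- glrlm_features(build_glrlm(disc, cmask))
  ngtdm <- ngtdm_features(build_ngtdm(disc, cmask))

  out <- c(shp, fo, glcm, glszm, glrlm, ngtdm)
  stopifnot(identical(names(out), feature_schema()$feature))
  attr(out, "provenance") <- list(
    bin_width = config$bin_width, glcm_distance = 1L, directions = 4L,
    zone_connectivity = 8L, merge = "sum-over-directions")
  out
}

#' Extract a long feature table from a synthetic cohort
#'
#' Applies [extract_all()] to every (case, sequence, reading) combination
#' and returns the long feature table: one row per ROI per reading, keyed
#' by `patient_id`, `side`, `sequence`, `reading`, followed by the 85
#' feature columns in schema order.
#'
#' @param cohort a list of cases from [generate_cohort()].
#' @param config a [run_config()].
#' @param readings subset of [reading_labels()] to extract (default all 3).
#' @return A tibble with `4 + 85` columns.
#' @export
extract_features <- function(cohort, config = run_config(),
                             readings = reading_labels()) {
  stopifnot(all(readings %in% reading_labels()))
  rows <- purrr::map(cohort, function(case) {
    purrr::map(names(case$images), function(sq) {
      img <- case$images[[sq]]
      purrr::map(readings, function(rd) {
        dl <- case$delineations[[sq]][[rd]]
        fv <- extract_all(img, dl, config)
        tibble::as_tibble_row(c(
          list(patient_id = case$patient_id, side = case$side,
               sequence = sq, reading = rd),
          as.list(fv)))
      })
    })
  })
  dplyr::bind_rows(purrr::flatten(purrr::flatten(rows)))
}
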