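#' Sequence, reading and feature name schema
#'
#' The extractor computes a fixed set of 85 two-dimensional radiomics
#' features per ROI, organised in six families: 13 shape, 15 first-order,
#' 26 grey-level co-occurrence matrix (GLCM), 13 grey-level size-zone
#' matrix (GLSZM), 13 grey-level run-length matrix (GLRLM) and 5
#' neighbourhood grey-tone difference matrix (NGTDM) features. Column
#' names carry a family prefix so that duplicated short names across
#' families (e.g. GLN, GLV, Contrast) stay unambiguous.
#'
#' @return `feature_schema()` returns a tibble with columns `feature` and
#'   `family` (one row per feature, in the frozen output order).
#'   `sequence_labels()` and `reading_labels()` return character vectors.
#' @export
#' @examples
#' feature_schema()
#' sequence_labels()
feature_schema <- function() {
  tibble::tibble(
    feature = c(.shape_names(), .fo_names(), .glcm_names(),
                .glszm_names(), .glrlm_names(), .ngtdm_names()),
    family = rep(c("shape", "first_order", "glcm", "glszm", "glrlm", "ngtdm"),
                 times = c(13L, 15L, 26L, 13L, 13L, 5L))
  )
}

#' @rdname feature_schema
#' @export
sequence_labels <- function() .sequence_label_set()

.sequence_label_set <- function() {
  c("T1", "ADC", "ipDIXON_T2", "wDIXON_T2", "PC_ipDIXON_T1", "PC_wDIXON_T1")
}

#' @rdname feature_schema
#' @export
reading_labels <- function() c("L1", "L2.1", "L2.2")

# key columns of the long feature table
.key_cols <- function() c("patient_id", "side", "sequence", "reading")

.shape_names <- function() {
  paste0("shape_", c(
    "convex_area", "deficit", "eccentricity", "elongation", "extension",
    "major_axis_length", "max_diameter", "max_geodesic_diameter",
    "minor_axis_length", "perimeter", "perimeter_solidity", "solidity",
    "surface_area"))
}

.fo_names <- function() {
  paste0("fo_", c(
    "energy", "entropy", "inter1090", "kurtosis", "maximum", "mean", "mad",
    "median", "minimum", "npix", "range", "rms", "skewness", "std",
    "uniformity"))
}

.glcm_names <- function() {
  paste0("glcm_", c(
    "agreement", "autocorrelation", "cluster_prominence", "cluster_shade",
    "cluster_tendency", "contrast", "correlation1", "correlation2",
    "difference_entropy", "dissimilarity", "homogeneity1", "homogeneity2",
    "imc1", "imc2", "idm", "idmn", "inverse_variance", "joint_energy",
    "joint_entropy", "maximum_probability", "sum_average", "sum_entropy",
    "sum_mean", "sum_variance", "variance1", "variance2"))
}

.glszm_names <- function() {
  paste0("glszm_", c(
    "gln", "glv", "hglze", "lae", "lahgle", "lalgle", "lglze", "zsn",
    "sae", "sahgle", "salgle", "zp", "zv"))
}

.glrlm_names <- function() {
  paste0("glrlm_", c(
    "glv", "gln", "hglre", "lre", "lrhgle", "lrlgle", "lglre", "rln",
    "rp", "rv", "sre", "srhgle", "srlgle"))
}

.ngtdm_names <- function() {
  paste0("ngtdm_", c("busyness", "coarseness", "complexity", "contrast",
                     "strength"))
}
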