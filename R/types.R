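#' Construct a single-slice MR sequence image
#'
#' A `seq_image` is one 2D grayscale slice of a named MR sequence, with its
#' in-plane pixel spacing in millimetres. Pixel values are in arbitrary
#' signal units except for ADC maps, which this package carries in units of
#' 1e-6 mm^2/s (see [compute_adc()] for the rescaling convention).
#'
#' @param pixels numeric matrix of finite pixel values.
#' @param spacing_mm numeric length-2, strictly positive `(row_mm, col_mm)`.
#' @param sequence_label one of [sequence_labels()].
#' @param patient_id,side identifiers; `side` is `"left"` or `"right"`.
#' @return An object of class `seq_image`.
#' @export
seq_image <- function(pixels, spacing_mm, sequence_label,
                      patient_id = NA_character_, side = NA_character_) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (!all(is.finite(pixels))) abort("seq_image: pixel values must be finite")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 2L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0)) {
    abort("seq_image: spacing_mm must be two strictly positive values")
  }
  sequence_label <- as.character(sequence_label)
  if (!sequence_label %in% sequence_labels()) {
    abort(paste0("seq_image: unknown sequence_label '", sequence_label, "'"))
  }
  if (!is.na(side) && !side %in% c("left", "right")) {
    abort("seq_image: side must be 'left' or 'right'")
  }
  structure(
    list(pixels = pixels, spacing_mm = spacing_mm,
         sequence_label = sequence_label,
         patient_id = as.character(patient_id), side = side),
    class = "seq_image")
}

#' @export
print.seq_image <- function(x, ...) {
  cat(sprintf("<seq_image %s %s/%s %dx%d px @ %.3gx%.3g mm>\n",
              x$sequence_label, x$patient_id, x$side,
              nrow(x$pixels), ncol(x$pixels),
              x$spacing_mm[1], x$spacing_mm[2]))
  invisible(x)
}

#' Construct a delineation (one observer's binary ROI mask)
#'
#' A delineation is a binary mask on the same grid as its image, labelled by
#' reading session: `L1` (reader 1), `L2.1` and `L2.2` (reader 2's two
#' sessions). The mask must contain at least one foreground pixel and form a
#' single 8-connected component.
#'
#' @param mask logical (or 0/1) matrix.
#' @param reading one of [reading_labels()].
#' @return An object of class `delineation`.
#' @export
delineation <- function(mask, reading) {
  mask <- as.matrix(mask)
  if (anyNA(mask)) abort("delineation: mask contains missing values")
  mask <- mask != 0
  if (!any(mask)) abort("delineation: mask is empty")
  reading <- as.character(reading)
  if (!reading %in% reading_labels()) {
    abort(paste0("delineation: unknown reading '", reading, "'"))
  }
  if (mask_n_components(mask) != 1L) {
    abort("delineation: mask has multiple components (must be one 8-connected component)")
  }
  structure(list(mask = mask, reading = reading), class = "delineation")
}

#' @export
print.delineation <- function(x, ...) {
  cat(sprintf("<delineation %s, %d px on %dx%d grid>\n",
              x$reading, sum(x$mask), nrow(x$mask), ncol(x$mask)))
  invisible(x)
}

.check_congruent <- function(image, delin) {
  if (!identical(dim(image$pixels), dim(delin$mask))) {
    abort(sprintf("grid mismatch: image is %dx%d but mask is %dx%d",
                  nrow(image$pixels), ncol(image$pixels),
                  nrow(delin$mask), ncol(delin$mask)))
  }
  invisible(TRUE)
}

#' Run configuration
#'
#' Bundles the analysis parameters: grey-level bin width for absolute
#' discretization, the ICC and CCC reproducibility thresholds, the Spearman
#' redundancy cutoff, the diffusion b-values used for ADC computation, the
#' RNG seed, and the synthetic cohort parameters.
#'
#' @param bin_width grey-level bin width in signal units (> 0). Default 20.
#' @param icc_threshold minimum intraclass correlation for a feature to
#'   count as reproducible, in `[0, 1]`. Default 0.8.
#' @param ccc_threshold minimum Lin's concordance correlation, in `[0, 1]`.
#'   Default 0.9.
#' @param spearman_cutoff Spearman correlation above which two features are
#'   considered redundant, in `(0, 1)`. Default 0.9.
#' @param b_values diffusion weightings (s/mm^2) for ADC computation.
#' @param rng_seed integer seed driving all simulation randomness.
#' @param cohort a [cohort_spec()] describing the synthetic cohort.
#' @return An object of class `run_config`.
#' @export
run_config <- function(bin_width = 20,
                       icc_threshold = 0.8,
                       ccc_threshold = 0.9,
                       spearman_cutoff = 0.9,
                       b_values = c(0, 1000),
                       rng_seed = 1L,
                       cohort = cohort_spec(rng_seed = rng_seed)) {
  if (!is.numeric(bin_width) || bin_width <= 0) {
    abort("run_config: bin_width must be > 0")
  }
  for (nm in c("icc_threshold", "ccc_threshold")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || v > 1) {
      abort(paste0("run_config: ", nm, " must be in [0, 1]"))
    }
  }
  if (spearman_cutoff <= 0 || spearman_cutoff >= 1) {
    abort("run_config: spearman_cutoff must be in (0, 1)")
  }
  if (length(b_values) != 2L || b_values[2] <= b_values[1]) {
    abort("run_config: b_values must be two increasing values")
  }
  structure(
    list(bin_width = bin_width, icc_threshold = icc_threshold,
         ccc_threshold = ccc_threshold, spearman_cutoff = spearman_cutoff,
         b_values = as.numeric(b_values), rng_seed = as.integer(rng_seed),
         cohort = cohort),
    class = "run_config")
}

#' Read and write a run configuration as JSON
#'
#' @param config a [run_config()].
#' @param path file path.
#' @return `read_run_config()` returns a [run_config()]; `write_run_config()`
#'   returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$cohort <- unclass(x$cohort)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ch <- x$cohort
  cohort <- do.call(cohort_spec, ch[names(ch) %in% names(formals(cohort_spec))])
  run_config(bin_width = x$bin_width, icc_threshold = x$icc_threshold,
             ccc_threshold = x$ccc_threshold,
             spearman_cutoff = x$spearman_cutoff,
             b_values = x$b_values, rng_seed = x$rng_seed, cohort = cohort)
}
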