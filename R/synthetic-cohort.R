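#' Specify a synthetic multi-sequence cohort
#'
#' Describes a simulated study: `n_patients` patients, two lacrimal glands
#' each, imaged on six MR sequences, each gland delineated three times
#' (reading `L1` by reader 1; `L2.1` and `L2.2` by reader 2). Glands are
#' ellipse-based regions filled with a spatially correlated Gaussian random
#' field texture, mapped through a per-sequence monotone affine contrast
#' transform with additive Gaussian noise. The diffusion pair (b0, b1000)
#' is synthesised from a known per-pixel ADC field so that [compute_adc()]
#' inverts the generator exactly in the noise-free case.
#'
#' Reader variability is a smooth random radial boundary deformation:
#' reader 1 and reader 2 each perturb the ground truth with magnitude
#' `inter_reader_perturb`; reader 2's two sessions add independent
#' deformations of magnitude `intra_reader_perturb` on top of reader 2's
#' shared offset, reproducing the intra < inter variability hierarchy.
#' Delineations are shared within each DIXON in-phase/water pair (same
#' acquisition geometry) and independent across T1, the diffusion
#' acquisition, the T2 DIXON pair and the post-contrast T1 DIXON pair.
#'
#' @param n_patients number of patients (default 37).
#' @param glands_per_patient glands per patient (default 2).
#' @param sequence_labels the sequences to simulate.
#' @param image_size `(rows, cols)` in pixels.
#' @param spacing_mm pixel spacing `(row_mm, col_mm)`.
#' @param semi_axes_mode list with `major` and `minor` ranges (pixels) for
#'   the ellipse semi-axes.
#' @param contrast named list per non-diffusion sequence of
#'   `offset`, `gain`, `noise_sd` (arbitrary signal units).
#' @param dwi list with `b0_offset`, `b0_gain`, `noise_frac` (relative
#'   multiplicative noise on both diffusion signals), `adc_mid`,
#'   `adc_amp` (mm^2/s; the ADC field is `adc_mid + adc_amp * tanh(field)`).
#' @param shape_irregularity magnitude (pixels) of the subject-specific
#'   smooth boundary deformation applied to the ellipse, giving glands
#'   realistic between-subject shape variation (lobulation); 0 yields
#'   exact ellipses.
#' @param texture_corr_len Gaussian-field correlation length (pixels).
#' @param texture_share fraction (on the variance scale) of each
#'   sequence's texture shared with the case's common anatomy field.
#' @param inter_reader_perturb,intra_reader_perturb residual boundary
#'   deformation magnitudes in pixels; intra must not exceed inter.
#' @param inter_reader_shift,intra_reader_shift standard deviation (pixels)
#'   of the reader's contour placement offset, applied as an integer
#'   in-plane translation of the delineation. A translation changes which
#'   pixels are sampled (so intensity and texture statistics change) while
#'   leaving the mask's own geometry exactly unchanged - the dominant
#'   reader effect when each reader picks a slightly different slice or
#'   centres the contour differently.
#' @param rng_seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 37L,
                        glands_per_patient = 2L,
                        sequence_labels = .sequence_label_set(),
                        image_size = c(96L, 96L),
                        spacing_mm = c(0.5, 0.5),
                        semi_axes_mode = list(major = c(9, 20),
                                              minor = c(6, 13)),
                        contrast = NULL,
                        dwi = NULL,
                        shape_irregularity = 3.5,
                        texture_corr_len = 3,
                        texture_share = 0.5,
                        inter_reader_perturb = 1.5,
                        intra_reader_perturb = 0.5,
                        inter_reader_shift = 2,
                        intra_reader_shift = 0.5,
                        rng_seed = 1L) {
  if (n_patients < 1L) abort("cohort_spec: n_patients must be >= 1")
  if (intra_reader_perturb > inter_reader_perturb) {
    abort("cohort_spec: intra_reader_perturb must not exceed inter_reader_perturb")
  }
  if (intra_reader_shift > inter_reader_shift) {
    abort("cohort_spec: intra_reader_shift must not exceed inter_reader_shift")
  }
  if (!all(sequence_labels %in% .sequence_label_set())) {
    abort("cohort_spec: unknown sequence label")
  }
  default_contrast <- list(
    T1            = list(offset = 400, gain = 90,  noise_sd = 25),
    ipDIXON_T2    = list(offset = 500, gain = 120, noise_sd = 20),
    wDIXON_T2     = list(offset = 450, gain = 140, noise_sd = 20),
    PC_ipDIXON_T1 = list(offset = 550, gain = 110, noise_sd = 20),
    PC_wDIXON_T1  = list(offset = 600, gain = 130, noise_sd = 20))
  if (is.null(contrast)) contrast <- default_contrast
  contrast <- lapply(contrast, as.list)
  default_dwi <- list(b0_offset = 800, b0_gain = 120, noise_frac = 0.01,
                      adc_mid = 1.25e-3, adc_amp = 0.5e-3)
  if (is.null(dwi)) dwi <- default_dwi
  dwi <- as.list(dwi)
  # ellipse + truth irregularity + reader perturbation must fit the image
  margin <- max(inter_reader_perturb, intra_reader_perturb) * 3 +
    max(inter_reader_shift, intra_reader_shift) * 3 +
    shape_irregularity * 3 + 3
  if (2 * (max(semi_axes_mode$major) + margin) > min(image_size)) {
    abort("cohort_spec: ellipse (plus perturbation margin) does not fit inside the image")
  }
  structure(
    list(n_patients = as.integer(n_patients),
         glands_per_patient = as.integer(glands_per_patient),
         sequence_labels = sequence_labels,
         image_size = as.integer(image_size), spacing_mm = spacing_mm,
         semi_axes_mode = semi_axes_mode, contrast = contrast, dwi = dwi,
         shape_irregularity = shape_irregularity,
         texture_corr_len = texture_corr_len, texture_share = texture_share,
         inter_reader_perturb = inter_reader_perturb,
         intra_reader_perturb = intra_reader_perturb,
         inter_reader_shift = inter_reader_shift,
         intra_reader_shift = intra_reader_shift,
         rng_seed = as.integer(rng_seed)),
    class = "cohort_spec")
}

# Stationary Gaussian random field: white noise smoothed with a Gaussian
# kernel of the given correlation length (circular FFT convolution),
# standardized to zero mean / unit sd.
gaussian_field <- function(nr, nc, corr_len) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  if (corr_len <= 0) return(z)
  # circularly wrapped Gaussian kernel
  dr <- pmin(0:(nr - 1L), nr - 0:(nr - 1L))
  dc <- pmin(0:(nc - 1L), nc - 0:(nc - 1L))
  k <- exp(-outer(dr^2, dc^2, "+") / (2 * corr_len^2))
  sm <- Re(fft(fft(z) * fft(k / sum(k)), inverse = TRUE)) / (nr * nc)
  (sm - mean(sm)) / sd(sm)
}

# random ellipse mask fitting the image with the given margin
.ellipse_mask <- function(image_size, axes_mode, margin) {
  nr <- image_size[1]; nc <- image_size[2]
  a <- runif(1, axes_mode$major[1], axes_mode$major[2])
  b <- runif(1, axes_mode$minor[1], axes_mode$minor[2])
  theta <- runif(1, 0, pi)
  rmax <- max(a, b) + margin
  if (2 * rmax >= min(nr, nc)) abort("ellipse out of bounds for this image size")
  cr <- runif(1, 1 + rmax, nr - rmax)
  cc <- runif(1, 1 + rmax, nc - rmax)
  r <- matrix(seq_len(nr), nr, nc)
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  u <- (r - cr) * cos(theta) + (c - cc) * sin(theta)
  v <- -(r - cr) * sin(theta) + (c - cc) * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Perturb a mask with a smooth random boundary deformation
#'
#' Applies a random smooth radial deformation to the mask boundary: the
#' signed Euclidean distance to the boundary is thresholded against a
#' random low-order Fourier series in the polar angle around the mask
#' centroid, with standard deviation `magnitude` (pixels). The result is
#' reduced to its largest 8-connected component. `magnitude = 0` returns
#' the input unchanged. If the deformation would empty the mask the call
#' retries with the magnitude halved, and errors after `max_retries`.
#'
#' The harmonic content controls the character of the deformation: low
#' harmonics (e.g. `1:2`) give the smooth global boundary misplacement
#' typical of human readers, higher harmonics (e.g. `2:6`) give the
#' lobulated irregularity of anatomy.
#'
#' @param mask logical matrix, single 8-connected component.
#' @param magnitude deformation standard deviation in pixels (>= 0).
#' @param harmonics integer vector of Fourier harmonics in the angular
#'   profile; harmonic 0 is a uniform in/out bias (over- or
#'   under-segmentation).
#' @param weights relative variance weights per harmonic (default: equal);
#'   normalized so the profile's standard deviation is `magnitude`.
#' @param max_retries bounded retries with damped magnitude.
#' @return A logical matrix of the same shape.
#' @export
perturb_mask <- function(mask, magnitude, harmonics = 1:3,
                         weights = c(0.8, 0.12, 0.08)[seq_along(harmonics)],
                         max_retries = 5L) {
  mask <- as.matrix(mask) != 0
  if (magnitude < 0) abort("perturb_mask: magnitude must be >= 0")
  if (!any(mask)) abort("perturb_mask: empty mask")
  if (magnitude == 0) return(mask)
  mag <- magnitude
  for (try in seq_len(max_retries)) {
    out <- .perturb_once(mask, mag, harmonics, weights)
    if (!is.null(out)) return(out)
    mag <- mag / 2
  }
  abort("perturb_mask: deformation emptied the mask despite damped retries")
}

.perturb_once <- function(mask, magnitude, harmonics, weights) {
  bb <- mask_bbox(mask, margin = as.integer(ceiling(4 * magnitude + 3)))
  sub <- mask[bb$r1:bb$r2, bb$c1:bb$c2, drop = FALSE]
  D <- mask_signed_distance(sub)
  ctr <- colMeans(which(sub, arr.ind = TRUE))
  r <- matrix(seq_len(nrow(sub)), nrow(sub), ncol(sub))
  c <- matrix(seq_len(ncol(sub)), nrow(sub), ncol(sub), byrow = TRUE)
  theta <- atan2(r - ctr[1], c - ctr[2])
  K <- length(harmonics)
  # variance of (a cos + b sin) averaged over theta is a^2/2 + b^2/2 for
  # k >= 1 and a^2 for k = 0; allocate so that sd(f) == magnitude
  w <- weights / sum(weights)
  f <- matrix(0, nrow(sub), ncol(sub))
  for (k in seq_len(K)) {
    h <- harmonics[k]
    if (h == 0L) {
      f <- f + rnorm(1, 0, magnitude * sqrt(w[k]))
    } else {
      s_k <- magnitude * sqrt(w[k])
      f <- f + rnorm(1, 0, s_k) * cos(h * theta) +
        rnorm(1, 0, s_k) * sin(h * theta)
    }
  }
  newsub <- D > f
  if (!any(newsub)) return(NULL)
  newsub <- mask_largest_component(newsub)
  out <- mask
  out[bb$r1:bb$r2, bb$c1:bb$c2] <- newsub
  out
}

#' Generate a synthetic cohort
#'
#' Deterministically (given `rng_seed`) simulates every case of the design
#' described by a [cohort_spec()]: per gland, a ground-truth ellipse mask,
#' a common anatomy texture field, per-sequence images through each
#' contrast transform (the ADC map is computed from synthesised b0/b1000
#' diffusion images via [compute_adc()]), and three delineations per
#' sequence image.
#'
#' @param spec a [cohort_spec()].
#' @return A list of cases; each case is a list with `patient_id`, `side`,
#'   `images` (named list of [seq_image()]), `delineations` (per sequence,
#'   a named list of three [delineation()]s), `truth_mask`, `adc_truth`
#'   (mm^2/s), `dwi` (the b0/b1000 matrices) and `provenance`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$rng_seed)
  sides <- c("left", "right")[seq_len(spec$glands_per_patient)]
  cases <- list()
  for (p in seq_len(spec$n_patients)) {
    pid <- sprintf("P%03d", p)
    for (s in sides) {
      cases[[length(cases) + 1L]] <- .generate_case(spec, pid, s)
    }
  }
  cases
}

.generate_case <- function(spec, patient_id, side) {
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  margin <- max(spec$inter_reader_perturb, spec$intra_reader_perturb) * 3 +
    max(spec$inter_reader_shift, spec$intra_reader_shift) * 3 +
    spec$shape_irregularity * 3 + 2
  truth <- .ellipse_mask(spec$image_size, spec$semi_axes_mode, margin)
  if (spec$shape_irregularity > 0) {
    truth <- perturb_mask(truth, spec$shape_irregularity,
                          harmonics = 2:6, weights = rep(1, 5))
  }
  anat <- gaussian_field(nr, nc, spec$texture_corr_len)
  w <- spec$texture_share

  seq_field <- function() {
    e <- gaussian_field(nr, nc, spec$texture_corr_len)
    sqrt(w) * anat + sqrt(1 - w) * e
  }

  images <- list()
  dwi_store <- NULL
  adc_truth <- NULL
  for (sq in spec$sequence_labels) {
    if (sq == "ADC") {
      fld <- seq_field()
      adc_truth <- spec$dwi$adc_mid + spec$dwi$adc_amp * tanh(fld)
      b0 <- spec$dwi$b0_offset + spec$dwi$b0_gain * seq_field()
      b0 <- pmax(b0, 1)
      b1000 <- b0 * exp(-1000 * adc_truth)
      if (spec$dwi$noise_frac > 0) {
        b0 <- b0 * (1 + rnorm(nr * nc, 0, spec$dwi$noise_frac))
        b1000 <- b1000 * (1 + rnorm(nr * nc, 0, spec$dwi$noise_frac))
        b0 <- pmax(b0, 1e-6); b1000 <- pmax(b1000, 1e-6)
      }
      dwi_store <- list(b0 = b0, b1000 = b1000)
      img <- compute_adc(b0, b1000, b_low = 0, b_high = 1000,
                         spacing_mm = spec$spacing_mm,
                         patient_id = patient_id, side = side)
    } else {
      cm <- spec$contrast[[sq]]
      px <- cm$offset + cm$gain * seq_field()
      if (cm$noise_sd > 0) px <- px + rnorm(nr * nc, 0, cm$noise_sd)
      px <- pmax(px, 0)  # magnitude images are non-negative
      img <- seq_image(matrix(px, nr, nc), spec$spacing_mm, sq,
                       patient_id = patient_id, side = side)
    }
    images[[sq]] <- img
  }

  # delineation groups sharing geometry (DIXON pairs share an acquisition)
  groups <- list(T1 = "T1", DWI = "ADC",
                 T2 = c("ipDIXON_T2", "wDIXON_T2"),
                 PCT1 = c("PC_ipDIXON_T1", "PC_wDIXON_T1"))
  groups <- Filter(length, lapply(groups, intersect, spec$sequence_labels))
  delins <- setNames(vector("list", length(spec$sequence_labels)),
                     spec$sequence_labels)
  reader_mask <- function(src, deform, shift) {
    m <- perturb_mask(src, deform)
    # clamp the offset at 3 sd so the margin bound holds
    d <- pmax(pmin(round(rnorm(2, 0, shift)), ceiling(3 * shift)),
              -ceiling(3 * shift))
    .shift_mask(m, d[1], d[2])
  }
  for (g in groups) {
    l1 <- reader_mask(truth, spec$inter_reader_perturb,
                      spec$inter_reader_shift)
    base2 <- reader_mask(truth, spec$inter_reader_perturb,
                         spec$inter_reader_shift)
    l21 <- reader_mask(base2, spec$intra_reader_perturb,
                       spec$intra_reader_shift)
    l22 <- reader_mask(base2, spec$intra_reader_perturb,
                       spec$intra_reader_shift)
    trio <- list("L1" = delineation(l1, "L1"),
                 "L2.1" = delineation(l21, "L2.1"),
                 "L2.2" = delineation(l22, "L2.2"))
    for (sq in g) delins[[sq]] <- trio
  }

  list(patient_id = patient_id, side = side, images = images,
       delineations = delins, truth_mask = truth, adc_truth = adc_truth,
       dwi = dwi_store,
       provenance = list(rng_seed = spec$rng_seed,
                         inter_reader_perturb = spec$inter_reader_perturb,
                         intra_reader_perturb = spec$intra_reader_perturb,
                         adc_scale = 1e6))
}

# integer in-plane translation of a mask (empty cells fall off the grid;
# callers guarantee a margin so the mask never reaches the border)
.shift_mask <- function(mask, dr, dc) {
  if (dr == 0L && dc == 0L) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  src_r <- max(1L, 1L - dr):min(nr, nr - dr)
  src_c <- max(1L, 1L - dc):min(nc, nc - dc)
  out[src_r + dr, src_c + dc] <- mask[src_r, src_c]
  if (!any(out)) return(mask)
  out
}
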