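#' Read one case (image + delineation masks) from NIfTI files
#'
#' Images and masks are stored as single-slice NIfTI volumes with the
#' in-plane pixel spacing in the header. The naming convention is
#' `<patient>_<side>_<sequence>.nii.gz` for images and
#' `<patient>_<side>_<sequence>_mask_<reading>.nii.gz` for masks, with
#' `<reading>` one of `L1`, `L2.1`, `L2.2`. Masks are binarized (any
#' non-zero value is foreground) and must match the image grid exactly.
#'
#' @param image_path path to the image volume.
#' @param mask_paths character vector of mask volume paths.
#' @return A list with elements `image` ([seq_image()]) and `delineations`
#'   (named list of [delineation()]s keyed by reading).
#' @export
read_case <- function(image_path, mask_paths) {
  meta <- .parse_case_filename(image_path)
  vol <- RNifti::readNifti(image_path)
  px <- .as_slice(vol, image_path)
  sp <- RNifti::pixdim(vol)[1:2]
  img <- seq_image(px, sp, meta$sequence, meta$patient_id, meta$side)
  delins <- purrr::map(mask_paths, function(mp) {
    reading <- .parse_reading_suffix(mp)
    mvol <- RNifti::readNifti(mp)
    m <- .as_slice(mvol, mp)
    if (!identical(dim(m), dim(px))) {
      abort(sprintf("read_case: grid mismatch between image and mask '%s'",
                    basename(mp)))
    }
    if (!any(m != 0)) {
      abort(sprintf("read_case: empty mask '%s'", basename(mp)))
    }
    delineation(m != 0, reading)
  })
  names(delins) <- vapply(delins, function(d) d$reading, "")
  list(image = img, delineations = delins)
}

.as_slice <- function(vol, path) {
  a <- array(as.numeric(as.array(vol)), dim = dim(vol))  # strip nifti class
  d <- dim(a)
  if (length(d) == 3L) {
    if (d[3] != 1L) abort(sprintf("'%s': expected a single-slice volume",
                                  basename(path)))
    a <- a[, , 1L]
  } else if (length(d) != 2L) {
    abort(sprintf("'%s': expected a 2D or single-slice 3D volume",
                  basename(path)))
  }
  a
}

.parse_case_filename <- function(path) {
  base <- sub("\\.nii(\\.gz)?$", "", basename(path))
  for (sq in sequence_labels()) {
    suffix <- paste0("_", sq)
    if (endsWith(base, suffix)) {
      rest <- substr(base, 1L, nchar(base) - nchar(suffix))
      parts <- strsplit(rest, "_")[[1]]
      side <- tail(parts, 1L)
      pid <- paste(head(parts, -1L), collapse = "_")
      if (!side %in% c("left", "right")) side <- NA_character_
      return(list(patient_id = if (nzchar(pid)) pid else NA_character_,
                  side = side, sequence = sq))
    }
  }
  abort(sprintf("cannot parse sequence label from file name '%s'",
                basename(path)))
}

.parse_reading_suffix <- function(path) {
  base <- sub("\\.nii(\\.gz)?$", "", basename(path))
  m <- regmatches(base, regexpr("_(L1|L2\\.1|L2\\.2)$", base))
  if (!length(m)) {
    abort(sprintf("cannot parse reading label (_L1/_L2.1/_L2.2) from '%s'",
                  basename(path)))
  }
  sub("^_", "", m)
}

#' Write a synthetic case to NIfTI files
#'
#' Writes each sequence image and its three delineation masks as
#' single-slice NIfTI volumes under `dir`, following the naming convention
#' of [read_case()].
#'
#' @param case one case from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a character vector of the file paths written.
#' @export
write_case <- function(case, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (sq in names(case$images)) {
    img <- case$images[[sq]]
    stem <- sprintf("%s_%s_%s", img$patient_id, img$side, sq)
    ipath <- file.path(dir, paste0(stem, ".nii.gz"))
    .write_slice(img$pixels, img$spacing_mm, ipath)
    paths <- c(paths, ipath)
    for (rd in names(case$delineations[[sq]])) {
      mpath <- file.path(dir, paste0(stem, "_mask_", rd, ".nii.gz"))
      .write_slice(case$delineations[[sq]][[rd]]$mask * 1,
                   img$spacing_mm, mpath)
      paths <- c(paths, mpath)
    }
  }
  invisible(paths)
}

.write_slice <- function(mat, spacing_mm, path) {
  arr <- matrix(as.numeric(mat), nrow(mat), ncol(mat))
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, as.numeric(spacing_mm))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Write a cohort to disk with a manifest
#'
#' Writes every case via [write_case()] plus a `manifest.csv` listing the
#' files per (patient, side, sequence, reading).
#'
#' @param cohort list of cases from [generate_cohort()].
#' @param dir output directory.
#' @return Invisibly, the manifest tibble.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- purrr::map(cohort, function(case) {
    write_case(case, dir)
    purrr::map(names(case$images), function(sq) {
      stem <- sprintf("%s_%s_%s", case$patient_id, case$side, sq)
      tibble::tibble(patient_id = case$patient_id, side = case$side,
                     sequence = sq,
                     image = paste0(stem, ".nii.gz"),
                     reading = reading_labels(),
                     mask = paste0(stem, "_mask_", reading_labels(), ".nii.gz"))
    })
  })
  manifest <- dplyr::bind_rows(purrr::flatten(rows))
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}
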