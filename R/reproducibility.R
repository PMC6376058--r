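#' Two-way intraclass correlation, absolute agreement, average measures
#'
#' McGraw-Wong ICC(A,k) for `k = 2` readings, written out from the two-way
#' ANOVA mean squares (rows = subjects/ROIs, columns = readings):
#' `ICC = (MS_R - MS_E) / (MS_R + (MS_C - MS_E) / n)`. The value may be
#' negative and is reported as computed, not floored at zero; it is 1 when
#' the two readings are identical and subjects vary. Zero between-subject
#' variance (a constant feature) is flagged missing (`NA`).
#'
#' @param x,y paired numeric vectors (one value per subject), `n >= 3`,
#'   no missing values.
#' @return A single numeric value in `(-Inf, 1]`, or `NA`.
#' @export
#' @examples
#' icc_agreement(1:5, 1:5)        # 1
icc_agreement <- function(x, y) {
  n <- length(x)
  if (length(y) != n) abort("icc_agreement: x and y must be paired")
  if (n < 3L) abort("icc_agreement: need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) return(NA_real_)
  Y <- cbind(x, y)
  k <- 2L
  grand <- mean(Y)
  rmeans <- rowMeans(Y)
  cmeans <- colMeans(Y)
  if (var(rmeans) == 0) return(NA_real_)   # no between-subject variance
  msr <- k * sum((rmeans - grand)^2) / (n - 1)
  msc <- n * sum((cmeans - grand)^2) / (k - 1)
  resid <- Y - outer(rmeans, rep(1, k)) -
    outer(rep(1, n), cmeans) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  denom <- msr + (msc - mse) / n
  if (denom == 0) return(NA_real_)
  (msr - mse) / denom
}

#' Lin's concordance correlation coefficient
#'
#' `rho_c = 2 * s_xy / (s_x^2 + s_y^2 + (mean_x - mean_y)^2)` with
#' population (divisor `n`) moments. Bounded in `[-1, 1]`; equals the
#' Pearson correlation times a bias-correction factor `<= 1`, with
#' equality when the two means and variances match. Two constant inputs
#' are flagged missing.
#'
#' @param x,y paired numeric vectors, `n >= 2`, no missing values.
#' @return A single numeric value in `[-1, 1]`, or `NA`.
#' @export
#' @examples
#' lin_ccc(c(1, 2, 3), c(2, 3, 4))  # 4/7
lin_ccc <- function(x, y) {
  n <- length(x)
  if (length(y) != n) abort("lin_ccc: x and y must be paired")
  if (n < 2L) abort("lin_ccc: need at least 2 paired observations")
  if (anyNA(x) || anyNA(y)) return(NA_real_)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  if (sx2 == 0 && sy2 == 0) return(NA_real_)   # both inputs constant
  denom <- sx2 + sy2 + (mx - my)^2
  2 * sxy / denom
}

#' Select reproducible features from a long feature table
#'
#' For every (feature, sequence) pair, computes the three pairwise ICCs
#' (`L1/L2.1`, `L1/L2.2`, `L2.1/L2.2`; [icc_agreement()]) and Lin's CCC on
#' the intra-reader pair (`L2.1/L2.2`; [lin_ccc()]), pooling all ROIs
#' (both glands of every patient) of that sequence as subjects. A pair is
#' flagged `reproducible` when all three ICCs are at or above
#' `icc_threshold`, the CCC is at or above `ccc_threshold`, and no input
#' value was flagged missing. ROIs missing one of the three readings are
#' dropped from all pairings with a warning.
#'
#' @param feature_table long tibble from [extract_features()].
#' @param icc_threshold,ccc_threshold reproducibility thresholds.
#' @return A tibble with one row per (feature, sequence): `feature`,
#'   `family`, `sequence`, `icc_L1_L21`, `icc_L1_L22`, `icc_L21_L22`,
#'   `ccc_L21_L22`, `n_subjects`, `reproducible`. Thresholds are attached
#'   as attributes.
#' @export
select_reproducible <- function(feature_table, icc_threshold = 0.8,
                                ccc_threshold = 0.9) {
  .check_feature_table(feature_table)
  schema <- feature_schema()
  n_dropped <- 0L
  res <- purrr::map(unique(feature_table$sequence), function(sq) {
    wide <- .reading_arrays(feature_table, sq)
    n_dropped <<- n_dropped + wide$n_dropped
    purrr::map(schema$feature, function(ft) {
      v1 <- wide$L1[, ft]; v21 <- wide$L21[, ft]; v22 <- wide$L22[, ft]
      iccs <- c(icc_agreement(v1, v21), icc_agreement(v1, v22),
                icc_agreement(v21, v22))
      ccc <- lin_ccc(v21, v22)
      any_missing <- anyNA(c(v1, v21, v22)) || anyNA(iccs) || is.na(ccc)
      tibble::tibble(
        feature = ft,
        family = schema$family[schema$feature == ft],
        sequence = sq,
        icc_L1_L21 = iccs[1], icc_L1_L22 = iccs[2], icc_L21_L22 = iccs[3],
        ccc_L21_L22 = ccc,
        n_subjects = length(v1),
        reproducible = !any_missing &&
          all(iccs >= icc_threshold) && ccc >= ccc_threshold)
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(res))
  if (n_dropped > 0L) {
    warn(paste0("select_reproducible: dropped ", n_dropped,
                " ROI reading set(s) missing at least one reading"))
  }
  attr(out, "icc_threshold") <- icc_threshold
  attr(out, "ccc_threshold") <- ccc_threshold
  out
}

# Per-sequence feature matrices aligned by subject (patient_id x side),
# one matrix per reading; subjects missing any reading are dropped.
.reading_arrays <- function(feature_table, sq) {
  d <- dplyr::filter(feature_table, .data$sequence == sq)
  d$subject <- paste(d$patient_id, d$side, sep = "/")
  complete <- Reduce(intersect, lapply(reading_labels(), function(rd) {
    d$subject[d$reading == rd]
  }))
  dropped <- setdiff(unique(d$subject), complete)
  feats <- feature_schema()$feature
  get_mat <- function(rd) {
    dd <- d[d$reading == rd, , drop = FALSE]
    dd <- dd[match(complete, dd$subject), , drop = FALSE]
    as.matrix(dd[, feats])
  }
  list(L1 = get_mat("L1"), L21 = get_mat("L2.1"), L22 = get_mat("L2.2"),
       n_dropped = length(dropped))
}

.check_feature_table <- function(feature_table) {
  missing_keys <- setdiff(.key_cols(), names(feature_table))
  if (length(missing_keys)) {
    abort(paste("feature table is missing key column(s):",
                paste(missing_keys, collapse = ", ")))
  }
  missing_feats <- setdiff(feature_schema()$feature, names(feature_table))
  if (length(missing_feats)) {
    abort(paste("feature table is missing", length(missing_feats),
                "feature column(s)"))
  }
  invisible(TRUE)
}
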