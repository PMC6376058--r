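# Texture feature formulas. Each function takes the matching
# `texture_matrix` object and returns a named numeric vector; degenerate
# matrices (no counted pairs / runs / zones) yield NA for every feature of
# the family, never silent zeros.

.entropy2 <- function(p) {
  p <- p[p > 0]
  if (!length(p)) return(0)
  -sum(p * log2(p))
}

#' GLCM features
#'
#' The 26 co-occurrence features of the extractor schema, computed from the
#' direction-merged symmetric normalized GLCM. IBSI-named features follow
#' the IBSI formulas. Name pairs without a unique published definition use
#' declared conventions: `Homogeneity 1` is inverse difference,
#' `Homogeneity 2` is inverse difference moment (so it coincides with the
#' separately listed `IDM`); `Correlation 1` / `Variance 1` use the
#' marginal-moment parameterization and `Correlation 2` / `Variance 2` the
#' joint-deviation parameterization (these coincide for a symmetric merged
#' matrix); `Sum Mean` is half the `Sum Average`; `Agreement` is the
#' chance-corrected diagonal agreement (Cohen's kappa of the co-occurrence
#' matrix against its marginals).
#'
#' @param tm a `texture_matrix` from [build_glcm()].
#' @return Named numeric vector of the 26 `glcm_*` features.
#' @export
glcm_features <- function(tm) {
  stopifnot(tm$kind == "GLCM")
  out <- setNames(rep(NA_real_, 26L), .glcm_names())
  P <- tm$p
  if (sum(tm$counts) == 0) return(out)
  L <- tm$n_levels
  i <- row(P); j <- col(P)
  pi_m <- rowSums(P)                     # marginal (== colSums, symmetric)
  mu <- sum(seq_len(L) * pi_m)
  sig2 <- sum((seq_len(L) - mu)^2 * pi_m)

  # diagonal |i-j| and cross i+j distributions
  dvals <- 0:(L - 1L)
  p_diff <- vapply(dvals, function(k) sum(P[abs(i - j) == k]), numeric(1))
  svals <- 2:(2L * L)
  p_sum <- vapply(svals, function(k) sum(P[(i + j) == k]), numeric(1))

  hx <- .entropy2(pi_m)
  hxy <- .entropy2(P)
  pp <- outer(pi_m, pi_m)
  ok <- P > 0 & pp > 0
  hxy1 <- -sum(P[ok] * log2(pp[ok]))
  hxy2 <- .entropy2(pp)

  p_o <- sum(diag(P))
  p_e <- sum(pi_m^2)
  out["glcm_agreement"] <- if (p_e < 1) (p_o - p_e) / (1 - p_e) else NA_real_
  out["glcm_autocorrelation"] <- sum(i * j * P)
  out["glcm_cluster_prominence"] <- sum((i + j - 2 * mu)^4 * P)
  out["glcm_cluster_shade"] <- sum((i + j - 2 * mu)^3 * P)
  out["glcm_cluster_tendency"] <- sum((i + j - 2 * mu)^2 * P)
  out["glcm_contrast"] <- sum((i - j)^2 * P)
  out["glcm_correlation1"] <-
    if (sig2 > 0) (sum(i * j * P) - mu^2) / sig2 else NA_real_
  out["glcm_correlation2"] <-
    if (sig2 > 0) sum((i - mu) * (j - mu) * P) / sig2 else NA_real_
  out["glcm_difference_entropy"] <- .entropy2(p_diff)
  out["glcm_dissimilarity"] <- sum(abs(i - j) * P)
  out["glcm_homogeneity1"] <- sum(P / (1 + abs(i - j)))
  out["glcm_homogeneity2"] <- sum(P / (1 + (i - j)^2))
  out["glcm_imc1"] <- if (hx > 0) (hxy - hxy1) / hx else NA_real_
  out["glcm_imc2"] <- sqrt(max(1 - exp(-2 * (hxy2 - hxy)), 0))
  out["glcm_idm"] <- sum(P / (1 + (i - j)^2))
  out["glcm_idmn"] <- sum(P / (1 + ((i - j) / L)^2))
  out["glcm_inverse_variance"] <- sum(P[i != j] / (i[i != j] - j[i != j])^2)
  out["glcm_joint_energy"] <- sum(P^2)
  out["glcm_joint_entropy"] <- hxy
  out["glcm_maximum_probability"] <- max(P)
  sa <- sum(svals * p_sum)
  out["glcm_sum_average"] <- sa
  out["glcm_sum_entropy"] <- .entropy2(p_sum)
  out["glcm_sum_mean"] <- sa / 2
  out["glcm_sum_variance"] <- sum((svals - sa)^2 * p_sum)
  out["glcm_variance1"] <- sig2
  out["glcm_variance2"] <- sum((i - mu)^2 * P)
  out
}

#' GLRLM features
#'
#' The 13 run-length features, per IBSI formulas, from the direction-merged
#' run-length matrix. `Run Percentage` uses the total run count over
#' (number of directions x ROI pixel count) so that an ROI in which every
#' run has length one attains exactly 1.
#'
#' @param tm a `texture_matrix` from [build_glrlm()].
#' @return Named numeric vector of the 13 `glrlm_*` features.
#' @export
glrlm_features <- function(tm) {
  stopifnot(tm$kind == "GLRLM")
  out <- setNames(rep(NA_real_, 13L), .glrlm_names())
  R <- tm$counts
  ns <- sum(R)
  if (ns == 0) return(out)
  p <- R / ns
  i <- row(R); j <- col(R)
  r_i <- rowSums(R); r_j <- colSums(R)
  jj <- seq_len(ncol(R)); ii <- seq_len(nrow(R))
  mu_g <- sum(i * p); mu_r <- sum(j * p)
  out["glrlm_glv"] <- sum((i - mu_g)^2 * p)
  out["glrlm_gln"] <- sum(r_i^2) / ns
  out["glrlm_hglre"] <- sum(r_i * ii^2) / ns
  out["glrlm_lre"] <- sum(r_j * jj^2) / ns
  out["glrlm_lrhgle"] <- sum(R * i^2 * j^2) / ns
  out["glrlm_lrlgle"] <- sum(R * j^2 / i^2) / ns
  out["glrlm_lglre"] <- sum(r_i / ii^2) / ns
  out["glrlm_rln"] <- sum(r_j^2) / ns
  out["glrlm_rp"] <- ns / (tm$directions * tm$n_pixels)
  out["glrlm_rv"] <- sum((j - mu_r)^2 * p)
  out["glrlm_sre"] <- sum(r_j / jj^2) / ns
  out["glrlm_srhgle"] <- sum(R * i^2 / j^2) / ns
  out["glrlm_srlgle"] <- sum(R / (i^2 * j^2)) / ns
  out
}

#' GLSZM features
#'
#' The 13 size-zone features, per IBSI formulas, from the zone matrix.
#' `Zone Percentage` is the number of zones over the ROI pixel count.
#'
#' @param tm a `texture_matrix` from [build_glszm()].
#' @return Named numeric vector of the 13 `glszm_*` features.
#' @export
glszm_features <- function(tm) {
  stopifnot(tm$kind == "GLSZM")
  out <- setNames(rep(NA_real_, 13L), .glszm_names())
  Z <- tm$counts
  ns <- sum(Z)
  if (ns == 0) return(out)
  p <- Z / ns
  i <- row(Z); j <- col(Z)
  z_i <- rowSums(Z); z_j <- colSums(Z)
  jj <- seq_len(ncol(Z)); ii <- seq_len(nrow(Z))
  mu_g <- sum(i * p); mu_z <- sum(j * p)
  out["glszm_gln"] <- sum(z_i^2) / ns
  out["glszm_glv"] <- sum((i - mu_g)^2 * p)
  out["glszm_hglze"] <- sum(z_i * ii^2) / ns
  out["glszm_lae"] <- sum(z_j * jj^2) / ns
  out["glszm_lahgle"] <- sum(Z * i^2 * j^2) / ns
  out["glszm_lalgle"] <- sum(Z * j^2 / i^2) / ns
  out["glszm_lglze"] <- sum(z_i / ii^2) / ns
  out["glszm_zsn"] <- sum(z_j^2) / ns
  out["glszm_sae"] <- sum(z_j / jj^2) / ns
  out["glszm_sahgle"] <- sum(Z * i^2 / j^2) / ns
  out["glszm_salgle"] <- sum(Z / (i^2 * j^2)) / ns
  out["glszm_zp"] <- ns / tm$n_pixels
  out["glszm_zv"] <- sum((j - mu_z)^2 * p)
  out
}

#' NGTDM features
#'
#' The 5 neighbourhood grey-tone difference features (Amadasun-King / IBSI
#' formulas). `Coarseness` is capped at 1e6 when its denominator vanishes
#' (perfectly flat ROI); `Busyness` and `Strength` are 0 when only one
#' grey level is present.
#'
#' @param tm a `texture_matrix` from the internal NGTDM builder.
#' @return Named numeric vector of the 5 `ngtdm_*` features.
#' @export
ngtdm_features <- function(tm) {
  stopifnot(tm$kind == "NGTDM")
  out <- setNames(rep(NA_real_, 5L), .ngtdm_names())
  if (tm$n_valid == 0) return(out)
  pres <- which(tm$p_i > 0)
  p <- tm$p_i[pres]; s <- tm$s_i[pres]; g <- pres
  ngp <- length(pres)
  nv <- tm$n_valid
  ps <- sum(p * s)
  out["ngtdm_coarseness"] <- if (ps > 0) min(1 / ps, 1e6) else 1e6
  if (ngp > 1L) {
    dg2 <- outer(g, g, "-")^2
    out["ngtdm_contrast"] <-
      sum(outer(p, p) * dg2) / (ngp * (ngp - 1)) * sum(s) / nv
    denom_b <- sum(abs(outer(g * p, g * p, "-")))
    out["ngtdm_busyness"] <- if (denom_b > 0) ps / denom_b else 0
    pij <- outer(p, p, "+")
    psij <- outer(p * s, p * s, "+")
    out["ngtdm_complexity"] <- sum(abs(outer(g, g, "-")) * psij / pij) / nv
    ssum <- sum(s)
    out["ngtdm_strength"] <- if (ssum > 0) sum(pij * dg2) / ssum else 0
  } else {
    out["ngtdm_contrast"] <- 0
    out["ngtdm_busyness"] <- 0
    out["ngtdm_complexity"] <- 0
    out["ngtdm_strength"] <- 0
  }
  out
}
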