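# Texture matrix construction. All builders take a level matrix `lev`
# (integer grey levels inside the ROI, NA outside) and operate in pixel
# units; direction-dependent matrices use the four 2D angles
# 0, 45, 90, 135 degrees at distance 1 and are merged by summing counts
# over directions before normalization.

.offsets4 <- function() list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))

# level matrix from a mask + discretized levels
.level_matrix <- function(mask, levels) {
  lev <- matrix(NA_integer_, nrow(mask), ncol(mask))
  lev[mask] <- levels
  lev
}

#' Build a grey-level co-occurrence matrix
#'
#' Counts co-occurrences of grey-level pairs at distance 1 along the four
#' 2D angles (0, 45, 90, 135 degrees), pooled by summing over directions
#' and symmetrised (each pair counted in both orders). Only pixel pairs
#' with both pixels inside the ROI are counted.
#'
#' @param discretized a [discretize()] result for the ROI pixels.
#' @param mask logical matrix locating those pixels.
#' @param distance neighbour distance in pixels (fixed at 1).
#' @return List of class `texture_matrix` with `kind = "GLCM"`: `counts`
#'   (symmetric level x level matrix), `p` (normalized, sums to 1 when any
#'   pair exists), `n_levels`, `directions`.
#' @export
build_glcm <- function(discretized, mask, distance = 1L) {
  stopifnot(distance == 1L)
  lev <- .level_matrix(mask, discretized$levels)
  L <- discretized$n_levels
  counts <- matrix(0, L, L)
  nr <- nrow(lev); nc <- ncol(lev)
  for (off in .offsets4()) {
    r1 <- max(1L, 1L - off[1]):min(nr, nr - off[1])
    c1 <- max(1L, 1L - off[2]):min(nc, nc - off[2])
    a <- lev[r1, c1, drop = FALSE]
    b <- lev[r1 + off[1], c1 + off[2], drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (any(ok)) {
      ia <- a[ok]; ib <- b[ok]
      t1 <- tabulate((ib - 1L) * L + ia, L * L)
      counts <- counts + matrix(t1, L, L)
    }
  }
  counts <- counts + t(counts)  # symmetrise (both orders of each pair)
  s <- sum(counts)
  structure(list(kind = "GLCM", counts = counts,
                 p = if (s > 0) counts / s else counts,
                 n_levels = L, directions = 4L),
            class = "texture_matrix")
}

#' Build a grey-level run-length matrix
#'
#' Runs of equal grey level along each of the four 2D directions, truncated
#' at the ROI boundary; the four per-direction matrices are summed into one
#' matrix before feature computation.
#'
#' @inheritParams build_glcm
#' @return List of class `texture_matrix` with `kind = "GLRLM"`: `counts`
#'   (level x run-length matrix), `p`, `n_levels`, `n_pixels`, `directions`.
#' @export
build_glrlm <- function(discretized, mask) {
  lev <- .level_matrix(mask, discretized$levels)
  L <- discretized$n_levels
  nr <- nrow(lev); nc <- ncol(lev)
  # scan lines: rows (0 deg), columns (90 deg), main diagonals
  # (row - col constant, 135 deg) and anti-diagonals (row + col, 45 deg)
  lines <- c(
    lapply(seq_len(nr), function(r) lev[r, ]),
    lapply(seq_len(nc), function(c) lev[, c]),
    split(lev, row(lev) - col(lev)),
    split(lev, row(lev) + col(lev))
  )
  runs_lev <- integer(0); runs_len <- integer(0)
  for (v in lines) {
    r <- rle(ifelse(is.na(v), -1L, as.integer(v)))
    keep <- r$values > 0L
    if (any(keep)) {
      runs_lev <- c(runs_lev, r$values[keep])
      runs_len <- c(runs_len, r$lengths[keep])
    }
  }
  Jmax <- if (length(runs_len)) max(runs_len) else 1L
  counts <- matrix(0, L, Jmax)
  if (length(runs_len)) {
    t1 <- tabulate((runs_len - 1L) * L + runs_lev, L * Jmax)
    counts <- matrix(t1, L, Jmax)
  }
  s <- sum(counts)
  structure(list(kind = "GLRLM", counts = counts,
                 p = if (s > 0) counts / s else counts,
                 n_levels = L, n_pixels = sum(!is.na(lev)), directions = 4L),
            class = "texture_matrix")
}

#' Build a grey-level size-zone matrix
#'
#' Zones are 8-connected components of equal grey level within the ROI;
#' the matrix counts zones by (level, size). Direction-free.
#'
#' @inheritParams build_glcm
#' @return List of class `texture_matrix` with `kind = "GLSZM"`: `counts`
#'   (level x zone-size matrix), `p`, `n_levels`, `n_pixels`.
#' @export
build_glszm <- function(discretized, mask) {
  lev <- .level_matrix(mask, discretized$levels)
  L <- discretized$n_levels
  lv <- numeric(length(lev)); lv[which(mask)] <- discretized$levels
  cc <- mask_components_full(mask, levels = lv)
  idx <- which(mask)
  zone_level <- vapply(seq_len(cc$n), function(k) {
    as.integer(lev[idx[match(k, cc$membership)]])
  }, integer(1))
  zone_size <- cc$sizes
  Smax <- if (length(zone_size)) max(zone_size) else 1L
  counts <- matrix(0, L, Smax)
  if (length(zone_size)) {
    t1 <- tabulate((zone_size - 1L) * L + zone_level, L * Smax)
    counts <- matrix(t1, L, Smax)
  }
  s <- sum(counts)
  structure(list(kind = "GLSZM", counts = counts,
                 p = if (s > 0) counts / s else counts,
                 n_levels = L, n_pixels = length(idx)),
            class = "texture_matrix")
}

# NGTDM accumulators: for each level i present in the ROI, n_i (pixel
# count), p_i = n_i / Nv, and s_i = sum over those pixels of
# |i - mean(valid 8-neighbourhood)| with neighbours restricted to the ROI.
# Pixels with no valid neighbour are excluded from Nv.
build_ngtdm <- function(discretized, mask) {
  lev <- .level_matrix(mask, discretized$levels)
  L <- discretized$n_levels
  nr <- nrow(lev); nc <- ncol(lev)
  pad <- matrix(NA_real_, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- lev
  nb_sum <- matrix(0, nr, nc)
  nb_cnt <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    sh <- pad[2:(nr + 1L) + dr, 2:(nc + 1L) + dc, drop = FALSE]
    ok <- !is.na(sh)
    nb_sum[ok] <- nb_sum[ok] + sh[ok]
    nb_cnt <- nb_cnt + ok
  }
  valid <- !is.na(lev) & nb_cnt > 0L
  dev <- abs(lev[valid] - nb_sum[valid] / nb_cnt[valid])
  li <- as.integer(lev[valid])
  s_i <- vapply(seq_len(L), function(i) sum(dev[li == i]), numeric(1))
  n_i <- tabulate(li, L)
  nv <- sum(n_i)
  structure(list(kind = "NGTDM", s_i = s_i, n_i = n_i,
                 p_i = if (nv > 0) n_i / nv else n_i,
                 n_levels = L, n_valid = nv),
            class = "texture_matrix")
}
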