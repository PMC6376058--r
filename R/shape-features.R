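#' Shape features of a 2D ROI mask
#'
#' Computes the 13 shape descriptors of the extractor's schema from a
#' binary mask and its pixel spacing. Shape features depend only on the
#' mask geometry, never on pixel intensities.
#'
#' Conventions: `Surface Area` is pixel count times pixel area (mm^2);
#' `Perimeter` is the pixel-edge perimeter (total length of exposed
#' 4-neighbour edges, mm); the convex hull is built over pixel corners, so
#' a filled axis-aligned rectangle has `Solidity = 1` exactly;
#' `Deficit = 1 - Solidity`; axis lengths come from the second-central-
#' moment ellipse of pixel centres (`4 * sqrt(eigenvalue)` convention);
#' `Elongation = Minor/Major`; `Extension` is area over axis-aligned
#' bounding-box area; `Maximum Diameter` is the largest Euclidean distance
#' between boundary pixel centres; `Maximum Geodesic Diameter` is the
#' longest within-mask 8-connected shortest path between boundary pixels;
#' `Perimeter Solidity` is convex-hull perimeter over perimeter.
#'
#' @param mask logical matrix, one 8-connected component.
#' @param spacing_mm `(row_mm, col_mm)`, strictly positive.
#' @return Named numeric vector of the 13 `shape_*` features.
#' @export
compute_shape <- function(mask, spacing_mm) {
  mask <- as.matrix(mask) != 0
  if (!any(mask)) abort("compute_shape: empty mask")
  sr <- spacing_mm[1]; sc <- spacing_mm[2]
  if (any(spacing_mm <= 0)) abort("compute_shape: spacing must be positive")
  idx <- which(mask, arr.ind = TRUE)
  npix <- nrow(idx)
  if (any(idx[, 1] %in% c(1L, nrow(mask))) ||
      any(idx[, 2] %in% c(1L, ncol(mask)))) {
    warn("compute_shape: mask touches the image border")
  }
  area <- npix * sr * sc

  # pixel-edge perimeter: each exposed 4-neighbour edge contributes the
  # corresponding pixel side length
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask
  core <- p[2:(nr + 1L), 2:(nc + 1L)]
  up <- core & !p[1:nr, 2:(nc + 1L)]
  dn <- core & !p[3:(nr + 2L), 2:(nc + 1L)]
  lf <- core & !p[2:(nr + 1L), 1:nc]
  rt <- core & !p[2:(nr + 1L), 3:(nc + 2L)]
  perimeter <- (sum(up) + sum(dn)) * sc + (sum(lf) + sum(rt)) * sr

  # convex hull over pixel corners (y = row coordinate, x = col coordinate,
  # both in mm); corners of pixel (r, c) are (r +/- 0.5, c +/- 0.5)
  corner_y <- c(idx[, 1] - 0.5, idx[, 1] - 0.5, idx[, 1] + 0.5, idx[, 1] + 0.5) * sr
  corner_x <- c(idx[, 2] - 0.5, idx[, 2] + 0.5, idx[, 2] - 0.5, idx[, 2] + 0.5) * sc
  pts <- unique(cbind(corner_x, corner_y))
  h <- grDevices::chull(pts)
  hx <- pts[h, 1]; hy <- pts[h, 2]
  # shoelace area and hull perimeter
  nh <- length(h)
  j <- c(seq_len(nh)[-1], 1L)
  convex_area <- abs(sum(hx * hy[j] - hx[j] * hy)) / 2
  hull_perimeter <- sum(sqrt((hx[j] - hx)^2 + (hy[j] - hy)^2))

  solidity <- min(area / convex_area, 1)
  deficit <- 1 - solidity

  # second-central-moment ellipse of pixel centres
  yy <- idx[, 1] * sr; xx <- idx[, 2] * sc
  my <- mean(yy); mx <- mean(xx)
  cyy <- mean((yy - my)^2); cxx <- mean((xx - mx)^2)
  cxy <- mean((yy - my) * (xx - mx))
  tr <- cyy + cxx
  det <- cyy * cxx - cxy^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc; l2 <- max(tr / 2 - disc, 0)
  major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
  elongation <- if (major > 0) minor / major else NA_real_
  eccentricity <- if (major > 0) sqrt(max(1 - (minor / major)^2, 0)) else NA_real_

  bbox_area <- (diff(range(idx[, 1])) + 1L) * sr *
    ((diff(range(idx[, 2])) + 1L) * sc)
  extension <- area / bbox_area

  bnd <- mask_boundary(mask)
  bidx <- which(bnd, arr.ind = TRUE)
  by <- bidx[, 1] * sr; bx <- bidx[, 2] * sc
  max_diam <- if (nrow(bidx) > 1L) max(stats::dist(cbind(bx, by))) else 0

  max_geo <- .max_geodesic_diameter(mask, bnd, sr, sc)

  perimeter_solidity <- hull_perimeter / perimeter

  out <- c(convex_area, deficit, eccentricity, elongation, extension,
           major, max_diam, max_geo, minor, perimeter,
           perimeter_solidity, solidity, area)
  names(out) <- .shape_names()
  out
}

# Longest within-mask shortest path (mm) between boundary pixels, over the
# 8-connected pixel graph with Euclidean step weights.
.max_geodesic_diameter <- function(mask, bnd = mask_boundary(mask), sr, sc) {
  idx <- which(mask)
  if (length(idx) == 1L) return(0)
  nr <- nrow(mask)
  id <- integer(length(mask)); id[idx] <- seq_along(idx)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  edges <- NULL; wts <- NULL
  for (off in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    r2 <- rows + off[1]; c2 <- cols + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(mask)
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    ok2 <- mask[nb]
    a <- id[idx[ok][ok2]]; b <- id[nb[ok2]]
    if (length(a)) {
      edges <- rbind(edges, cbind(a, b))
      wts <- c(wts, rep(sqrt((off[1] * sr)^2 + (off[2] * sc)^2), length(a)))
    }
  }
  g <- igraph::make_graph(t(edges), n = length(idx), directed = FALSE)
  bv <- id[which(bnd)]
  d <- igraph::distances(g, v = bv, to = bv, weights = wts)
  max(d[is.finite(d)])
}
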