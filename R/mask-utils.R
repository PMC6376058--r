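# Low-level binary-mask utilities shared by the shape extractor, the
# size-zone labeller and the synthetic delineation perturbation model.
# Masks are logical matrices indexed [row, col]; connectivity is
# 8-connected for foreground unless stated otherwise.

# Edge list between 8-neighbouring pixels of `idx` (linear indices into an
# nr x nc grid) that satisfy `same(a, b)`. Returns a 2-column matrix of
# positions into `idx`.
.mask_edges <- function(mask, levels = NULL) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  id <- integer(nr * nc)
  id[idx] <- seq_along(idx)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  edges <- vector("list", 4L)
  k <- 0L
  for (off in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    r2 <- rows + off[1]; c2 <- cols + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    ok2 <- mask[nb]
    a <- idx[ok][ok2]; b <- nb[ok2]
    if (!is.null(levels)) {
      same <- levels[a] == levels[b]
      a <- a[same]; b <- b[same]
    }
    k <- k + 1L
    edges[[k]] <- cbind(id[a], id[b])
  }
  do.call(rbind, edges)
}

# Label 8-connected components; optionally split by equal `levels`
# (a matrix congruent with mask, used for grey-level zones).
# Returns list(membership = integer over which(mask), n, sizes).
mask_components_full <- function(mask, levels = NULL) {
  idx <- which(mask)
  n <- length(idx)
  if (n == 0L) return(list(membership = integer(0), n = 0L, sizes = integer(0)))
  e <- .mask_edges(mask, levels)
  g <- igraph::make_graph(t(e), n = n, directed = FALSE)
  comp <- igraph::components(g)
  list(membership = comp$membership, n = comp$no,
       sizes = as.integer(comp$csize))
}

mask_n_components <- function(mask) mask_components_full(mask)$n

# Keep only the largest 8-connected component.
mask_largest_component <- function(mask) {
  cc <- mask_components_full(mask)
  if (cc$n <= 1L) return(mask)
  keep <- which.max(cc$sizes)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  out[which(mask)[cc$membership == keep]] <- TRUE
  out
}

# Foreground pixels with at least one 4-neighbour outside the mask
# (the image border counts as outside).
mask_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask
  core <- p[2:(nr + 1L), 2:(nc + 1L)]
  nb_all <- p[1:nr, 2:(nc + 1L)] & p[3:(nr + 2L), 2:(nc + 1L)] &
    p[2:(nr + 1L), 1:nc] & p[2:(nr + 1L), 3:(nc + 2L)]
  core & !nb_all
}

# Bounding box (row/col ranges) of a mask, optionally padded by `margin`
# pixels and clipped to the grid.
mask_bbox <- function(mask, margin = 0L) {
  idx <- which(mask, arr.ind = TRUE)
  r <- range(idx[, 1]); c <- range(idx[, 2])
  list(r1 = max(1L, r[1] - margin), r2 = min(nrow(mask), r[2] + margin),
       c1 = max(1L, c[1] - margin), c2 = min(ncol(mask), c[2] + margin))
}

# Signed Euclidean distance (pixel units) to the mask boundary, positive
# inside, computed on the full grid brute-force against the inner and
# outer boundary pixel sets. Intended for the modest grids used here.
mask_signed_distance <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  inner <- mask_boundary(mask)
  outer <- mask_boundary(!mask) & !mask
  all_r <- rep.int(seq_len(nr), nc)
  all_c <- rep(seq_len(nc), each = nr)
  min_dist_to <- function(set) {
    idx <- which(set, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(matrix(Inf, nr, nc))
    d2 <- matrix(Inf, nr, nc)
    for (k in seq_len(nrow(idx))) {
      cand <- (all_r - idx[k, 1])^2 + (all_c - idx[k, 2])^2
      d2 <- pmin(d2, matrix(cand, nr, nc))
    }
    sqrt(d2)
  }
  # distance from foreground pixels to nearest outside pixel, and from
  # background pixels to nearest foreground pixel
  d_out <- min_dist_to(outer)
  d_in <- min_dist_to(inner)
  ifelse(mask, d_out, -d_in)
}
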