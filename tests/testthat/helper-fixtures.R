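# Shared fixtures and independent brute-force oracles. Oracles are written
# as plain enumerations, independent of the package's vectorised builders.

make_image <- function(pixels, spacing = c(1, 1), label = "T1",
                       patient = "P001", side = "left") {
  seq_image(as.matrix(pixels), spacing, label, patient, side)
}

rect_mask <- function(nr, nc, r, c) {
  m <- matrix(FALSE, nr, nc)
  m[r, c] <- TRUE
  m
}

# small random ROI on an nr x nc grid: a random connected blob grown from
# a seed pixel (always a single 8-connected component)
random_blob <- function(nr, nc, npix, margin = 1) {
  m <- matrix(FALSE, nr, nc)
  lo <- 1 + margin
  cur <- c(sample(lo:(nr - margin), 1), sample(lo:(nc - margin), 1))
  m[cur[1], cur[2]] <- TRUE
  npix <- min(npix, (nr - 2 * margin) * (nc - 2 * margin))
  while (sum(m) < npix) {
    idx <- which(m, arr.ind = TRUE)
    p <- idx[sample(nrow(idx), 1), ]
    step <- p + c(sample(-1:1, 1), sample(-1:1, 1))
    if (step[1] >= lo && step[1] <= nr - margin &&
        step[2] >= lo && step[2] <= nc - margin) {
      m[step[1], step[2]] <- TRUE
    }
  }
  m
}

tiny_cohort_spec <- function(n_patients = 2, seed = 101, ...) {
  cohort_spec(n_patients = n_patients, rng_seed = seed, ...)
}

# --- independent oracles ----------------------------------------------------

# GLCM by exhaustive enumeration of all ordered pixel pairs at the four
# distance-1 angle offsets
oracle_glcm <- function(lev) {
  L <- max(lev, na.rm = TRUE)
  counts <- matrix(0, L, L)
  nr <- nrow(lev); nc <- ncol(lev)
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(lev[r, c])) next
    for (o in offs) for (sgn in c(1, -1)) {
      r2 <- r + sgn * o[1]; c2 <- c + sgn * o[2]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc && !is.na(lev[r2, c2])) {
        counts[lev[r, c], lev[r2, c2]] <- counts[lev[r, c], lev[r2, c2]] + 1
      }
    }
  }
  counts
}

# GLRLM by walking every scan line of every direction pixel by pixel
oracle_glrlm <- function(lev) {
  L <- max(lev, na.rm = TRUE)
  runs <- list()
  nr <- nrow(lev); nc <- ncol(lev)
  walk <- function(cells) {
    vals <- apply(cells, 1, function(rc) lev[rc[1], rc[2]])
    cur <- NA; len <- 0
    for (v in c(vals, NA)) {
      if (!is.na(v) && !is.na(cur) && v == cur) {
        len <- len + 1
      } else {
        if (!is.na(cur)) runs[[length(runs) + 1]] <<- c(cur, len)
        cur <- v; len <- 1
      }
    }
  }
  for (r in seq_len(nr)) walk(cbind(r, seq_len(nc)))
  for (c in seq_len(nc)) walk(cbind(seq_len(nr), c))
  for (d in (1 - nc):(nr - 1)) {   # main diagonals: r - c = d
    cells <- cbind(seq_len(nr), seq_len(nr) - d)
    cells <- cells[cells[, 2] >= 1 & cells[, 2] <= nc, , drop = FALSE]
    if (nrow(cells)) walk(cells)
  }
  for (d in 2:(nr + nc)) {         # anti-diagonals: r + c = d
    cells <- cbind(seq_len(nr), d - seq_len(nr))
    cells <- cells[cells[, 2] >= 1 & cells[, 2] <= nc, , drop = FALSE]
    if (nrow(cells)) walk(cells)
  }
  if (!length(runs)) return(matrix(0, L, 1))
  rl <- do.call(rbind, runs)
  counts <- matrix(0, L, max(rl[, 2]))
  for (i in seq_len(nrow(rl))) {
    counts[rl[i, 1], rl[i, 2]] <- counts[rl[i, 1], rl[i, 2]] + 1
  }
  counts
}

# GLSZM by repeated seed-fill over equal-level 8-neighbours
oracle_glszm <- function(lev) {
  L <- max(lev, na.rm = TRUE)
  seen <- is.na(lev)
  zones <- list()
  nr <- nrow(lev); nc <- ncol(lev)
  while (any(!seen)) {
    start <- which(!seen, arr.ind = TRUE)[1, ]
    val <- lev[start[1], start[2]]
    stack <- list(start)
    seen[start[1], start[2]] <- TRUE
    size <- 0
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- p[1] + dr; c2 <- p[2] + dc
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            !seen[r2, c2] && lev[r2, c2] == val) {
          seen[r2, c2] <- TRUE
          stack[[length(stack) + 1]] <- c(r2, c2)
        }
      }
    }
    zones[[length(zones) + 1]] <- c(val, size)
  }
  zs <- do.call(rbind, zones)
  counts <- matrix(0, L, max(zs[, 2]))
  for (i in seq_len(nrow(zs))) {
    counts[zs[i, 1], zs[i, 2]] <- counts[zs[i, 1], zs[i, 2]] + 1
  }
  counts
}

# NGTDM s_i by direct per-pixel neighbourhood enumeration
oracle_ngtdm_s <- function(lev) {
  L <- max(lev, na.rm = TRUE)
  s <- numeric(L)
  nr <- nrow(lev); nc <- ncol(lev)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(lev[r, c])) next
    nbr <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc && !is.na(lev[r2, c2])) {
        nbr <- c(nbr, lev[r2, c2])
      }
    }
    if (length(nbr)) s[lev[r, c]] <- s[lev[r, c]] + abs(lev[r, c] - mean(nbr))
  }
  s
}

# ICC(A,k) via stats::aov two-way ANOVA mean squares (independent route)
oracle_icc_aov <- function(x, y) {
  n <- length(x)
  d <- data.frame(y = c(x, y),
                  subj = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (msc - mse) / n)
}

# geodesic diameter by Floyd-Warshall over the 8-connected pixel graph
oracle_geodesic <- function(mask, sr = 1, sc = 1) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dr <- abs(idx[i, 1] - idx[j, 1]); dc <- abs(idx[i, 2] - idx[j, 2])
    if (dr <= 1 && dc <= 1 && (dr + dc) > 0) {
      D[i, j] <- sqrt((dr * sr)^2 + (dc * sc)^2)
    }
  }
  for (k in seq_len(n)) for (i in seq_len(n)) {
    D[i, ] <- pmin(D[i, ], D[i, k] + D[k, ])
  }
  # restrict to boundary pixels (4-neighbour definition, border counts)
  onb <- apply(idx, 1, function(rc) {
    any(vapply(list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1)), function(o) {
      r2 <- rc[1] + o[1]; c2 <- rc[2] + o[2]
      r2 < 1 || r2 > nrow(mask) || c2 < 1 || c2 > ncol(mask) || !mask[r2, c2]
    }, TRUE))
  })
  max(D[onb, onb][is.finite(D[onb, onb])])
}

level_matrix_of <- function(vals, mask, bin_width = 20) {
  lev <- matrix(NA_integer_, nrow(mask), ncol(mask))
  lev[mask] <- discretize(vals[mask], bin_width)$levels
  lev
}
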