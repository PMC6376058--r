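#' Spearman correlation matrix of feature columns
#'
#' Rank correlation (average ranks for ties) between every pair of items.
#' Constant columns have undefined rank correlation; their off-diagonal
#' entries are flagged `NA` and such items are later isolated as singleton
#' clusters.
#'
#' @param feature_data numeric matrix or data frame, one column per item,
#'   one row per observation (>= 2 columns).
#' @return Symmetric numeric matrix in `[-1, 1]` with unit diagonal.
#' @export
spearman_matrix <- function(feature_data) {
  m <- as.matrix(feature_data)
  if (ncol(m) < 2L) abort("spearman_matrix: need at least 2 items")
  rho <- suppressWarnings(cor(m, method = "spearman"))
  diag(rho) <- 1
  rho
}

#' Cluster features by Spearman-correlation redundancy
#'
#' Agglomerative hierarchical clustering with distance `d = 1 - rho` and
#' complete linkage, cut so that two items share a cluster only when every
#' within-cluster pair has `rho > cutoff` (complete linkage makes this
#' guarantee exact). Items are put in canonical (lexicographic) order
#' before clustering, so the result is invariant to input order; at equal
#' merge heights the smallest item pair merges first. Items with undefined
#' correlations (constant columns) become singletons.
#'
#' @param rho correlation matrix from [spearman_matrix()], or a feature
#'   data matrix (converted automatically).
#' @param cutoff redundancy cutoff on the Spearman correlation (default
#'   0.9): pairs with `rho > cutoff` are considered redundant.
#' @param absolute if `TRUE`, cluster on `|rho|` so that strongly
#'   anti-correlated features also merge. Default `FALSE` (signed).
#' @return An object of class `radstab_clusters`: list with `items`,
#'   `assignment` (named integer), `n_clusters`, `cutoff`, `absolute`,
#'   `linkage`, and the `hclust` tree (`NULL` for < 2 items).
#' @export
cluster_features <- function(rho, cutoff = 0.9, absolute = FALSE) {
  if (is.data.frame(rho) || (!isSymmetric(unname(as.matrix(rho))) ||
                             is.null(colnames(rho)))) {
    rho <- spearman_matrix(rho)
  }
  items <- colnames(rho)
  if (is.null(items)) items <- paste0("item", seq_len(ncol(rho)))
  n <- length(items)
  if (n == 0L) {
    return(.new_clusters(character(0), integer(0), cutoff, absolute, NULL))
  }
  if (n == 1L) {
    return(.new_clusters(items, setNames(1L, items), cutoff, absolute, NULL))
  }
  ord <- order(items)
  rho <- rho[ord, ord, drop = FALSE]
  items <- items[ord]
  r <- if (absolute) abs(rho) else rho
  d <- 1 - r
  d[is.na(d)] <- 2        # undefined correlation: farther than any cut
  diag(d) <- 0
  tree <- hclust(as.dist(d), method = "complete")
  # cut strictly below 1 - cutoff: ties at rho == cutoff are not redundant
  assign <- cutree(tree, h = (1 - cutoff) - 1e-9)
  names(assign) <- items
  .new_clusters(items, assign, cutoff, absolute, tree)
}

.new_clusters <- function(items, assignment, cutoff, absolute, tree) {
  structure(list(items = items, assignment = assignment,
                 n_clusters = if (length(assignment)) max(assignment) else 0L,
                 cutoff = cutoff, absolute = absolute,
                 linkage = "complete", tree = tree),
            class = "radstab_clusters")
}

#' @export
print.radstab_clusters <- function(x, ...) {
  cat(sprintf("<radstab_clusters: %d item(s) in %d cluster(s), rho cutoff %.3g%s>\n",
              length(x$items), x$n_clusters, x$cutoff,
              if (x$absolute) " (absolute)" else ""))
  invisible(x)
}

#' Tidy a redundancy clustering
#'
#' @param x a `radstab_clusters` object.
#' @param ... unused.
#' @return A tibble with columns `item`, `cluster` and, when items are
#'   pooled `(sequence, feature)` pairs, `sequence` and `feature`.
#' @method tidy radstab_clusters
#' @export
tidy.radstab_clusters <- function(x, ...) {
  out <- tibble::tibble(item = x$items,
                        cluster = unname(x$assignment[x$items]))
  if (all(grepl("::", out$item, fixed = TRUE))) {
    parts <- strsplit(out$item, "::", fixed = TRUE)
    out$sequence <- vapply(parts, `[`, "", 1L)
    out$feature <- vapply(parts, `[`, "", 2L)
  }
  out
}

#' @rdname tidy.radstab_clusters
#' @method glance radstab_clusters
#' @export
glance.radstab_clusters <- function(x, ...) {
  tibble::tibble(n_items = length(x$items), n_clusters = x$n_clusters,
                 cutoff = x$cutoff, absolute = x$absolute,
                 linkage = x$linkage)
}

#' Dendrogram plot of a redundancy clustering
#'
#' Draws the complete-linkage dendrogram on the `1 - rho` distance scale
#' with the cut height marked.
#'
#' @param object a `radstab_clusters` object (with >= 2 items).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot radstab_clusters
#' @export
autoplot.radstab_clusters <- function(object, ...) {
  if (is.null(object$tree)) {
    abort("autoplot.radstab_clusters: need at least 2 items to draw a dendrogram")
  }
  seg <- .dendro_segments(object$tree)
  labs <- tibble::tibble(x = seq_along(object$tree$order),
                         label = object$tree$labels[object$tree$order])
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend)) +
    ggplot2::geom_hline(yintercept = 1 - object$cutoff,
                        linetype = "dashed", colour = "red") +
    ggplot2::scale_x_continuous(breaks = labs$x, labels = labs$label) +
    ggplot2::labs(x = NULL, y = "1 - Spearman rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1, vjust = 0.5))
}

# segment coordinates of an hclust tree (leaves at heights 0)
.dendro_segments <- function(tree) {
  n <- length(tree$order)
  leaf_x <- numeric(n)
  leaf_x[tree$order] <- seq_len(n)
  node_x <- numeric(nrow(tree$merge))
  node_h <- tree$height
  segs <- vector("list", nrow(tree$merge))
  pos <- function(id) if (id < 0) leaf_x[-id] else node_x[id]
  hgt <- function(id) if (id < 0) 0 else node_h[id]
  for (m in seq_len(nrow(tree$merge))) {
    a <- tree$merge[m, 1]; b <- tree$merge[m, 2]
    xa <- pos(a); xb <- pos(b)
    node_x[m] <- (xa + xb) / 2
    segs[[m]] <- tibble::tibble(
      x = c(xa, xb, xa), y = c(hgt(a), hgt(b), node_h[m]),
      xend = c(xa, xb, xb), yend = c(node_h[m], node_h[m], node_h[m]))
  }
  dplyr::bind_rows(segs)
}

#' Per-sequence redundancy clustering of reproducible features
#'
#' For each sequence, clusters the features flagged reproducible using the
#' feature values of a single reference reading (default `L1`, so reader
#' variance does not leak into the redundancy structure).
#'
#' @param repro_records output of [select_reproducible()].
#' @param feature_table the long feature table the records came from.
#' @param cutoff Spearman redundancy cutoff.
#' @param reading reference reading supplying the observation vectors.
#' @param absolute cluster on `|rho|` instead of signed `rho`.
#' @return A named list of `radstab_clusters`, one per sequence (sequences
#'   with no reproducible feature get an empty clustering).
#' @export
cluster_by_sequence <- function(repro_records, feature_table, cutoff = 0.9,
                                reading = "L1", absolute = FALSE) {
  .check_feature_table(feature_table)
  seqs <- unique(repro_records$sequence)
  out <- purrr::map(seqs, function(sq) {
    feats <- repro_records$feature[repro_records$sequence == sq &
                                     repro_records$reproducible]
    m <- .reference_matrix(feature_table, sq, feats, reading)
    if (length(feats) < 2L) {
      return(.new_clusters(feats, setNames(seq_along(feats), feats),
                           cutoff, absolute, NULL))
    }
    cluster_features(spearman_matrix(m), cutoff, absolute)
  })
  setNames(out, seqs)
}

#' Pooled redundancy clustering across sequences
#'
#' Pools every reproducible (feature, sequence) pair into one clustering:
#' items are labelled `"<sequence>::<feature>"` and their observation
#' vectors are that feature's values on that sequence across all ROIs of
#' the reference reading. The tidy output reports which sequences co-occur
#' within clusters.
#'
#' @inheritParams cluster_by_sequence
#' @return A `radstab_clusters` object over the pooled items.
#' @export
pooled_cluster <- function(repro_records, feature_table, cutoff = 0.9,
                           reading = "L1", absolute = FALSE) {
  .check_feature_table(feature_table)
  rep_items <- repro_records[repro_records$reproducible, , drop = FALSE]
  if (nrow(rep_items) == 0L) {
    return(.new_clusters(character(0), integer(0), cutoff, absolute, NULL))
  }
  cols <- purrr::map(seq_len(nrow(rep_items)), function(r) {
    .reference_matrix(feature_table, rep_items$sequence[r],
                      rep_items$feature[r], reading)[, 1]
  })
  m <- do.call(cbind, cols)
  colnames(m) <- paste0(rep_items$sequence, "::", rep_items$feature)
  if (ncol(m) == 1L) {
    return(.new_clusters(colnames(m), setNames(1L, colnames(m)),
                         cutoff, absolute, NULL))
  }
  cluster_features(spearman_matrix(m), cutoff, absolute)
}

# feature columns of one sequence/reading, subjects in canonical order
.reference_matrix <- function(feature_table, sq, feats, reading) {
  d <- feature_table[feature_table$sequence == sq &
                       feature_table$reading == reading, , drop = FALSE]
  d <- d[order(d$patient_id, d$side), , drop = FALSE]
  as.matrix(d[, feats, drop = FALSE])
}

#' Sequence co-occurrence within pooled clusters
#'
#' Counts, for every unordered pair of sequences, how many pooled clusters
#' contain items from both — the basis for statements about sequence pairs
#' that always or never share redundancy clusters.
#'
#' @param clusters a pooled `radstab_clusters` (items `sequence::feature`).
#' @return A tibble with `sequence_a`, `sequence_b`, `n_shared_clusters`.
#' @export
sequence_cooccurrence <- function(clusters) {
  td <- tidy(clusters)
  if (!"sequence" %in% names(td)) {
    abort("sequence_cooccurrence: clusters are not pooled (sequence, feature) items")
  }
  seqs <- sort(unique(td$sequence))
  pairs <- utils::combn(seqs, 2L)
  res <- purrr::map(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    shared <- intersect(td$cluster[td$sequence == a],
                        td$cluster[td$sequence == b])
    tibble::tibble(sequence_a = a, sequence_b = b,
                   n_shared_clusters = length(shared))
  })
  dplyr::bind_rows(res)
}
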