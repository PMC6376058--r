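#' Subset-overlap summary of reproducible features across sequences
#'
#' Partitions the features reproducible in at least one sequence by the
#' exact subset of sequences in which each is reproducible (UpSet
#' semantics: a feature reproducible on all six sequences contributes only
#' to the full-subset cell), split by feature family. Marginal per-sequence
#' counts and the total are attached as attributes, and satisfy the
#' conservation laws: subset counts sum to the total, and a sequence's
#' marginal is the sum over subsets containing it.
#'
#' @param repro_records output of [select_reproducible()].
#' @return A tibble with `subset` (sequence names joined by `+`, in
#'   [sequence_labels()] order), `n_sequences`, `family`, `n_features`;
#'   attributes `marginals` (named integer per sequence) and `total`.
#' @export
overlap_summary <- function(repro_records) {
  rr <- repro_records[repro_records$reproducible, , drop = FALSE]
  seq_order <- intersect(sequence_labels(), unique(repro_records$sequence))
  if (nrow(rr) == 0L) {
    out <- tibble::tibble(subset = character(0), n_sequences = integer(0),
                          family = character(0), n_features = integer(0))
    attr(out, "marginals") <- setNames(integer(length(seq_order)), seq_order)
    attr(out, "total") <- 0L
    return(out)
  }
  per_feature <- rr |>
    dplyr::group_by(.data$feature, .data$family) |>
    dplyr::summarise(
      subset = paste(intersect(seq_order, .data$sequence), collapse = "+"),
      n_sequences = dplyr::n_distinct(.data$sequence), .groups = "drop")
  out <- per_feature |>
    dplyr::count(.data$subset, .data$n_sequences, .data$family,
                 name = "n_features") |>
    dplyr::arrange(dplyr::desc(.data$n_sequences), .data$subset, .data$family)
  marg <- vapply(seq_order, function(sq) {
    length(unique(rr$feature[rr$sequence == sq]))
  }, integer(1))
  attr(out, "marginals") <- marg
  attr(out, "total") <- length(unique(rr$feature))
  out
}

#' ICC/CCC threshold sensitivity sweep
#'
#' Computes the per-(feature, sequence) ICC and CCC statistics once, then
#' counts, for every grid cell `(icc_threshold, ccc_threshold)` and every
#' sequence, the number of reproducible features and the number of
#' redundancy clusters they form (same clustering configuration as the
#' main analysis, per-sequence Spearman matrices computed once). Both
#' counts are non-increasing in each threshold with the other held fixed.
#'
#' @param feature_table long feature table from [extract_features()].
#' @param icc_values,ccc_values threshold grids.
#' @param spearman_cutoff redundancy cutoff used for cluster counting.
#' @param reading reference reading for the redundancy correlations.
#' @return A tibble with `sequence`, `icc_threshold`, `ccc_threshold`,
#'   `n_reproducible`, `n_clusters`.
#' @export
threshold_sweep <- function(feature_table,
                            icc_values = c(0.5, 0.6, 0.7, 0.8, 0.9),
                            ccc_values = seq(0.5, 0.95, by = 0.05),
                            spearman_cutoff = 0.9,
                            reading = "L1") {
  stats_tbl <- select_reproducible(feature_table, icc_threshold = 0,
                                   ccc_threshold = 0)
  stats_tbl$icc_min <- pmin(stats_tbl$icc_L1_L21, stats_tbl$icc_L1_L22,
                            stats_tbl$icc_L21_L22)
  seqs <- unique(stats_tbl$sequence)
  # per-sequence Spearman matrix over all features, computed once
  rho_by_seq <- setNames(purrr::map(seqs, function(sq) {
    m <- .reference_matrix(feature_table, sq, feature_schema()$feature,
                           reading)
    spearman_matrix(m)
  }), seqs)
  grid <- tidyr::expand_grid(sequence = seqs, icc_threshold = icc_values,
                             ccc_threshold = ccc_values)
  res <- purrr::pmap(grid, function(sequence, icc_threshold, ccc_threshold) {
    st <- stats_tbl[stats_tbl$sequence == sequence, , drop = FALSE]
    sel <- !is.na(st$icc_min) & !is.na(st$ccc_L21_L22) &
      st$icc_min >= icc_threshold & st$ccc_L21_L22 >= ccc_threshold
    feats <- st$feature[sel]
    ncl <- if (length(feats) < 2L) {
      length(feats)
    } else {
      rho <- rho_by_seq[[sequence]][feats, feats]
      cluster_features(rho, spearman_cutoff)$n_clusters
    }
    tibble::tibble(sequence = sequence, icc_threshold = icc_threshold,
                   ccc_threshold = ccc_threshold,
                   n_reproducible = length(feats), n_clusters = ncl)
  })
  dplyr::bind_rows(res)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Orchestrates simulate -> extract -> select -> cluster -> overlap ->
#' sweep and writes all artifacts to `out_dir`: `features.csv`,
#' `repro.csv`, `clusters.csv` (per-sequence assignments),
#' `pooled_clusters.csv`, `overlap.csv`, `sweep.csv` and
#' `provenance.json`. Deterministic (byte-identical CSV payloads) given
#' the seed in the configuration.
#'
#' @param config a [run_config()].
#' @param out_dir artifacts directory (created if needed).
#' @param sweep_icc,sweep_ccc threshold grids forwarded to
#'   [threshold_sweep()].
#' @return Invisibly, a list with the in-memory results
#'   (`cohort`, `features`, `repro`, `clusters`, `pooled`, `overlap`,
#'   `sweep`) and `paths`.
#' @export
run_pipeline <- function(config = run_config(), out_dir,
                         sweep_icc = c(0.5, 0.6, 0.7, 0.8, 0.9),
                         sweep_ccc = seq(0.5, 0.95, by = 0.05)) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  cohort <- stage("simulate", generate_cohort(config$cohort))
  features <- stage("extract", extract_features(cohort, config))
  message(sprintf("extract: %d ROIs x %d features x %d readings",
                  nrow(features) / 3L, nrow(feature_schema()), 3L))
  repro <- stage("select", select_reproducible(
    features, config$icc_threshold, config$ccc_threshold))
  message(sprintf("select: %d of %d (feature, sequence) pairs reproducible; %d feature(s) in at least one sequence",
                  sum(repro$reproducible), nrow(repro),
                  length(unique(repro$feature[repro$reproducible]))))
  clusters <- stage("cluster", cluster_by_sequence(
    repro, features, config$spearman_cutoff))
  pooled <- stage("cluster", pooled_cluster(
    repro, features, config$spearman_cutoff))
  message(sprintf("cluster: per-sequence clusters %s; pooled %d items in %d clusters",
                  paste(vapply(clusters, function(x) x$n_clusters, 0L),
                        collapse = "/"),
                  length(pooled$items), pooled$n_clusters))
  overlap <- stage("report", overlap_summary(repro))
  sweep <- stage("sweep", threshold_sweep(
    features, icc_values = sweep_icc, ccc_values = sweep_ccc,
    spearman_cutoff = config$spearman_cutoff))

  paths <- list(
    features = file.path(out_dir, "features.csv"),
    repro = file.path(out_dir, "repro.csv"),
    clusters = file.path(out_dir, "clusters.csv"),
    pooled = file.path(out_dir, "pooled_clusters.csv"),
    overlap = file.path(out_dir, "overlap.csv"),
    sweep = file.path(out_dir, "sweep.csv"),
    provenance = file.path(out_dir, "provenance.json"))
  write_feature_table(features, paths$features)
  readr::write_csv(repro, paths$repro)
  per_seq_tidy <- dplyr::bind_rows(purrr::imap(clusters, function(cl, sq) {
    td <- tidy(cl)
    if (nrow(td) == 0L) return(NULL)
    tibble::tibble(sequence = sq, feature = td$item, cluster = td$cluster)
  }))
  readr::write_csv(per_seq_tidy, paths$clusters)
  readr::write_csv(tidy(pooled), paths$pooled)
  readr::write_csv(out_strip_attrs(overlap), paths$overlap)
  readr::write_csv(sweep, paths$sweep)
  prov <- list(
    config = unclass_deep(config),
    counts = list(
      n_cases = length(cohort),
      n_rows = nrow(features),
      n_reproducible_pairs = sum(repro$reproducible),
      n_clusters_per_sequence = lapply(clusters, function(x) x$n_clusters),
      n_pooled_items = length(pooled$items),
      n_pooled_clusters = pooled$n_clusters),
    versions = list(radstab = as.character(utils::packageVersion("radstab")),
                    r = paste(R.version$major, R.version$minor, sep = ".")))
  jsonlite::write_json(prov, paths$provenance, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort, features = features, repro = repro,
                 clusters = clusters, pooled = pooled, overlap = overlap,
                 sweep = sweep, paths = paths))
}

out_strip_attrs <- function(x) {
  attr(x, "marginals") <- NULL
  attr(x, "total") <- NULL
  x
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}
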