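test_that("Spearman matrix matches hand rank computation", {
  m <- cbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4))
  rho <- spearman_matrix(m)
  expect_equal(rho["a", "b"], 0.8)
  expect_equal(diag(rho), c(a = 1, b = 1))
  # rank correlation is invariant under monotone transforms
  x <- runif(20)
  rho2 <- spearman_matrix(cbind(x = x, ex = exp(x)))
  expect_equal(rho2["x", "ex"], 1)
  # constant column flagged missing off-diagonal
  rho3 <- spearman_matrix(cbind(x = x, k = rep(1, 20)))
  expect_true(is.na(rho3["x", "k"]))
})

test_that("clustering groups monotone copies and isolates the rest", {
  set.seed(21)
  f <- rnorm(30)
  g <- sample(f)  # same values, rank-independent ordering
  m <- cbind(f = f, f2 = 2 * f + 1, g = g)
  cl <- cluster_features(spearman_matrix(m), cutoff = 0.9)
  td <- tidy(cl)
  expect_equal(cl$n_clusters, 2L)
  expect_equal(td$cluster[td$item == "f"], td$cluster[td$item == "f2"])
  expect_false(td$cluster[td$item == "g"] == td$cluster[td$item == "f"])

  # all pairwise below the cutoff: every item is its own cluster
  set.seed(22)
  m2 <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, letters[1:4]))
  expect_equal(cluster_features(spearman_matrix(m2), 0.9)$n_clusters, 4L)

  # a duplicated column always merges at height 0
  m3 <- cbind(a = f, b = f, c = g)
  td3 <- tidy(cluster_features(spearman_matrix(m3), 0.999))
  expect_equal(td3$cluster[td3$item == "a"], td3$cluster[td3$item == "b"])

  # constant column becomes a singleton cluster
  m4 <- cbind(a = f, b = 2 * f, k = rep(3, 30))
  td4 <- tidy(cluster_features(spearman_matrix(m4), 0.9))
  expect_equal(sum(td4$cluster == td4$cluster[td4$item == "k"]), 1L)
})

test_that("within-cluster pairwise correlation always exceeds the cutoff", {
  set.seed(23)
  for (i in 1:10) {
    n_items <- sample(5:12, 1)
    base <- matrix(rnorm(40 * 3), 40, 3)
    m <- sapply(seq_len(n_items), function(j) {
      base[, sample(3, 1)] + rnorm(40, sd = runif(1, 0.05, 2))
    })
    colnames(m) <- paste0("v", seq_len(n_items))
    rho <- spearman_matrix(m)
    cl <- cluster_features(rho, cutoff = 0.9)
    for (k in seq_len(cl$n_clusters)) {
      members <- names(cl$assignment)[cl$assignment == k]
      if (length(members) > 1) {
        sub <- rho[members, members]
        expect_true(all(sub[upper.tri(sub)] > 0.9))
      }
    }
  }
})

test_that("clustering is invariant to item order and monotone in cutoff", {
  set.seed(24)
  base <- rnorm(40)
  m <- cbind(a = base + rnorm(40, sd = 0.1), b = base + rnorm(40, sd = 0.1),
             c = rnorm(40), d = base + rnorm(40, sd = 1.5),
             e = rnorm(40))
  rho <- spearman_matrix(m)
  cl1 <- cluster_features(rho, 0.9)
  perm <- c("d", "b", "e", "a", "c")
  cl2 <- cluster_features(rho[perm, perm], 0.9)
  expect_identical(cl1$assignment, cl2$assignment)

  counts <- sapply(c(0.99, 0.9, 0.7, 0.5, 0.2),
                   function(ct) cluster_features(rho, ct)$n_clusters)
  expect_true(all(diff(counts) <= 0))
})

test_that("absolute mode merges anti-correlated items, signed mode does not", {
  set.seed(25)
  x <- rnorm(30)
  m <- cbind(a = x, b = -x + rnorm(30, sd = 0.01))
  rho <- spearman_matrix(m)
  expect_equal(cluster_features(rho, 0.9, absolute = FALSE)$n_clusters, 2L)
  expect_equal(cluster_features(rho, 0.9, absolute = TRUE)$n_clusters, 1L)
})

test_that("pooled clustering co-clusters duplicated sequences", {
  sp <- tiny_cohort_spec(n_patients = 3, seed = 401,
                         inter_reader_perturb = 0, intra_reader_perturb = 0,
                         inter_reader_shift = 0, intra_reader_shift = 0)
  ft <- extract_features(generate_cohort(sp), run_config(cohort = sp))
  # make wDIXON_T2 a verbatim copy of ipDIXON_T2: each feature's two
  # sequence-copies must co-cluster at distance zero
  copy <- ft[ft$sequence == "ipDIXON_T2", ]
  copy$sequence <- "wDIXON_T2"
  ft2 <- dplyr::bind_rows(ft[ft$sequence != "wDIXON_T2", ], copy)
  rr <- select_reproducible(ft2)
  pc <- pooled_cluster(rr, ft2, cutoff = 0.9)
  td <- tidy(pc)
  ip <- td[td$sequence == "ipDIXON_T2", ]
  w <- td[td$sequence == "wDIXON_T2", ]
  shared <- intersect(ip$feature, w$feature)
  expect_gt(length(shared), 0)
  for (f in shared) {
    expect_equal(ip$cluster[ip$feature == f], w$cluster[w$feature == f])
  }
  co <- sequence_cooccurrence(pc)
  row <- co[co$sequence_a == "ipDIXON_T2" & co$sequence_b == "wDIXON_T2", ]
  expect_gt(row$n_shared_clusters, 0)
})

test_that("independent sequence textures rarely co-cluster across sequences", {
  sp <- tiny_cohort_spec(n_patients = 5, seed = 402, texture_share = 0,
                         inter_reader_perturb = 0, intra_reader_perturb = 0,
                         inter_reader_shift = 0, intra_reader_shift = 0)
  ft <- extract_features(generate_cohort(sp), run_config(cohort = sp))
  rr <- select_reproducible(ft)
  pc <- pooled_cluster(rr, ft, cutoff = 0.9)
  td <- tidy(pc)
  tex <- td[grepl("^(glcm|glrlm|glszm|ngtdm)_", td$feature), ]
  # cross-sequence texture pairs in one cluster are rare by construction:
  # textures are independent fields, only the masks are shared
  cross <- 0; total <- 0
  for (k in unique(tex$cluster)) {
    seqs <- tex$sequence[tex$cluster == k]
    total <- total + 1
    if (length(unique(seqs)) > 1) cross <- cross + 1
  }
  expect_lt(cross / total, 0.25)
})

test_that("tidiers summarise cluster objects", {
  set.seed(26)
  m <- cbind(a = rnorm(20), b = rnorm(20))
  cl <- cluster_features(spearman_matrix(m), 0.9)
  g <- glance(cl)
  expect_identical(g$n_items, 2L)
  expect_identical(g$linkage, "complete")
  expect_s3_class(autoplot(cl), "ggplot")
  # single item: one cluster, no tree
  one <- cluster_features(matrix(1, 1, 1, dimnames = list("x", "x")), 0.9)
  expect_equal(one$n_clusters, 1L)
})
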