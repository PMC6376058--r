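# Texture matrices against exhaustive enumeration oracles, plus the
# closed-form degenerate cases.

test_that("GLCM of a 2x2 checkerboard matches pair enumeration", {
  lev <- matrix(c(1L, 2L, 2L, 1L), 2, 2)
  mask <- matrix(TRUE, 2, 2)
  d <- discretize(c(0, 25, 25, 0))   # levels 1,2,2,1 column-major
  tm <- build_glcm(d, mask)
  expect_equal(tm$counts, oracle_glcm(lev))
  # 0/90 degrees give only (1,2)/(2,1); 45/135 give (1,1) and (2,2)
  expect_gt(tm$counts[1, 2], 0)
  expect_gt(tm$counts[1, 1], 0)
  expect_equal(tm$counts, t(tm$counts))
  expect_equal(sum(tm$p), 1)

  f <- glcm_features(tm)
  P <- tm$p; i <- row(P); j <- col(P)
  expect_equal(f[["glcm_contrast"]], sum(P * (i - j)^2))
  expect_equal(f[["glcm_dissimilarity"]], sum(P * abs(i - j)))
})

test_that("constant ROI collapses the GLCM to one cell", {
  d <- discretize(rep(30, 9))
  tm <- build_glcm(d, matrix(TRUE, 3, 3))
  f <- glcm_features(tm)
  expect_equal(f[["glcm_joint_energy"]], 1)
  expect_equal(f[["glcm_joint_entropy"]], 0)
  expect_equal(f[["glcm_contrast"]], 0)
  expect_equal(f[["glcm_maximum_probability"]], 1)
  # single grey level: correlation undefined, flagged missing
  expect_true(is.na(f[["glcm_correlation1"]]))
})

test_that("texture matrices match enumeration oracles on random small ROIs", {
  set.seed(77)
  for (i in 1:25) {
    nr <- sample(2:6, 1); nc <- sample(2:6, 1)
    mask <- matrix(runif(nr * nc) < 0.8, nr, nc)
    if (!any(mask)) mask[1, 1] <- TRUE
    vals <- matrix(runif(nr * nc, 0, 100), nr, nc)
    lev <- level_matrix_of(vals, mask)
    d <- discretize(vals[mask])
    expect_equal(build_glcm(d, mask)$counts, oracle_glcm(lev))
    expect_equal(build_glrlm(d, mask)$counts, oracle_glrlm(lev))
    expect_equal(build_glszm(d, mask)$counts, oracle_glszm(lev))
    s_oracle <- oracle_ngtdm_s(lev)
    tm <- radstab:::build_ngtdm(d, mask)
    expect_equal(tm$s_i, s_oracle, tolerance = 1e-12)
  }
})

test_that("normalized texture matrices sum to one and GLCM is symmetric", {
  set.seed(88)
  for (i in 1:10) {
    mask <- random_blob(8, 8, 20)
    vals <- matrix(runif(64, 0, 120), 8, 8)
    d <- discretize(vals[mask])
    g <- build_glcm(d, mask)
    expect_equal(sum(g$p), 1)
    expect_equal(g$p, t(g$p))
    expect_equal(sum(build_glrlm(d, mask)$p), 1)
    expect_equal(sum(build_glszm(d, mask)$p), 1)
  }
})

test_that("run-length features behave on canonical run patterns", {
  # 1x4 constant line: horizontal run of 4, vertical/diagonal runs of 1
  mask <- matrix(TRUE, 1, 4)
  d <- discretize(rep(10, 4))
  tm <- build_glrlm(d, mask)
  expect_equal(tm$counts[1, 4], 1)   # one run of length 4
  expect_equal(tm$counts[1, 1], 12)  # 4 vertical + 8 diagonal singletons
  f <- glrlm_features(tm)
  expect_lt(f[["glrlm_rp"]], 1)

  # all-distinct levels: every run has length 1 in every direction
  vals <- matrix(20 * (0:8), 3, 3)
  mask3 <- matrix(TRUE, 3, 3)
  f2 <- glrlm_features(build_glrlm(discretize(vals[mask3]), mask3))
  expect_equal(f2[["glrlm_sre"]], 1)
  expect_equal(f2[["glrlm_lre"]], 1)
  expect_equal(f2[["glrlm_rp"]], 1)

  # constant N x N ROI: runs merge pixels
  dc <- discretize(rep(30, 16))
  fc <- glrlm_features(build_glrlm(dc, matrix(TRUE, 4, 4)))
  expect_lt(fc[["glrlm_rp"]], 1)
})

test_that("size-zone features behave on canonical zone patterns", {
  # constant N x N ROI: a single zone of size N^2
  n <- 4
  d <- discretize(rep(30, n^2))
  tm <- build_glszm(d, matrix(TRUE, n, n))
  f <- glszm_features(tm)
  expect_equal(f[["glszm_zp"]], 1 / n^2)
  expect_equal(f[["glszm_lae"]], n^4)

  # two disjoint same-level blobs of sizes 3 and 5 within the ROI
  vals <- matrix(100, 5, 5)            # background level 6
  vals[1, 1:3] <- 10                   # blob of 3 at level 1
  vals[c(21:25)] <- 10                 # column 5: blob of 5 at level 1
  mask <- matrix(TRUE, 5, 5)
  tm2 <- build_glszm(discretize(vals[mask]), mask)
  expect_equal(tm2$counts[1, 3], 1)
  expect_equal(tm2$counts[1, 5], 1)

  # all-distinct levels: every zone is a singleton (note a two-level
  # checkerboard would NOT give singletons under 8-connectivity, since
  # diagonal same-level pixels connect)
  vals3 <- matrix(20 * (0:15), 4, 4)
  mask3 <- matrix(TRUE, 4, 4)
  f3 <- glszm_features(build_glszm(discretize(vals3[mask3]), mask3))
  expect_equal(f3[["glszm_sae"]], 1)
  expect_equal(f3[["glszm_zp"]], 1)
})

test_that("NGTDM features follow the Amadasun-King forms", {
  # flat ROI: zero grey-tone differences, coarseness capped
  d <- discretize(rep(30, 9))
  f <- ngtdm_features(radstab:::build_ngtdm(d, matrix(TRUE, 3, 3)))
  expect_equal(f[["ngtdm_contrast"]], 0)
  expect_equal(f[["ngtdm_coarseness"]], 1e6)

  # single bright centre pixel in a 3x3 ROI: hand-enumerated s_i
  vals <- matrix(10, 3, 3); vals[2, 2] <- 90   # levels 1 and 5
  mask <- matrix(TRUE, 3, 3)
  lev <- level_matrix_of(vals, mask)
  tm <- radstab:::build_ngtdm(discretize(vals[mask]), mask)
  expect_equal(tm$s_i, oracle_ngtdm_s(lev), tolerance = 1e-12)
  # centre pixel: |5 - 1| = 4; each corner sees mean (2*1 + 2 + 5)/3 etc.
  expect_equal(tm$s_i[5], 4)

  # busyness and complexity are non-negative on fuzzed ROIs
  set.seed(99)
  for (i in 1:40) {
    mask <- random_blob(7, 7, sample(5:30, 1))
    vals <- matrix(runif(49, 0, 150), 7, 7)
    f <- ngtdm_features(radstab:::build_ngtdm(discretize(vals[mask]), mask))
    expect_gte(f[["ngtdm_busyness"]], 0)
    expect_gte(f[["ngtdm_complexity"]], 0)
  }
})

test_that("single-pixel ROI flags texture families as missing", {
  mask <- rect_mask(3, 3, 2, 2)
  d <- discretize(30)
  expect_true(all(is.na(glcm_features(build_glcm(d, mask)))))
  expect_true(all(is.na(ngtdm_features(radstab:::build_ngtdm(d, mask)))))
})
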