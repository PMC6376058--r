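test_that("a written case reads back bitwise for masks, exactly for pixels", {
  sp <- tiny_cohort_spec(n_patients = 1, glands_per_patient = 1, seed = 61)
  case <- generate_cohort(sp)[[1]]
  d <- withr::local_tempdir()
  write_case(case, d)
  for (sq in c("T1", "ADC")) {
    ip <- file.path(d, sprintf("P001_left_%s.nii.gz", sq))
    mp <- file.path(d, sprintf("P001_left_%s_mask_%s.nii.gz", sq,
                               c("L1", "L2.1", "L2.2")))
    rc <- read_case(ip, mp)
    expect_equal(rc$image$pixels, case$images[[sq]]$pixels)
    expect_equal(rc$image$spacing_mm, sp$spacing_mm)
    expect_identical(rc$image$sequence_label, sq)
    expect_identical(rc$image$patient_id, "P001")
    expect_identical(rc$image$side, "left")
    for (rd in reading_labels()) {
      expect_identical(rc$delineations[[rd]]$mask,
                       case$delineations[[sq]][[rd]]$mask)
    }
  }
})

test_that("the reader rejects malformed cases", {
  d <- withr::local_tempdir()
  img <- matrix(runif(36, 1, 9), 6, 6)
  radstab:::.write_slice(img, c(1, 1), file.path(d, "P9_left_T1.nii.gz"))
  radstab:::.write_slice(matrix(0, 6, 6), c(1, 1),
                         file.path(d, "P9_left_T1_mask_L1.nii.gz"))
  expect_error(read_case(file.path(d, "P9_left_T1.nii.gz"),
                         file.path(d, "P9_left_T1_mask_L1.nii.gz")),
               "empty mask")
  radstab:::.write_slice(matrix(1, 7, 7), c(1, 1),
                         file.path(d, "P9_left_T1_mask_L2.1.nii.gz"))
  expect_error(read_case(file.path(d, "P9_left_T1.nii.gz"),
                         file.path(d, "P9_left_T1_mask_L2.1.nii.gz")),
               "grid mismatch")
  m2 <- matrix(0, 6, 6); m2[1, 1] <- 1; m2[5, 5] <- 1  # two components
  radstab:::.write_slice(m2, c(1, 1),
                         file.path(d, "P9_left_T1_mask_L2.2.nii.gz"))
  expect_error(read_case(file.path(d, "P9_left_T1.nii.gz"),
                         file.path(d, "P9_left_T1_mask_L2.2.nii.gz")),
               "multiple components")
  expect_error(read_case(file.path(d, "whatever.nii.gz"), character(0)),
               "sequence label")
})

test_that("feature tables round-trip losslessly including NaN flags", {
  sp <- tiny_cohort_spec(n_patients = 1, glands_per_patient = 1, seed = 62)
  ft <- extract_features(generate_cohort(sp),
                         run_config(cohort = sp), readings = "L1")
  expect_equal(nrow(ft), 6L)
  expect_equal(ncol(ft), 89L)
  ft$glcm_imc1[2] <- NaN
  ft$fo_skewness[1] <- NA_real_
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ft, path)
  back <- read_feature_table(path)
  expect_equal(as.data.frame(back), as.data.frame(ft[, names(back)]),
               tolerance = 1e-15)
  expect_true(is.nan(back$glcm_imc1[2]))
  expect_true(is.na(back$fo_skewness[1]))
  expect_error(write_feature_table(ft[, -1], path), "key column")
})

test_that("run configurations survive a JSON round trip", {
  cfg <- run_config(bin_width = 25, icc_threshold = 0.7,
                    ccc_threshold = 0.85, spearman_cutoff = 0.8,
                    rng_seed = 9L,
                    cohort = cohort_spec(n_patients = 5, rng_seed = 9L))
  path <- withr::local_tempfile(fileext = ".json")
  write_run_config(cfg, path)
  cfg2 <- read_run_config(path)
  expect_equal(cfg2$bin_width, 25)
  expect_equal(cfg2$spearman_cutoff, 0.8)
  expect_equal(cfg2$cohort$n_patients, 5L)
  expect_equal(cfg2$cohort$contrast, cfg$cohort$contrast)
  expect_error(run_config(bin_width = -1), "bin_width")
  expect_error(run_config(icc_threshold = 1.2), "icc_threshold")
  expect_error(run_config(spearman_cutoff = 1), "spearman_cutoff")
})

test_that("a cohort manifest indexes every written file", {
  sp <- tiny_cohort_spec(n_patients = 1, seed = 63)
  ch <- generate_cohort(sp)
  d <- withr::local_tempdir()
  manifest <- write_cohort(ch, d)
  expect_equal(nrow(manifest), 2L * 6L * 3L)
  expect_true(all(file.exists(file.path(d, unique(manifest$image)))))
  expect_true(all(file.exists(file.path(d, manifest$mask))))
})
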