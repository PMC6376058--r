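test_that("the cohort realises the study design arithmetic", {
  sp <- tiny_cohort_spec(n_patients = 1, glands_per_patient = 1, seed = 51)
  ch <- generate_cohort(sp)
  expect_length(ch, 1L)
  case <- ch[[1]]
  expect_length(case$images, 6L)
  expect_setequal(names(case$images), sequence_labels())
  n_delins <- sum(vapply(case$delineations, length, 0L))
  expect_equal(n_delins, 18L)  # 6 sequences x 3 readings
  # DIXON pairs share delineations; T1/ADC are independent
  expect_identical(case$delineations$ipDIXON_T2$L1$mask,
                   case$delineations$wDIXON_T2$L1$mask)
  expect_identical(case$delineations$PC_ipDIXON_T1$L1$mask,
                   case$delineations$PC_wDIXON_T1$L1$mask)
})

test_that("cohort generation is bit-reproducible under a fixed seed", {
  sp <- tiny_cohort_spec(n_patients = 2, seed = 52)
  c1 <- generate_cohort(sp)
  c2 <- generate_cohort(sp)
  expect_identical(c1[[3]]$images$T1$pixels, c2[[3]]$images$T1$pixels)
  expect_identical(c1[[3]]$delineations$T1$`L2.1`$mask,
                   c2[[3]]$delineations$T1$`L2.1`$mask)
  c3 <- generate_cohort(tiny_cohort_spec(n_patients = 2, seed = 53))
  expect_false(identical(c1[[1]]$images$T1$pixels, c3[[1]]$images$T1$pixels))
})

test_that("every delineation overlaps the truth and is one component", {
  sp <- tiny_cohort_spec(n_patients = 2, seed = 54)
  for (case in generate_cohort(sp)) {
    for (sq in names(case$delineations)) {
      for (d in case$delineations[[sq]]) {
        expect_gt(sum(d$mask & case$truth_mask), 0)  # Dice > 0
      }
    }
  }
})

test_that("intra-reader boundary displacement is below inter-reader", {
  sp <- tiny_cohort_spec(n_patients = 6, seed = 55)
  ch <- generate_cohort(sp)
  dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
  inter <- c(); intra <- c()
  for (case in ch) {
    d <- case$delineations$T1
    inter <- c(inter, dice(d$L1$mask, d$`L2.1`$mask))
    intra <- c(intra, dice(d$`L2.1`$mask, d$`L2.2`$mask))
  }
  expect_gt(mean(intra), mean(inter))  # higher Dice = smaller displacement
})

test_that("mask perturbation is identity at zero and bounded at magnitude 2", {
  m <- matrix(FALSE, 40, 40)
  r <- matrix(seq_len(40), 40, 40); c <- t(r)
  m[((r - 20)/12)^2 + ((c - 20)/8)^2 <= 1] <- TRUE  # ~300 px ellipse
  expect_identical(perturb_mask(m, 0), m)

  set.seed(56)
  dices <- replicate(100, {
    p <- perturb_mask(m, 2)
    2 * sum(p & m) / (sum(p) + sum(m))
  })
  expect_true(all(dices > 0.6))
  expect_true(all(dices < 1 + 1e-12))
  expect_gt(mean(dices < 1), 0.9)  # almost always actually perturbed
})

test_that("expected area change grows monotonically with magnitude", {
  m <- matrix(FALSE, 48, 48)
  r <- matrix(seq_len(48), 48, 48); c <- t(r)
  m[((r - 24)/13)^2 + ((c - 24)/9)^2 <= 1] <- TRUE
  set.seed(57)
  mean_abs_change <- vapply(c(0.5, 1, 2, 4), function(mag) {
    mean(replicate(100, abs(sum(perturb_mask(m, mag)) - sum(m))))
  }, numeric(1))
  expect_true(all(diff(mean_abs_change) > 0))
})

test_that("perturbed masks stay single 8-connected components", {
  set.seed(58)
  m <- matrix(FALSE, 30, 30)
  m[8:22, 10:20] <- TRUE
  for (i in 1:25) {
    p <- perturb_mask(m, runif(1, 0.5, 4))
    expect_gte(sum(p), 1)
    expect_silent(delineation(p, "L1"))  # validates single component
  }
})

test_that("invalid specs are rejected", {
  expect_error(cohort_spec(n_patients = 0), "n_patients")
  expect_error(cohort_spec(inter_reader_perturb = 1,
                           intra_reader_perturb = 2), "intra")
  expect_error(cohort_spec(image_size = c(24L, 24L)), "fit")
  expect_error(perturb_mask(matrix(FALSE, 4, 4), 1), "empty")
})
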