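test_that("a filled square has the symmetric convex-case shape values", {
  m <- rect_mask(14, 14, 3:12, 3:12)
  s <- compute_shape(m, c(1, 1))
  expect_equal(s[["shape_surface_area"]], 100)
  expect_equal(s[["shape_solidity"]], 1)
  expect_equal(s[["shape_deficit"]], 0)
  expect_equal(s[["shape_extension"]], 1)
  expect_equal(s[["shape_elongation"]], 1)
  expect_equal(s[["shape_eccentricity"]], 0)
  expect_equal(s[["shape_perimeter"]], 40)
  expect_equal(s[["shape_perimeter_solidity"]], 1)
  # convex region: geodesic and Euclidean diameters coincide
  expect_equal(s[["shape_max_diameter"]], s[["shape_max_geodesic_diameter"]])
  expect_equal(s[["shape_max_diameter"]], 9 * sqrt(2))
})

test_that("a concave mask separates geodesic from Euclidean diameter", {
  m <- matrix(FALSE, 12, 12)
  m[2:10, 2:3] <- TRUE   # vertical arm
  m[9:10, 2:10] <- TRUE  # horizontal arm
  s <- compute_shape(m, c(1, 1))
  expect_gt(s[["shape_max_geodesic_diameter"]], s[["shape_max_diameter"]])
  expect_lt(s[["shape_solidity"]], 1)
  expect_equal(s[["shape_max_geodesic_diameter"]], oracle_geodesic(m),
               tolerance = 1e-12)
})

test_that("geodesic diameter matches the all-pairs oracle on random blobs", {
  set.seed(31)
  for (i in 1:8) {
    m <- random_blob(9, 9, 12 + i)
    s <- compute_shape(m, c(1, 1))
    expect_equal(s[["shape_max_geodesic_diameter"]], oracle_geodesic(m),
                 tolerance = 1e-12)
  }
})

test_that("shape features are translation-invariant and spacing-equivariant", {
  set.seed(17)
  m <- matrix(FALSE, 20, 20)
  m[5:12, 4:14] <- TRUE
  m[6:9, 12:16] <- TRUE
  base <- compute_shape(m, c(1, 1))
  shifted <- matrix(FALSE, 20, 20)
  shifted[(5:12) + 3, (4:14) + 2] <- TRUE
  shifted[(6:9) + 3, (12:16) + 2] <- TRUE
  expect_equal(compute_shape(shifted, c(1, 1)), base, tolerance = 1e-12)

  # isotropic spacing scale s: lengths scale by s, areas by s^2,
  # dimensionless ratios are unchanged
  s2 <- compute_shape(m, c(2, 2))
  lengths <- c("shape_major_axis_length", "shape_minor_axis_length",
               "shape_max_diameter", "shape_max_geodesic_diameter",
               "shape_perimeter")
  areas <- c("shape_surface_area", "shape_convex_area")
  ratios <- c("shape_solidity", "shape_deficit", "shape_elongation",
              "shape_eccentricity", "shape_extension",
              "shape_perimeter_solidity")
  expect_equal(s2[lengths], 2 * base[lengths], tolerance = 1e-12)
  expect_equal(s2[areas], 4 * base[areas], tolerance = 1e-12)
  expect_equal(s2[ratios], base[ratios], tolerance = 1e-12)
})

test_that("masks touching the image border warn but still compute", {
  m <- rect_mask(6, 6, 1:3, 1:3)
  expect_warning(s <- compute_shape(m, c(1, 1)), "border")
  expect_equal(s[["shape_surface_area"]], 9)
})
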