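# Morphology, intensity and histogram features.

test_that("single-voxel morphology follows the voxel-face oracle relations", {
  # voxel-face oracle: A = 6, V = 1 for a unit cube
  expect_equal(radvox:::sphericity_from_va(1, 6), (36 * pi)^(1 / 3) / 6,
               tolerance = 1e-12)
  expect_equal(radvox:::sphericity_from_va(1, 6), 0.80600, tolerance = 1e-4)
  arr <- array(FALSE, c(3, 3, 3)); arr[2, 2, 2] <- TRUE
  mf <- morphology_features(voi_mask(arr, c(1, 1, 1)))
  expect_equal(unname(mf["approx_volume"]), 1)            # count * voxel volume
  # the mesh's own V and A must be internally consistent
  expect_equal(unname(mf["compactness_2"]), unname(mf["sphericity"])^3,
               tolerance = 1e-10)
  expect_equal(unname(mf["compactness_1"]),
               unname(mf["volume"] / (sqrt(pi) * mf["surface_area"]^1.5)),
               tolerance = 1e-12)
  expect_equal(unname(mf["surface_to_volume_ratio"]),
               unname(mf["surface_area"] / mf["volume"]), tolerance = 1e-12)
  expect_equal(unname(mf["max_3d_diameter"]), 1)  # floored at voxel spacing
  expect_gt(mf["sphericity"], 0)
  expect_lte(mf["sphericity"], 1.001)
})

test_that("a digitized ball is recognized as nearly spherical", {
  m <- ball_mask(15)
  mf <- morphology_features(m)
  expect_gte(unname(mf["sphericity"]), 0.95)
  expect_lte(unname(mf["sphericity"]), 1.001)
  expect_equal(unname(mf["volume"]), 4 / 3 * pi * 15^3, tolerance = 0.03)
  expect_equal(unname(mf["approx_volume"]), sum(m$values))
  expect_equal(unname(mf["max_3d_diameter"]), 30, tolerance = 0.1)
})

test_that("morphology respects anisotropic voxel spacing", {
  m <- ball_mask(12, spacing = c(1, 1, 3))
  mf <- morphology_features(m)
  expect_equal(unname(mf["approx_volume"]), sum(m$values) * 3)
  expect_equal(unname(mf["volume"]), 4 / 3 * pi * 12^3, tolerance = 0.08)
  expect_equal(unname(mf["max_3d_diameter"]), 24, tolerance = 1.5)
})

test_that("intensity features match hand computations", {
  g <- volume_image(array(1:4, c(4, 1, 1)))
  m <- voi_mask(array(TRUE, c(4, 1, 1)))
  f <- intensity_features(g, m)
  expect_equal(unname(f["mean"]), 2.5)
  expect_equal(unname(f["range"]), 3)
  expect_equal(unname(f["skewness"]), 0)
  expect_equal(unname(f["variance"]), 1.25)  # population convention
  expect_equal(unname(f["median"]), 2.5)
  g2 <- volume_image(array(c(1, 2), c(2, 1, 1)))
  m2 <- voi_mask(array(TRUE, c(2, 1, 1)))
  expect_equal(unname(intensity_features(g2, m2)["energy"]), 5)
  gc <- volume_image(array(4.2, c(3, 1, 1)))
  mc <- voi_mask(array(TRUE, c(3, 1, 1)))
  fc <- intensity_features(gc, mc)
  expect_equal(unname(fc[c("variance", "skewness", "kurtosis")]), c(0, 0, 0))
})

test_that("intensity moments transform correctly under affine maps", {
  set.seed(11)
  vals <- rnorm(60)
  v <- volume_image(array(vals, c(60, 1, 1)))
  m <- voi_mask(array(TRUE, c(60, 1, 1)))
  f1 <- intensity_features(v, m)
  a <- 2.5; b <- -3
  f2 <- intensity_features(volume_image(array(a * vals + b, c(60, 1, 1))), m)
  expect_equal(unname(f2["mean"]), unname(a * f1["mean"] + b), tolerance = 1e-10)
  expect_equal(unname(f2["variance"]), unname(a^2 * f1["variance"]), tolerance = 1e-10)
  expect_true(f1["minimum"] <= f1["mean"] && f1["mean"] <= f1["maximum"])
})

test_that("histogram features on constructed level sets are exact", {
  q1 <- qvoi_from_array(array(1L, c(3, 3, 3)), 64)
  h1 <- histogram_features(q1)
  expect_equal(unname(h1["uniformity"]), 1)
  expect_equal(unname(h1["entropy"]), 0)
  lev <- array(0L, c(10, 1, 1))
  lev[1:5] <- 1L; lev[6:10] <- 64L
  h2 <- histogram_features(qvoi_from_array(lev, 64))
  expect_equal(unname(h2["entropy"]), 1)      # two equal bins = 1 bit
  expect_equal(unname(h2["uniformity"]), 0.5)
  # mode ties break to the smallest level: counts (5, 3, 5) at levels 1..3
  lev3 <- array(0L, c(13, 1, 1))
  lev3[1:13] <- c(rep(1L, 5), rep(2L, 3), rep(3L, 5))
  expect_equal(unname(histogram_features(qvoi_from_array(lev3, 64))["mode"]), 1)
})

test_that("histogram entropy is maximal iff all 64 levels are equally occupied", {
  lev <- array(rep(1:64, each = 2), c(128, 1, 1))
  h <- histogram_features(qvoi_from_array(lev, 64))
  expect_equal(unname(h["entropy"]), log2(64), tolerance = 1e-12)
  set.seed(5)
  lev2 <- array(sample(1:64, 128, replace = TRUE, prob = runif(64)^2), c(128, 1, 1))
  h2 <- histogram_features(qvoi_from_array(lev2, 64))
  expect_lt(unname(h2["entropy"]), log2(64))
})

test_that("histogram features require 64 bins", {
  q <- qvoi_from_array(array(1L, c(2, 2, 2)), 16)
  expect_error(histogram_features(q), "64")
})
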