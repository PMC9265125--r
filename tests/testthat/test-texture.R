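# Texture matrices and features: degenerate cases with hand-enumerated
# values, brute-force oracle equivalence and conservation laws.

test_that("registry counts and per-family feature counts are exact", {
  reg <- feature_registry()
  expect_equal(vapply(reg$families, length, 1L),
               c(MORPH = 8L, INT = 18L, HIST = 20L, GLCM = 11L,
                 GLRLM = 13L, GLSZM = 13L, NGLDM = 16L, NGTDM = 5L))
  expect_length(feature_names("GD"), 2438)
  expect_length(unique(feature_names("GD")), 2438)
})

test_that("constant VOI gives the single-entry GLCM conventions", {
  q <- qvoi_from_array(array(1L, c(3, 3, 3)), 8)
  mats <- texture_matrices(q)
  P <- mats$glcm_counts / sum(mats$glcm_counts)
  expect_equal(P[1, 1], 1)
  f <- glcm_features(q)
  expect_equal(unname(f["inverse_difference_moment"]), 1)
  expect_equal(unname(f["correlation"]), 0)   # zero-variance guard
  expect_equal(unname(f["contrast"]), 0)
})

test_that("a two-voxel VOI reproduces hand-enumerated GLCM and NGTDM", {
  lev <- array(0L, c(2, 1, 1)); lev[1] <- 1L; lev[2] <- 2L
  q <- qvoi_from_array(lev, 2)
  mats <- texture_matrices(q)
  P <- mats$glcm_counts / sum(mats$glcm_counts)
  expect_equal(P[1, 2], 0.5)
  expect_equal(P[2, 1], 0.5)
  expect_equal(unname(glcm_features(q)["contrast"]), 1)
  # NGTDM: s_1 = s_2 = |1 - 2| = 1
  expect_equal(as.numeric(mats$ngtdm_s[1:2]), c(1, 1))
})

test_that("GLRLM runs on a 1x1x4 constant line match enumeration", {
  lev <- array(1L, c(1, 1, 4))
  q <- qvoi_from_array(lev, 4)
  rl <- texture_matrices(q)$glrlm
  # one run of length 4 along z; each of the other 12 directions
  # contributes 4 singleton runs
  expect_equal(rl[1, 4], 1)
  expect_equal(rl[1, 1], 48)
  expect_equal(sum(rl), 49)
})

test_that("all-distinct levels make every run and zone a singleton", {
  lev <- array(seq_len(27), c(3, 3, 3))
  q <- qvoi_from_array(lev, 27)
  rl <- texture_matrices(q)$glrlm
  expect_equal(ncol(rl), 1)             # all runs have length 1
  n_runs <- sum(rl)
  expect_equal(n_runs, 13 * 27)
  expect_equal(unname(glrlm_features(q)["run_length_non_uniformity"]), n_runs)
  sz <- texture_matrices(q)$glszm
  expect_equal(ncol(sz), 1)
  expect_equal(sum(sz), 27)             # 27 singleton zones
})

test_that("GLSZM of a constant VOI is one zone with zero size variance", {
  q <- qvoi_from_array(array(1L, c(3, 4, 2)), 8)
  f <- glszm_features(q)
  expect_equal(unname(f["low_gray_level_zone_emphasis"]), 1)
  expect_equal(unname(f["zone_size_variance"]), 0)
  expect_equal(sum(texture_matrices(q)$glszm), 1)
})

test_that("NGLDM dependence counts match the neighbor geometry", {
  q <- qvoi_from_array(array(1L, c(3, 3, 3)), 4)
  m <- texture_matrices(q)$ngldm
  expect_equal(m[1, 27], 1)             # interior voxel: 26 equal neighbors
  expect_equal(sum(m), 27)              # mass = VOI voxel count
  single <- qvoi_from_array(array(c(0L, 1L, 0L), c(3, 1, 1)), 4)
  ms <- texture_matrices(single)$ngldm
  expect_equal(ms[1, 1], 1)             # dependence 0
})

test_that("constant VOI has zero NGTDM tone difference", {
  q <- qvoi_from_array(array(1L, c(3, 3, 3)), 8)
  f <- ngtdm_features(q)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(sum(texture_matrices(q)$ngtdm_s), 0)
})

test_that("every texture feature matches the brute-force oracle", {
  for (s in 1:12) {
    lev <- random_level_array(seed = 200 + s, side = sample(4:6, 1),
                              nbins = c(4, 8, 16)[1 + s %% 3])
    nb <- max(4, max(lev))
    q <- qvoi_from_array(lev, nb)
    got <- texture_features(q)
    want <- oracle_texture_features(lev, nb)
    expect_equal(unname(got), unname(want), tolerance = 1e-8,
                 label = paste("features, seed", 200 + s))
  }
})

test_that("mass conservation holds for GLSZM and NGLDM on random VOIs", {
  for (s in 1:10) {
    lev <- random_level_array(seed = 300 + s, side = 6, nbins = 8)
    q <- qvoi_from_array(lev, 8)
    mats <- texture_matrices(q)
    nvoi <- sum(lev > 0)
    expect_equal(sum(mats$glszm %*% seq_len(ncol(mats$glszm))), nvoi)
    expect_equal(sum(mats$ngldm), nvoi)
    expect_equal(sum(mats$glcm_counts %% 1), 0)  # integer pair counts
    expect_true(isSymmetric(mats$glcm_counts))
  }
})

test_that("texture features are invariant to affine intensity maps", {
  set.seed(17)
  dims <- c(6, 6, 6)
  vals <- array(rnorm(prod(dims)), dims)
  mask <- voi_mask(array(runif(prod(dims)) < 0.8, dims))
  v1 <- volume_image(vals)
  v2 <- volume_image(3 * vals - 10)
  for (nb in c(16, 64)) {
    f1 <- texture_features(quantize(v1, mask, nb))
    f2 <- texture_features(quantize(v2, mask, nb))
    expect_identical(f1, f2)
  }
})

test_that("single-voxel VOIs are rejected for GLCM", {
  q <- qvoi_from_array(array(c(0L, 1L), c(2, 1, 1)), 4)
  expect_error(glcm_features(q), "at least 2")
})
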