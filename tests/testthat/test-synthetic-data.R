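# Synthetic cohort generator: determinism, geometry, class balance and the
# behavior of the effect-size knob.

small_cfg <- function(seed, ...) {
  cohort_config(n_cases_per_class = 2, grid_shape = c(16, 16, 16),
                voxel_spacing = c(1, 1, 3), voi_radius_range = c(4, 6),
                seed = seed, ...)
}

test_that("same config and seed give bit-identical cohorts", {
  a <- generate_cohort(small_cfg(7))
  b <- generate_cohort(small_cfg(7))
  expect_identical(a, b)
  c2 <- generate_cohort(small_cfg(8))
  expect_false(identical(a, c2))
})

test_that("cohorts are balanced and masks satisfy their invariants", {
  cases <- generate_cohort(small_cfg(3))
  expect_equal(sum(vapply(cases, `[[`, 0, "label") == 0), 2)
  expect_equal(sum(vapply(cases, `[[`, 0, "label") == 1), 2)
  for (cs in cases) {
    m <- cs$mask$values
    expect_gte(sum(m), 27)
    # mask strictly interior: no foreground on any grid face
    expect_false(any(m[c(1, dim(m)[1]), , ]))
    expect_false(any(m[, c(1, dim(m)[2]), ]))
    expect_false(any(m[, , c(1, dim(m)[3])]))
    expect_identical(dim(cs$volumes$GD$values), dim(m))
    expect_identical(dim(cs$volumes$T2$values), dim(m))
    expect_equal(cs$volumes$GD$spacing, cs$mask$spacing)
    # the two sequences share the label but not the noise
    expect_false(identical(cs$volumes$GD$values, cs$volumes$T2$values))
  }
})

test_that("impossible VOI geometry and degenerate counts are rejected", {
  expect_error(cohort_config(n_cases_per_class = 0), "n_cases_per_class")
  # radius > half the grid extent cannot fit
  expect_error(
    cohort_config(grid_shape = c(32, 32, 32), voxel_spacing = c(1, 1, 1),
                  voi_radius_range = c(10, 20)),
    "fit"
  )
  # passes config validation but cannot place the ellipsoid interior
  cfg <- cohort_config(n_cases_per_class = 1, grid_shape = c(32, 32, 32),
                       voxel_spacing = c(1, 1, 1),
                       voi_radius_range = c(15.5, 15.9), seed = 1)
  expect_error(generate_cohort(cfg), "fit")
})

test_that("effect_size = 0 yields classes with equal mean VOI intensity", {
  pvals <- vapply(1:60, function(s) {
    cases <- generate_cohort(
      cohort_config(n_cases_per_class = 8, grid_shape = c(16, 16, 16),
                    voxel_spacing = c(1, 1, 3), voi_radius_range = c(4, 6),
                    effect_size = 0, seed = 1000 + s))
    mu <- vapply(cases, function(cs) mean(cs$volumes$GD$values[cs$mask$values]), 0)
    lab <- vapply(cases, `[[`, 0, "label")
    t.test(mu[lab == 0], mu[lab == 1])$p.value
  }, 0)
  expect_gte(mean(pvals > 0.05), 0.90)
})

test_that("between-class intensity separation grows with effect_size", {
  gaps <- vapply(c(0, 1, 2, 3), function(es) {
    mean(vapply(1:10, function(s) {
      cases <- generate_cohort(
        cohort_config(n_cases_per_class = 6, grid_shape = c(16, 16, 16),
                      voxel_spacing = c(1, 1, 3), voi_radius_range = c(4, 6),
                      effect_size = es, seed = 500 + s))
      mu <- vapply(cases, function(cs) mean(cs$volumes$GD$values[cs$mask$values]), 0)
      lab <- vapply(cases, `[[`, 0, "label")
      mean(mu[lab == 1]) - mean(mu[lab == 0])
    }, 0))
  }, 0)
  slope <- coef(lm(gaps ~ c(0, 1, 2, 3)))[2]
  expect_gt(slope, 0)
  expect_true(all(diff(gaps) > 0))
})
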