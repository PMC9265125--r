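# Feature selection phase: RFE mechanics, feature-number determination,
# frequency voting and correlation pruning.

test_that("rfe_rank keeps all columns when target_k equals the width", {
  pt <- planted_table(1, n = 30, p = 8)
  out <- rfe_rank(pt$X, pt$y, ncol(pt$X))
  expect_equal(as.character(out), colnames(pt$X))
  expect_length(attr(out, "elimination_order"), 0)
})

test_that("RFE survivors form a nested chain within one run", {
  pt <- planted_table(2, n = 40, p = 20)
  survivors <- lapply(1:10, function(k) as.character(rfe_rank(pt$X, pt$y, k)))
  for (k in 1:9) {
    expect_true(all(survivors[[k]] %in% survivors[[k + 1]]))
  }
})

test_that("a strongly informative column survives to k = 1", {
  hits <- vapply(1:25, function(s) {
    pt <- planted_table(1000 + s)
    as.character(rfe_rank(pt$X, pt$y, 1)) == pt$informative
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("of two identical planted columns exactly one survives", {
  set.seed(33)
  n <- 40
  y <- rep(0:1, each = n / 2)
  base <- y + rnorm(n, sd = 0.3)
  X <- matrix(rnorm(n * 10), n, 10)
  X[, 4] <- base
  X[, 7] <- base
  colnames(X) <- sprintf("-_GD_original_INT_f%02d", 1:10)
  X <- scale(X)
  surv <- as.character(rfe_rank(X, y, 1))
  expect_length(surv, 1)
  # ties eliminate the later (larger-index) twin, so f04 is the survivor
  expect_equal(surv, colnames(X)[4])
  # with k = 2 both twins carry half the signal each and survive together
  expect_setequal(as.character(rfe_rank(X, y, 2)), colnames(X)[c(4, 7)])
})

test_that("degenerate labels are rejected", {
  pt <- planted_table(3, n = 20, p = 5)
  expect_error(rfe_rank(pt$X, rep(1, 20), 2), "one class")
})

test_that("feature-number determination is seeded and deterministic", {
  pt <- planted_table(4, n = 32, p = 15)
  cfg <- selection_config(seed = 42)
  d1 <- determine_feature_number(pt$X, pt$y, cfg)
  d2 <- determine_feature_number(pt$X, pt$y, cfg)
  expect_identical(d1, d2)
  expect_equal(dim(d1$accuracy), c(10, 5))
  expect_true(d1$k %in% 1:10)
  d3 <- determine_feature_number(pt$X, pt$y, selection_config(seed = 43))
  expect_false(identical(d1$accuracy, d3$accuracy))
})

test_that("three planted features steer the chosen number near 3", {
  hits <- vapply(1:30, function(s) {
    set.seed(2000 + s)
    n <- 60
    y <- rep(0:1, each = 30)
    X <- matrix(rnorm(n * 30), n, 30)
    for (j in 1:3) X[, j] <- 0.8 * y + rnorm(n, sd = 0.45)
    colnames(X) <- sprintf("-_GD_original_INT_f%02d", 1:30)
    X <- scale(X)
    determine_feature_number(X, y, selection_config(seed = s))$k
  }, 0)
  expect_gte(mean(hits %in% 2:4), 0.6)
  expect_lt(median(hits), 8)
})

test_that("frequency voting returns integer frequencies and keeps sure winners", {
  pt <- planted_table(5, n = 50, p = 30, beta = 1.5, noise = 0.2)
  sel <- select_by_frequency(pt$X, pt$y, 5, selection_config(seed = 9))
  expect_length(sel$features, 5)
  expect_true(all(sel$frequency %in% 1:5))
  expect_equal(unname(sel$frequency[pt$informative]), 5)
  expect_equal(sel$features[1], pt$informative)  # most frequent first
})

test_that("correlation pruning removes the right member of a triple", {
  set.seed(12)
  n <- 40
  # orthonormal basis of centered columns so sample correlations are exact
  B <- qr.Q(qr(scale(matrix(rnorm(n * 3), n, 3), scale = FALSE)))
  a <- B[, 1]
  bb <- 0.9 * a + sqrt(1 - 0.81) * B[, 2]
  cc_x <- 0.2
  cc_y <- (0.2 - 0.9 * cc_x) / sqrt(1 - 0.81)
  cc <- cc_x * a + cc_y * B[, 2] + sqrt(1 - cc_x^2 - cc_y^2) * B[, 3]
  X <- cbind(a, bb, cc)
  colnames(X) <- paste0("-_GD_original_INT_", c("fa", "fb", "fc"))
  expect_equal(abs(cor(X)[1, 2]), 0.9, tolerance = 1e-10)
  expect_equal(abs(cor(X)[1, 3]), 0.2, tolerance = 1e-10)
  expect_equal(abs(cor(X)[2, 3]), 0.2, tolerance = 1e-10)
  freq <- c(3, 1, 2)
  names(freq) <- colnames(X)
  kept <- prune_correlated(colnames(X), X, 0.7, frequency = freq)
  expect_setequal(kept, colnames(X)[c(1, 3)])   # b dropped: lower frequency
})

test_that("pruning handles identical and orthogonal columns", {
  set.seed(13)
  X <- matrix(rnorm(30 * 2), 30, 2)
  X <- cbind(X, X[, 1])
  colnames(X) <- paste0("-_T2_original_INT_f", 1:3)
  kept <- prune_correlated(colnames(X), X, 0.7)
  expect_length(kept, 2)                         # one of the twins removed
  Xo <- qr.Q(qr(matrix(rnorm(30 * 3), 30, 3)))
  colnames(Xo) <- paste0("-_T2_original_INT_g", 1:3)
  expect_equal(prune_correlated(colnames(Xo), Xo, 0.7), colnames(Xo))
})

test_that("pruned sets never retain a pair above the threshold", {
  for (s in 1:10) {
    set.seed(400 + s)
    n <- 30; p <- 12
    X <- matrix(rnorm(n * p), n, p)
    X[, 2] <- X[, 1] + rnorm(n, sd = 0.1)
    X[, 5] <- -X[, 4] + rnorm(n, sd = 0.2)      # anticorrelated pair
    colnames(X) <- sprintf("-_GD_original_INT_h%02d", 1:p)
    kept <- prune_correlated(colnames(X), X, 0.7)
    if (length(kept) > 1) {
      cm <- abs(cor(X[, kept]))
      diag(cm) <- 0
      expect_lte(max(cm), 0.7)
    }
  }
})

test_that("select_features runs per sequence and prunes within each", {
  set.seed(14)
  n <- 40
  y <- rep(0:1, each = 20)
  Xg <- matrix(rnorm(n * 12), n, 12)
  Xg[, 1] <- y + rnorm(n, sd = 0.3)
  colnames(Xg) <- sprintf("-_GD_original_INT_f%02d", 1:12)
  Xt <- matrix(rnorm(n * 12), n, 12)
  Xt[, 3] <- y + rnorm(n, sd = 0.3)
  colnames(Xt) <- sprintf("-_T2_original_INT_f%02d", 1:12)
  X <- scale(cbind(Xg, Xt))
  sel <- select_features(X, y, selection_config(seed = 21), normalized = TRUE)
  expect_named(sel$per_block, c("GD", "T2"))
  expect_true(all(radvox:::feature_sequence(sel$per_block$GD$pruned) == "GD"))
  expect_true(all(radvox:::feature_sequence(sel$per_block$T2$pruned) == "T2"))
  expect_true("-_GD_original_INT_f01" %in% sel$features)
  expect_true("-_T2_original_INT_f03" %in% sel$features)
})
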