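# Model selection and test phase: ROC/AUC, tuning, cross-validated
# evaluation, hold-out accuracy and the reader-comparison statistics.

test_that("trapezoidal AUC is rank-invariant and orientation-covariant", {
  set.seed(21)
  y <- rep(0:1, each = 15)
  s <- rnorm(30) + y
  expect_equal(auc_trapezoid(s, y), auc_trapezoid(rank(s), y))
  expect_equal(auc_trapezoid(-s, y), 1 - auc_trapezoid(s, y))
  expect_equal(auc_trapezoid(y, y), 1)
  # agreement with an established implementation, including ties
  s_t <- round(s, 1)
  expect_equal(auc_trapezoid(s_t, y),
               as.numeric(pROC::auc(pROC::roc(y, s_t, quiet = TRUE,
                                              direction = "<"))))
})

test_that("ridge logistic regression agrees with glmnet", {
  set.seed(22)
  n <- 40; p <- 12
  X <- matrix(rnorm(n * p), n, p)
  y <- rbinom(n, 1, plogis(X[, 1] - X[, 2]))
  for (C in c(0.1, 1, 10)) {
    fit <- ridge_logistic(X, y, C)
    ref <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                          lambda = 1 / (n * C), standardize = FALSE,
                          thresh = 1e-14, maxit = 1e6)
    expect_lt(max(abs(fit$beta - as.numeric(ref$beta))), 1e-4)
    expect_lt(abs(fit$intercept - as.numeric(ref$a0)), 1e-4)
  }
})

test_that("tuning returns the sole grid point and is deterministic", {
  pt <- planted_table(23, n = 40, p = 5, beta = 1.5, noise = 0.2)
  cfg <- model_config(lr_cost = 1, seed = 3)
  t1 <- tune_model(pt$X, pt$y, "lr", cfg)
  expect_equal(t1$params$cost, 1)
  expect_equal(nrow(t1$grid), 1)
  cfg2 <- model_config(seed = 3)
  t2 <- tune_model(pt$X, pt$y, "lr", cfg2)
  t3 <- tune_model(pt$X, pt$y, "lr", cfg2)
  expect_identical(t2, t3)
  # clearly separable data reaches inner-CV AUC 1 for both learners
  expect_equal(t2$inner_auc, 1)
  ts <- tune_model(pt$X, pt$y, "svm", cfg2)
  expect_equal(ts$inner_auc, 1)
})

test_that("cross-validated evaluation reports per-fold AUCs and their spread", {
  pt <- planted_table(24, n = 40, p = 4, beta = 2, noise = 0.15)
  ev <- evaluate_cv(pt$X, pt$y, "lr", list(cost = 1), model_config(seed = 5))
  expect_length(ev$auc, 5)
  expect_true(all(ev$auc >= 0 & ev$auc <= 1))
  expect_equal(ev$mean_auc, 1)          # separable phantom
  expect_equal(ev$sd_auc, 0)
  expect_length(ev$roc, 5)
  expect_equal(ev$roc[[1]]$fpr[1], 0)
  expect_equal(tail(ev$roc[[1]]$tpr, 1), 1)
})

test_that("holdout accuracy is exact arithmetic and order-invariant", {
  pt <- planted_table(25, n = 40, p = 4, beta = 2, noise = 0.1)
  Xv <- pt$X[1:10, ]
  yv <- pt$y[1:10]
  yv_flip <- yv
  yv_flip[1] <- 1 - yv_flip[1]          # force exactly one error
  ho <- test_holdout(pt$X[11:40, ], pt$y[11:40], Xv, yv_flip, "lr",
                     list(cost = 1))
  expect_equal(ho$accuracy, 0.9)
  expect_equal(ho$fraction, "9/10")
  expect_equal(ho$n_correct, 9)
  perm <- sample(ncol(pt$X))
  ho2 <- test_holdout(pt$X[11:40, perm], pt$y[11:40], Xv[, perm], yv_flip,
                      "lr", list(cost = 1))
  expect_equal(ho2$accuracy, ho$accuracy)
  ho3 <- test_holdout(pt$X[11:40, ], pt$y[11:40], Xv, yv, "lr", list(cost = 1))
  expect_equal(ho3$accuracy, 1)
})

test_that("overlapping train/validation case ids are refused", {
  pt <- planted_table(26, n = 20, p = 3)
  expect_error(
    test_holdout(pt$X[1:15, ], pt$y[1:15], pt$X[14:20, ], pt$y[14:20], "lr",
                 list(cost = 1), train_ids = paste0("c", 1:15),
                 val_ids = paste0("c", 14:20)),
    "overlap"
  )
})

test_that("svm models produce class-1-oriented decision scores", {
  pt <- planted_table(27, n = 40, p = 3, beta = 2, noise = 0.1)
  m <- fit_classifier(pt$X, pt$y, "svm",
                      list(kernel = "linear", cost = 1, gamma = NA))
  s <- predict_scores(m, pt$X)
  expect_gt(auc_trapezoid(s, pt$y), 0.95)
  expect_gt(mean(s[pt$y == 1]), mean(s[pt$y == 0]))
})

test_that("reader comparison reproduces the closed-form t-test", {
  rc <- compare_readers(c(0.5, 0.6, 0.7), 0.9)
  expect_equal(rc$t, -5.196, tolerance = 1e-3)
  expect_equal(rc$p, 0.0351, tolerance = 1e-2)
  expect_true(rc$significant)           # p < 0.05 decision rule
  expect_equal(rc$median, 0.6)
  expect_true(rc$shapiro_p >= 0 && rc$shapiro_p <= 1)
  # sample mean equal to the reference: t = 0, p = 1
  rc0 <- compare_readers(c(0.5, 0.6, 0.7), 0.6)
  expect_equal(rc0$t, 0)
  expect_equal(rc0$p, 1)
  expect_false(rc0$significant)
  expect_error(compare_readers(c(0.6, 0.6, 0.6), 0.9), "degenerate")
  expect_error(compare_readers(c(0.5, 0.7), 0.9), "3 readers")
})

test_that("evaluation on permuted labels is not optimistic", {
  pt <- planted_table(28, n = 40, p = 5, beta = 1.5, noise = 0.3)
  aucs <- vapply(1:20, function(s) {
    set.seed(s)
    yp <- sample(pt$y)
    evaluate_cv(pt$X, yp, "lr", list(cost = 1),
                model_config(seed = s))$mean_auc
  }, 0)
  expect_gt(mean(aucs), 0.3)
  expect_lt(mean(aucs), 0.7)
})
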