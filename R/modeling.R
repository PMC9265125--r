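# Model selection and test phase: grid-searched logistic regression and SVM
# with nested 2-fold CV on a stratified 80% tuning subset, repeated 5-fold
# AUC evaluation with per-fold renormalization, hold-out testing, and the
# reader-comparison statistics.

#' Model configuration and hyperparameter grids
#'
#' The grids are deliberately small and standard: logistic regression uses
#' an L2 penalty with inverse strength `C` in \{0.01, 0.1, 1, 10, 100\};
#' the SVM searches linear and RBF kernels over the same cost grid with RBF
#' width gamma in \{1/d, 0.01, 0.1, 1\} (d = number of features). Grid
#' order breaks ties: the first grid point with the best inner-CV AUC wins.
#'
#' @param learner `"lr"` or `"svm"`.
#' @param lr_cost inverse L2 penalty grid for logistic regression.
#' @param svm_cost,svm_gamma,svm_kernel SVM grids; `NA` in `svm_gamma`
#'   stands for the data-dependent 1/d default.
#' @param inner_folds folds of the nested tuning CV.
#' @param tune_fraction fraction of training cases used for tuning (drawn
#'   stratified once per seed).
#' @param eval_folds folds of the AUC evaluation CV.
#' @param seed RNG seed.
#' @return A `model_config` list.
#' @export
model_config <- function(learner = c("lr", "svm"),
                         lr_cost = c(0.01, 0.1, 1, 10, 100),
                         svm_cost = c(0.01, 0.1, 1, 10, 100),
                         svm_gamma = c(NA, 0.01, 0.1, 1),
                         svm_kernel = c("linear", "radial"),
                         inner_folds = 2, tune_fraction = 0.8,
                         eval_folds = 5, seed = 1) {
  if (tune_fraction <= 0 || tune_fraction >= 1) stop("tune_fraction must be in (0, 1)")
  if (inner_folds < 2 || eval_folds < 2) stop("folds must be >= 2")
  structure(list(learner = match.arg(learner), lr_cost = lr_cost,
                 svm_cost = svm_cost, svm_gamma = svm_gamma,
                 svm_kernel = svm_kernel,
                 inner_folds = as.integer(inner_folds),
                 tune_fraction = tune_fraction,
                 eval_folds = as.integer(eval_folds),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' L2-regularized logistic regression
#'
#' The package's core binary classifier (also the RFE importance model):
#' minimizes the logistic deviance plus `1/(2C) * ||beta||^2` with an
#' unpenalized intercept, solved by a damped Newton iteration in the
#' observation space.
#'
#' @param X feature matrix.
#' @param y binary labels (0/1).
#' @param C inverse penalty strength.
#' @return list with `beta`, `intercept`, `converged`.
#' @export
ridge_logistic <- function(X, y, C = 1) {
  X <- as.matrix(X)
  y <- check_labels(y)
  fit <- cpp_ridge_logistic(X, y, C)
  fit$beta <- as.numeric(fit$beta)
  names(fit$beta) <- colnames(X)
  fit
}

hyper_grid <- function(learner, config, d) {
  if (learner == "lr") {
    data.frame(cost = config$lr_cost)
  } else {
    grids <- lapply(config$svm_kernel, function(k) {
      if (k == "linear") {
        data.frame(kernel = k, cost = config$svm_cost, gamma = NA_real_)
      } else {
        expand.grid(kernel = k, cost = config$svm_cost,
                    gamma = ifelse(is.na(config$svm_gamma), 1 / d, config$svm_gamma),
                    stringsAsFactors = FALSE)
      }
    })
    do.call(rbind, grids)
  }
}

#' Fit a classifier with fixed hyperparameters
#'
#' @param X normalized feature matrix.
#' @param y binary labels.
#' @param learner `"lr"` or `"svm"`.
#' @param params one row of the hyperparameter grid (list or data frame
#'   row): `cost` for `"lr"`; `kernel`, `cost`, `gamma` for `"svm"`.
#' @return A `radvox_model`.
#' @export
fit_classifier <- function(X, y, learner, params) {
  X <- as.matrix(X)
  y <- check_labels(y)
  fit <- if (learner == "lr") {
    ridge_logistic(X, y, C = params$cost)
  } else {
    e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
               kernel = as.character(params$kernel), cost = params$cost,
               gamma = if (is.na(params$gamma %||% NA)) 1 / ncol(X) else params$gamma,
               scale = FALSE)
  }
  structure(list(learner = learner, fit = fit, params = params,
                 features = colnames(X)),
            class = "radvox_model")
}

#' Decision scores of a fitted classifier
#'
#' Logistic regression returns class-1 probabilities; the SVM returns the
#' signed decision margin oriented so larger means more class-1-like (AUC is
#' rank-based, so no probability calibration is needed).
#'
#' @param model a [fit_classifier()] result.
#' @param X matrix with the model's feature columns.
#' @return Numeric score vector.
#' @export
predict_scores <- function(model, X) {
  X <- as.matrix(X)[, model$features, drop = FALSE]
  if (model$learner == "lr") {
    as.numeric(plogis(X %*% model$fit$beta + model$fit$intercept))
  } else {
    pr <- predict(model$fit, X, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # e1071 orients the margin toward the first factor level ("0")
    if (colnames(dv)[1] == "0/1") -as.numeric(dv) else as.numeric(dv)
  }
}

predict_class <- function(model, X) {
  s <- predict_scores(model, X)
  threshold <- if (model$learner == "lr") 0.5 else 0
  as.numeric(s >= threshold)
}

#' Hyperparameter tuning by grid search with nested CV
#'
#' Every grid point is scored by stratified `inner_folds`-fold CV AUC on a
#' stratified `tune_fraction` subset of the training cases (drawn once per
#' seed); the first grid point attaining the best mean AUC wins.
#'
#' @param X normalized training features (already restricted to the
#'   selected features).
#' @param y binary labels.
#' @param learner `"lr"` or `"svm"`.
#' @param config a [model_config()].
#' @return list with `learner`, `params` (best row), `inner_auc` and the
#'   scored `grid`.
#' @export
tune_model <- function(X, y, learner, config = model_config()) {
  X <- as.matrix(X)
  y <- check_labels(y)
  grid <- hyper_grid(learner, config, ncol(X))
  with_seed(config$seed, {
    sub <- stratified_subset(y, config$tune_fraction)
    Xs <- X[sub, , drop = FALSE]
    ys <- y[sub]
    fold <- stratified_folds(ys, config$inner_folds)
    aucs <- vapply(seq_len(nrow(grid)), function(g) {
      mean(vapply(seq_len(config$inner_folds), function(f) {
        tr <- fold != f
        m <- fit_classifier(Xs[tr, , drop = FALSE], ys[tr], learner, grid[g, , drop = FALSE])
        auc_trapezoid(predict_scores(m, Xs[!tr, , drop = FALSE]), ys[!tr])
      }, 0))
    }, 0)
  })
  best <- which.max(aucs)  # first max = first in declared grid order
  list(learner = learner, params = grid[best, , drop = FALSE],
       inner_auc = aucs[best], grid = cbind(grid, inner_auc = aucs))
}

#' Repeated k-fold ROC/AUC evaluation
#'
#' Stratified `eval_folds`-fold CV on the training cases: per fold the
#' z-score normalization is refit on the training portion, the model refit,
#' and the ROC/AUC computed on the held-out portion by the trapezoidal rule.
#' Reports the mean and sample SD of the fold AUCs.
#'
#' @param X raw (unnormalized) feature matrix of the selected features.
#' @param y binary labels.
#' @param learner,params classifier specification (see [fit_classifier()]).
#' @param config a [model_config()].
#' @return An `eval_report`: `auc` per fold, `mean_auc`, `sd_auc`, `roc`
#'   (per-fold ROC curves).
#' @export
evaluate_cv <- function(X, y, learner, params, config = model_config()) {
  X <- as.matrix(X)
  y <- check_labels(y)
  if (length(y) < 2L * config$eval_folds) stop("too few cases for ", config$eval_folds, "-fold CV")
  with_seed(config$seed, {
    fold <- stratified_folds(y, config$eval_folds)
    res <- lapply(seq_len(config$eval_folds), function(f) {
      tr <- fold != f
      z <- zscore_fit(X[tr, , drop = FALSE])
      m <- fit_classifier(zscore_apply(z, X[tr, , drop = FALSE]), y[tr], learner, params)
      s <- predict_scores(m, zscore_apply(z, X[!tr, , drop = FALSE]))
      list(auc = auc_trapezoid(s, y[!tr]), roc = roc_curve(s, y[!tr]))
    })
  })
  aucs <- vapply(res, `[[`, 0, "auc")
  structure(list(auc = aucs, mean_auc = mean(aucs), sd_auc = sd(aucs),
                 roc = lapply(res, `[[`, "roc"),
                 learner = learner, params = params),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s: AUC %.3f +/- %.3f over %d folds\n",
              x$learner, x$mean_auc, x$sd_auc, length(x$auc)))
  invisible(x)
}

#' Hold-out test of a model fit on the full training set
#'
#' Normalization statistics come from the training rows only. Training and
#' validation case sets must be disjoint.
#'
#' @param X_train,y_train training features (raw) and labels.
#' @param X_val,y_val validation features and labels.
#' @param learner,params classifier specification.
#' @param train_ids,val_ids optional case identifiers, checked for overlap.
#' @return list with `accuracy`, `n_correct`, `n_total`, `fraction` (exact
#'   rational as text), `predictions` and `scores`.
#' @export
test_holdout <- function(X_train, y_train, X_val, y_val, learner, params,
                         train_ids = NULL, val_ids = NULL) {
  if (!is.null(train_ids) && !is.null(val_ids) &&
      length(intersect(train_ids, val_ids)) > 0L) {
    stop("training and validation case_ids overlap")
  }
  y_val <- as.numeric(y_val)
  z <- zscore_fit(as.matrix(X_train))
  m <- fit_classifier(zscore_apply(z, as.matrix(X_train)), y_train, learner, params)
  Xv <- zscore_apply(z, as.matrix(X_val))
  pred <- predict_class(m, Xv)
  n_correct <- sum(pred == y_val)
  list(accuracy = n_correct / length(y_val),
       n_correct = n_correct, n_total = length(y_val),
       fraction = sprintf("%d/%d", n_correct, length(y_val)),
       predictions = pred, scores = predict_scores(m, Xv), model = m)
}

#' Compare reader accuracies against a model's accuracy
#'
#' One-sample two-sided t-test of the reader accuracies against the model
#' accuracy as reference value, with a Shapiro-Wilk normality check, the
#' reader median, and the 95% CI of the reader mean
#' (`mean +/- t_{0.975, n-1} * SE`). p < 0.05 is flagged significant.
#'
#' @param reader_accuracies numeric vector (>= 3 readers, non-constant).
#' @param model_accuracy reference accuracy in `[0, 1]`.
#' @return A `reader_comparison` list.
#' @export
compare_readers <- function(reader_accuracies, model_accuracy) {
  x <- as.numeric(reader_accuracies)
  if (length(x) < 3L) stop("need at least 3 readers")
  if (sd(x) == 0) stop("degenerate sample: reader accuracies are constant")
  tt <- t.test(x, mu = model_accuracy)
  sw <- shapiro.test(x)
  n <- length(x)
  ci_half <- qt(0.975, n - 1) * sd(x) / sqrt(n)
  structure(list(t = unname(tt$statistic), p = tt$p.value,
                 shapiro_p = sw$p.value,
                 mean = mean(x), median = median(x),
                 ci = c(mean(x) - ci_half, mean(x) + ci_half),
                 model_accuracy = model_accuracy,
                 significant = tt$p.value < 0.05),
            class = "reader_comparison")
}

#' @export
print.reader_comparison <- function(x, ...) {
  cat(sprintf(paste0("<reader_comparison> readers mean %.3f (median %.3f, ",
                     "95%% CI %.3f-%.3f) vs model %.3f: t = %.3f, p = %.4f%s\n"),
              x$mean, x$median, x$ci[1], x$ci[2], x$model_accuracy, x$t, x$p,
              if (x$significant) " (significant at 0.05)" else ""))
  invisible(x)
}

#' Run the full pipeline on extracted feature tables
#'
#' Normalizes on the training table, runs the feature selection phase, tunes
#' logistic regression and SVM by nested CV, picks the learner with the
#' higher inner-CV AUC (tie: logistic regression), evaluates it by repeated
#' 5-fold AUC with per-fold renormalization, and tests on the hold-out
#' table.
#'
#' @param train_table,val_table feature tables from [extract_cohort()].
#' @param sel_config a [selection_config()].
#' @param mod_config a [model_config()].
#' @return list with `selection`, `tuning` (both learners), `chosen`,
#'   `evaluation` ([evaluate_cv()] report) and `holdout`
#'   ([test_holdout()] result).
#' @export
run_pipeline <- function(train_table, val_table,
                         sel_config = selection_config(),
                         mod_config = model_config()) {
  y_tr <- as.numeric(train_table$label)
  y_va <- as.numeric(val_table$label)
  X_tr <- feature_matrix(train_table)
  X_va <- feature_matrix(val_table)
  z <- zscore_fit(X_tr)
  Xn_full <- zscore_apply(z, X_tr)
  sel <- select_features(Xn_full, y_tr, sel_config, normalized = TRUE)
  feats <- sel$features
  Xn <- Xn_full[, feats, drop = FALSE]
  tunes <- list(lr = tune_model(Xn, y_tr, "lr", mod_config),
                svm = tune_model(Xn, y_tr, "svm", mod_config))
  chosen <- if (tunes$svm$inner_auc > tunes$lr$inner_auc) tunes$svm else tunes$lr
  evaluation <- evaluate_cv(X_tr[, feats, drop = FALSE], y_tr,
                            chosen$learner, chosen$params, mod_config)
  holdout <- test_holdout(X_tr[, feats, drop = FALSE], y_tr,
                          X_va[, feats, drop = FALSE], y_va,
                          chosen$learner, chosen$params,
                          train_ids = train_table$case_id,
                          val_ids = val_table$case_id)
  list(selection = sel, tuning = tunes, chosen = chosen,
       evaluation = evaluation, holdout = holdout)
}
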