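# Feature selection phase: (1) determine the feature number by a 4-subgroup
# cross-validation simulation repeated 5 times, (2) select features by
# logistic-regression RFE with frequency voting over the repeats, (3) prune
# correlated features until all pairwise |r| <= 0.7 within each sequence.
#
# Importance during RFE is the absolute coefficient of an L2-regularized
# logistic regression (C = 1) on the z-scored features; one feature is
# removed per refit. Ties remove the feature later in registry order.

#' Configuration of the feature selection phase
#'
#' @param candidate_numbers candidate feature counts (default 1..10).
#' @param n_subgroups outer CV subgroups for the feature-number simulation.
#' @param n_repeats repeats of the subgroup split (and of the RFE runs used
#'   for frequency voting).
#' @param cor_threshold redundancy threshold on the absolute pairwise
#'   Pearson correlation.
#' @param C inverse L2 penalty of the RFE logistic regression.
#' @param per_sequence select independently per sequence (GD and T2) or
#'   jointly on the pooled table.
#' @param seed RNG seed; subgroup splits of repeat r are drawn from
#'   `seed + r`, so the feature-number simulation and the frequency voting
#'   re-use the same splits.
#' @return A `selection_config` list.
#' @export
selection_config <- function(candidate_numbers = 1:10, n_subgroups = 4,
                             n_repeats = 5, cor_threshold = 0.7, C = 1,
                             per_sequence = TRUE, seed = 1) {
  if (cor_threshold <= 0 || cor_threshold >= 1) stop("threshold must be in (0, 1)")
  if (n_subgroups < 2) stop("need at least 2 subgroups")
  structure(list(candidate_numbers = as.integer(candidate_numbers),
                 n_subgroups = as.integer(n_subgroups),
                 n_repeats = as.integer(n_repeats),
                 cor_threshold = cor_threshold, C = C,
                 per_sequence = isTRUE(per_sequence),
                 seed = as.integer(seed)),
            class = "selection_config")
}

check_labels <- function(y) {
  if (length(unique(y)) < 2L) stop("degenerate labels: only one class present")
  as.numeric(y)
}

#' Logistic-regression recursive feature elimination
#'
#' Repeatedly fits an L2-regularized logistic regression and removes the
#' single feature with the smallest absolute coefficient until `target_k`
#' features remain. Survivors are nested: the survivors at k are a subset of
#' the survivors at k+1 of the same run.
#'
#' @param X normalized feature matrix with named columns.
#' @param y binary labels (0/1).
#' @param target_k number of features to retain.
#' @param C inverse L2 penalty strength.
#' @return Character vector of the surviving features, longest-surviving
#'   first, with the full elimination order (first removed first) in
#'   attribute `"elimination_order"`.
#' @export
rfe_rank <- function(X, y, target_k, C = 1) {
  X <- as.matrix(X)
  y <- check_labels(y)
  if (target_k < 1L) stop("target_k must be >= 1")
  if (target_k > ncol(X)) stop("target_k exceeds the number of features")
  if (target_k == ncol(X)) {
    out <- colnames(X)
    attr(out, "elimination_order") <- character(0)
    return(out)
  }
  ord <- cpp_rfe_order(X, y, C)
  surv <- rev(tail(ord, target_k))
  out <- colnames(X)[surv]
  attr(out, "elimination_order") <- colnames(X)[head(ord, ncol(X) - target_k)]
  out
}

repeat_folds <- function(y, config, rep) {
  with_seed(config$seed + rep, stratified_folds(y, config$n_subgroups))
}

#' Determine the feature number by cross-validated simulation
#'
#' For each candidate k and each of `n_repeats` repeats: the training cases
#' are split into `n_subgroups` stratified subgroups; per subgroup, RFE runs
#' to k on the remaining subgroups, a logistic regression is fit on those k
#' features, and accuracy is measured on the held-out subgroup. The k with
#' the highest mean accuracy wins (ties go to the smaller k).
#'
#' @inheritParams rfe_rank
#' @param config a [selection_config()].
#' @return list with `k` (chosen number), `accuracy` (candidates x repeats
#'   matrix of fold-mean accuracies) and `mean_accuracy` per candidate.
#' @export
determine_feature_number <- function(X, y, config = selection_config()) {
  X <- as.matrix(X)
  y <- check_labels(y)
  if (length(y) < 2L * config$n_subgroups) stop("too few cases for the subgroup split")
  ks <- config$candidate_numbers
  acc <- matrix(NA_real_, nrow = length(ks), ncol = config$n_repeats,
                dimnames = list(paste0("k", ks), paste0("rep", seq_len(config$n_repeats))))
  for (r in seq_len(config$n_repeats)) {
    fold <- repeat_folds(y, config, r)
    fold_acc <- matrix(NA_real_, nrow = length(ks), ncol = config$n_subgroups)
    for (f in seq_len(config$n_subgroups)) {
      tr <- fold != f
      ord <- cpp_rfe_order(X[tr, , drop = FALSE], y[tr], config$C)
      for (ki in seq_along(ks)) {
        feats <- tail(ord, ks[ki])
        fit <- cpp_ridge_logistic(X[tr, feats, drop = FALSE], y[tr], config$C)
        scores <- plogis(X[!tr, feats, drop = FALSE] %*% fit$beta + fit$intercept)
        fold_acc[ki, f] <- mean((scores >= 0.5) == (y[!tr] == 1))
      }
    }
    acc[, r] <- rowMeans(fold_acc)
  }
  mean_acc <- rowMeans(acc)
  list(k = ks[which.max(mean_acc)], accuracy = acc, mean_accuracy = mean_acc)
}

#' Select features by RFE frequency voting
#'
#' Runs one RFE per repeat on a re-randomized 3/4 training subsample (the
#' first subgroup of that repeat's split held out), counts how often each
#' feature survives to size k, and returns the k most frequent. Ties prefer
#' the feature with the better (higher) mean survival position, then the
#' lexicographically smaller name.
#'
#' @inheritParams determine_feature_number
#' @param k the feature number, typically from [determine_feature_number()].
#' @return list with `features` (length k), `frequency` (integer counts in
#'   1..n_repeats for every feature ever selected) and `mean_position`
#'   (mean elimination position; larger = survived longer).
#' @export
select_by_frequency <- function(X, y, k, config = selection_config()) {
  X <- as.matrix(X)
  y <- check_labels(y)
  if (k < 1L) stop("k must be >= 1")
  p <- ncol(X)
  survivors <- vector("list", config$n_repeats)
  position <- matrix(0, nrow = config$n_repeats, ncol = p,
                     dimnames = list(NULL, colnames(X)))
  for (r in seq_len(config$n_repeats)) {
    fold <- repeat_folds(y, config, r)
    tr <- fold != 1L
    ord <- cpp_rfe_order(X[tr, , drop = FALSE], y[tr], config$C)
    survivors[[r]] <- colnames(X)[tail(ord, k)]
    position[r, ord] <- seq_len(p)  # later elimination = higher position
  }
  freq <- table(unlist(survivors))
  mean_pos <- colMeans(position)
  cand <- names(freq)
  o <- order(-as.integer(freq), -mean_pos[cand], cand)
  list(features = cand[o][seq_len(min(k, length(cand)))],
       frequency = freq,
       mean_position = mean_pos)
}

#' Prune correlated features
#'
#' Pearson correlations are computed within each sequence's features on the
#' training rows. While any pair exceeds the threshold in absolute value,
#' the member with the lower selection frequency is removed (ties: lower
#' mean survival position, then the lexicographically larger name).
#'
#' @param features candidate feature names (subset of `colnames(X)`).
#' @param X training feature matrix.
#' @param threshold absolute correlation threshold (default 0.7).
#' @param frequency named selection frequencies (optional).
#' @param mean_position named mean survival positions (optional).
#' @return The pruned feature vector (original order), with all pairwise
#'   absolute correlations at or below the threshold.
#' @export
prune_correlated <- function(features, X, threshold = 0.7,
                             frequency = NULL, mean_position = NULL) {
  X <- as.matrix(X)
  stopifnot(all(features %in% colnames(X)))
  fr <- function(f) {
    v <- if (!is.null(frequency)) unname(frequency[f]) else NA
    ifelse(is.na(v), 0, as.numeric(v))
  }
  mp <- function(f) {
    v <- if (!is.null(mean_position)) unname(mean_position[f]) else NA
    ifelse(is.na(v), 0, as.numeric(v))
  }
  keep <- features
  for (seq_tok in unique(feature_sequence(features))) {
    grp <- keep[feature_sequence(keep) == seq_tok]
    while (length(grp) > 1L) {
      cm <- abs(suppressWarnings(cor(X[, grp, drop = FALSE])))
      cm[is.na(cm)] <- 0
      diag(cm) <- 0
      if (max(cm) <= threshold) break
      ij <- which(cm == max(cm), arr.ind = TRUE)[1, ]
      a <- grp[ij[1]]; b <- grp[ij[2]]
      drop <- if (fr(a) != fr(b)) {
        if (fr(a) < fr(b)) a else b
      } else if (mp(a) != mp(b)) {
        if (mp(a) < mp(b)) a else b
      } else {
        max(a, b)  # lexicographically larger
      }
      grp <- setdiff(grp, drop)
      keep <- setdiff(keep, drop)
    }
  }
  keep
}

#' Run the full feature selection phase
#'
#' Per sequence (or on the pooled table if `per_sequence = FALSE`):
#' determine the feature number, vote features by frequency, then prune
#' correlated features.
#'
#' @param table feature table ([extract_cohort()]) or a normalized feature
#'   matrix with named columns.
#' @param y binary labels; taken from the table's `label` column when
#'   missing.
#' @param config a [selection_config()].
#' @param normalized set to TRUE when `table` is already z-scored.
#' @return A `selection_result`: `features` (final pruned list), `per_block`
#'   (chosen k, frequencies and accuracy tables per sequence block).
#' @export
select_features <- function(table, y = NULL, config = selection_config(),
                            normalized = FALSE) {
  if (is.data.frame(table)) {
    y <- y %||% table$label
    X <- feature_matrix(table)
  } else {
    X <- as.matrix(table)
  }
  y <- check_labels(y)
  if (!normalized) X <- zscore_apply(zscore_fit(X), X)
  blocks <- if (config$per_sequence) {
    split(colnames(X), feature_sequence(colnames(X)))
  } else {
    list(all = colnames(X))
  }
  per_block <- list()
  final <- character(0)
  for (bn in names(blocks)) {
    Xb <- X[, blocks[[bn]], drop = FALSE]
    det <- determine_feature_number(Xb, y, config)
    sel <- select_by_frequency(Xb, y, det$k, config)
    pruned <- prune_correlated(sel$features, Xb, config$cor_threshold,
                               sel$frequency, sel$mean_position)
    per_block[[bn]] <- list(k = det$k, accuracy = det$accuracy,
                            mean_accuracy = det$mean_accuracy,
                            selected = sel$features,
                            frequency = sel$frequency, pruned = pruned)
    final <- c(final, pruned)
  }
  structure(list(features = final, per_block = per_block, config = config),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> ", length(x$features), " features after pruning\n",
      sep = "")
  for (bn in names(x$per_block)) {
    b <- x$per_block[[bn]]
    cat("  block ", bn, ": k = ", b$k, ", kept ", length(b$pruned), "\n", sep = "")
  }
  invisible(x)
}
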