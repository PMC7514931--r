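#' Group-aware k-fold assignment
#'
#' Partitions *groups* (subjects), not samples, into k folds, so that all
#' samples sharing a group id land in the same fold and no subject leaks
#' across the train/test boundary. Groups are shuffled (per seed), ordered
#' by size, and assigned greedily to the currently smallest fold by sample
#' count, keeping fold sizes as balanced as the group sizes permit.
#'
#' @param groups Group id per sample (any atomic type).
#' @param k Number of folds, >= 2; at most the number of distinct groups.
#' @param seed Integer seed for the shuffle.
#' @return Integer fold id (1..k) per sample.
#' @examples
#' grouped_kfold(rep(1:5, each = 4), k = 5, seed = 1)
#' @export
grouped_kfold <- function(groups, k, seed = 1L) {
  if (anyNA(groups)) stop("`groups` contains missing values")
  k <- as.integer(k)
  if (k < 2L) stop("`k` must be >= 2")
  ug <- unique(groups)
  if (length(ug) < k) {
    stop(sprintf("only %d distinct group(s) for %d folds", length(ug), k))
  }
  sizes <- as.integer(table(factor(groups, levels = ug)))
  ord <- with_seed(seed, sample.int(length(ug)))
  ord <- ord[order(sizes[ord], decreasing = TRUE)]   # stable: shuffle breaks ties
  fold_of_group <- integer(length(ug))
  fold_sizes <- integer(k)
  for (g in ord) {
    f <- which.min(fold_sizes)
    fold_of_group[g] <- f
    fold_sizes[f] <- fold_sizes[f] + sizes[g]
  }
  fold_of_group[match(groups, ug)]
}

#' Random undersampling to a minimum class ratio
#'
#' If the minority/majority ratio of a binary labeling is below
#' `min_ratio`, majority samples are removed uniformly at random until the
#' ratio first reaches it (the kept majority count is the largest c with
#' minority/c >= min_ratio). Minority samples are never removed. Apply
#' this to *training* splits only; undersampling test data biases the
#' evaluation.
#'
#' @param labels Binary labels.
#' @param groups Optional group ids, echoed in the log message only; the
#'   removal itself is uniform over majority samples.
#' @param min_ratio Minimum minority/majority ratio in (0, 1].
#' @param seed Integer seed.
#' @return Sorted integer indices of the kept samples.
#' @examples
#' table(rep(c("a", "b"), c(10, 100))[
#'   undersample(rep(c("a", "b"), c(10, 100)), min_ratio = 0.3, seed = 1)])
#' @export
undersample <- function(labels, groups = NULL, min_ratio = 0.3, seed = 1L) {
  if (anyNA(labels)) stop("labels contain missing values")
  if (!is.finite(min_ratio) || min_ratio <= 0 || min_ratio > 1) {
    stop("`min_ratio` must be in (0, 1]")
  }
  cls <- encode_labels(labels)
  if (cls$d != 2L) {
    stop(sprintf("undersampling needs binary labels, got %d class(es)",
                 cls$d))
  }
  counts <- tabulate(cls$ids, 2L)
  minor <- which.min(counts)
  major <- 3L - minor
  if (counts[minor] / counts[major] >= min_ratio) {
    return(seq_along(cls$ids))
  }
  target <- floor(counts[minor] / min_ratio)
  maj_idx <- which(cls$ids == major)
  keep_maj <- with_seed(seed, sample(maj_idx, target))
  message(sprintf(
    "undersampling (seed %d): removed %d of %d majority ('%s') samples; ratio %.3f -> %.3f",
    seed, counts[major] - target, counts[major], cls$levels[major],
    counts[minor] / counts[major], counts[minor] / target))
  sort(c(which(cls$ids == minor), keep_maj))
}

#' Area under the ROC curve
#'
#' The Mann-Whitney form: the probability that a random positive sample
#' scores above a random negative one, counting ties as 1/2.
#'
#' @param labels Binary true labels.
#' @param scores Numeric score for the positive class, one per sample.
#' @param positive Which label value is the positive class (default: the
#'   second factor level).
#' @return AUROC in `[0, 1]`.
#' @examples
#' auroc(c("p", "p", "n", "n"), c(0.9, 0.4, 0.6, 0.2), positive = "p")
#' @export
auroc <- function(labels, scores, positive = NULL) {
  if (length(labels) != length(scores)) {
    stop("`labels` and `scores` must have the same length")
  }
  if (anyNA(labels) || anyNA(scores)) stop("missing values in input")
  cls <- encode_labels(labels)
  if (cls$d != 2L) stop("AUROC needs exactly 2 classes present")
  positive <- as.character(positive %||% cls$levels[2L])
  if (!positive %in% cls$levels) {
    stop(sprintf("positive class '%s' not present in labels", positive))
  }
  pos <- cls$levels[cls$ids] == positive
  r <- rank(scores)                      # average ranks handle ties
  n_pos <- sum(pos); n_neg <- sum(!pos)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Euclidean k-nearest-neighbour scores (baseline)
#'
#' Plain unweighted k-NN used as an in-package comparator: the score of a
#' test sample for each class is the fraction of its k nearest training
#' samples (Euclidean distance, ties by index order) in that class.
#'
#' @param x_train,y_train Training features and labels.
#' @param x_test Test features.
#' @param k Number of neighbours (default 7).
#' @return Matrix of class-vote fractions, one row per test sample, one
#'   column per class level.
#' @export
knn_scores <- function(x_train, y_train, x_test, k = 7L) {
  Xtr <- as_feature_matrix(x_train)
  Xte <- as_feature_matrix(x_test)
  cls <- encode_labels(y_train, m = nrow(Xtr))
  k <- min(as.integer(k), nrow(Xtr))
  # squared cross distances: |a|^2 + |b|^2 - 2 a.b
  D2 <- outer(rowSums(Xte^2), rowSums(Xtr^2), "+") - 2 * Xte %*% t(Xtr)
  votes <- matrix(0, nrow(Xte), cls$d, dimnames = list(NULL, cls$levels))
  for (j in seq_len(nrow(Xte))) {
    nb <- order(D2[j, ])[seq_len(k)]
    tab <- tabulate(cls$ids[nb], nbins = cls$d)
    votes[j, ] <- tab / k
  }
  votes
}

#' Cross-validate a LUCCK configuration
#'
#' Runs group-aware k-fold cross-validation: per fold, optionally
#' undersamples the *training* split to a minimum class ratio, fits the
#' classifier, and scores the held-out fold. Reports per-fold and mean
#' accuracy (%) and, for binary problems, AUROC from the positive-class
#' probability. Fully reproducible for a fixed seed.
#'
#' @param x Feature matrix or data frame.
#' @param y Class labels.
#' @param groups Group (subject) ids; one per sample.
#' @param k Number of folds (default 10).
#' @param seed Integer seed driving fold assignment and undersampling.
#' @param capital_lambda,capital_theta Kernel hyperparameters.
#' @param reweight Learn class weights on each training split.
#' @param min_ratio If non-NULL, undersample each training split to this
#'   minimum minority/majority ratio (binary only).
#' @param positive Positive class for AUROC (default: second level).
#' @return An object of class `lucck_cv`: per-fold accuracy/AUROC, their
#'   means, per-fold class counts before/after undersampling, the
#'   configuration, and the seed.
#' @export
cross_validate <- function(x, y, groups, k = 10L, seed = 1L,
                           capital_lambda = 1, capital_theta = 1,
                           reweight = FALSE, min_ratio = NULL,
                           positive = NULL) {
  X <- as_feature_matrix(x)
  cls <- encode_labels(y, m = nrow(X))
  if (length(groups) != nrow(X)) stop("`groups` must have one id per sample")
  folds <- grouped_kfold(groups, k, seed = seed)
  fold_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
  y_fac <- factor(cls$levels[cls$ids], levels = cls$levels)
  binary <- cls$d == 2L
  positive <- if (binary) as.character(positive %||% cls$levels[2L]) else NULL

  acc <- auc <- rep(NA_real_, k)
  counts <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    before <- table(y_fac[tr])
    if (!is.null(min_ratio) && binary) {
      tr <- tr[undersample(y_fac[tr], min_ratio = min_ratio,
                           seed = fold_seeds[f])]
    }
    counts[[f]] <- list(before = as.integer(before),
                        after = as.integer(table(y_fac[tr])),
                        test = as.integer(table(y_fac[te])))
    fit <- lucck(X[tr, , drop = FALSE], y_fac[tr],
                 capital_lambda = capital_lambda,
                 capital_theta = capital_theta, reweight = reweight)
    pred <- predict(fit, X[te, , drop = FALSE])
    acc[f] <- 100 * mean(as.character(pred) == as.character(y_fac[te]))
    if (binary) {
      if (length(unique(y_fac[te])) < 2L) {
        warning(sprintf("fold %d: single-class test split, AUROC undefined", f))
      } else {
        P <- predict_proba(fit, X[te, , drop = FALSE])
        auc[f] <- auroc(y_fac[te], P[, positive], positive = positive)
      }
    }
  }
  structure(
    list(fold_accuracy = acc, mean_accuracy = mean(acc),
         fold_auroc = auc,
         mean_auroc = if (binary) mean(auc, na.rm = TRUE) else NA_real_,
         class_counts = counts, k = k, seed = seed,
         config = list(capital_lambda = capital_lambda,
                       capital_theta = capital_theta,
                       reweight = reweight, min_ratio = min_ratio,
                       positive = positive)),
    class = "lucck_cv")
}

#' @export
print.lucck_cv <- function(x, ...) {
  cat(sprintf("%d-fold grouped cross-validation (seed %d)\n", x$k, x$seed))
  cat(sprintf("  mean accuracy: %.2f%%\n", x$mean_accuracy))
  if (!is.na(x$mean_auroc)) cat(sprintf("  mean AUROC:    %.4f\n", x$mean_auroc))
  cat("  per-fold accuracy:",
      paste(sprintf("%.1f", x$fold_accuracy), collapse = " "), "\n")
  invisible(x)
}

#' Grid search over the global kernel hyperparameters
#'
#' Evaluates every (Lambda, Theta) pair by grouped cross-validation and
#' returns the grid with its mean accuracies plus the best pair (ties go
#' to the first row in grid order).
#'
#' @inheritParams cross_validate
#' @param lambda_grid,theta_grid Candidate values for Lambda and Theta.
#' @return List with `grid` (data frame: capital_lambda, capital_theta,
#'   mean_accuracy, mean_auroc) and `best` (row of the grid).
#' @export
lucck_tune <- function(x, y, groups, k = 5L, seed = 1L,
                       lambda_grid = c(0.1, 1, 10),
                       theta_grid = c(0.5, 1, 2), ...) {
  grid <- expand.grid(capital_lambda = lambda_grid,
                      capital_theta = theta_grid,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(r) {
    cv <- cross_validate(x, y, groups, k = k, seed = seed,
                         capital_lambda = grid$capital_lambda[r],
                         capital_theta = grid$capital_theta[r], ...)
    c(mean_accuracy = cv$mean_accuracy, mean_auroc = cv$mean_auroc)
  })
  grid <- cbind(grid, do.call(rbind, res))
  list(grid = grid, best = grid[which.max(grid$mean_accuracy), ])
}
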