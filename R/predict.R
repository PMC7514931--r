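# Log class scores log R(x, C_k) for each row of Xnew, computed with a
# per-row shift (log-sum-exp) so that long kernel products cannot underflow.
log_class_scores <- function(model, Xnew) {
  L <- log_kernel_cross(Xnew, model$x,
                        model$params$lambdas, model$params$thetas)
  d <- length(model$levels)
  out <- matrix(NA_real_, nrow(Xnew), d)
  shift <- apply(L, 1L, max)
  E <- exp(L - shift)
  for (k in seq_len(d)) {
    out[, k] <- shift + log(rowSums(E[, model$class_ids == k, drop = FALSE]))
  }
  colnames(out) <- model$levels
  out
}

check_newdata <- function(model, newdata) {
  X <- as_feature_matrix(newdata)
  if (ncol(X) == 1L && ncol(model$x) > 1L &&
      nrow(X) == ncol(model$x)) {
    # a bare vector of one sample came in as a column
    X <- matrix(X, nrow = 1L)
  }
  if (ncol(X) != ncol(model$x)) {
    stop(sprintf("model has %d features but newdata has %d",
                 ncol(model$x), ncol(X)))
  }
  X
}

#' Per-class proximity scores
#'
#' Raw class scores \eqn{R(x, C_k) = \sum_{y \in C_k} Q(x - y)}: the summed
#' similarity of `newdata` to every stored training sample of class k.
#' Scores lie in \eqn{(0, m_k]}; larger classes naturally reach larger
#' sums (no per-class normalization is applied).
#'
#' @param model A fitted [lucck] model.
#' @param newdata Numeric vector (one sample) or matrix (one per row).
#' @return Numeric matrix, one row per sample, one column per class.
#' @export
class_scores <- function(model, newdata) {
  stopifnot(inherits(model, "lucck"))
  exp(log_class_scores(model, check_newdata(model, newdata)))
}

#' Class membership probabilities
#'
#' Normalized proximity scores \eqn{p_k = R(x, C_k) / R(x, C)}. If the
#' model carries learned class weights, the reweighting map
#' \eqn{W_\omega} is applied (see [apply_weights]).
#'
#' @param model A fitted [lucck] model.
#' @param newdata Numeric vector or matrix of samples.
#' @param reweight Apply the model's class weights, if present. Default:
#'   yes, when they exist.
#' @return Matrix of probabilities; each row is nonnegative and sums to 1.
#' @export
predict_proba <- function(model, newdata,
                          reweight = !is.null(model$class_weights)) {
  stopifnot(inherits(model, "lucck"))
  logR <- log_class_scores(model, check_newdata(model, newdata))
  shift <- apply(logR, 1L, max)
  E <- exp(logR - shift)
  P <- E / rowSums(E)
  if (isTRUE(reweight)) {
    if (is.null(model$class_weights)) {
      stop("model has no class weights; fit with reweight = TRUE")
    }
    P <- apply_weights(P, model$class_weights)
  }
  P
}

#' Predict classes or probabilities
#'
#' The predicted class maximizes the (possibly reweighted) class
#' probability; exact ties go to the class that comes first in the
#' model's level order.
#'
#' @param object A fitted [lucck] model.
#' @param newdata Numeric vector or matrix of samples.
#' @param type `"class"` (default) for labels, `"prob"` for the
#'   probability matrix, `"score"` for raw proximity sums.
#' @param ... Unused.
#' @return A factor of predicted labels, or a numeric matrix.
#' @export
predict.lucck <- function(object, newdata,
                          type = c("class", "prob", "score"), ...) {
  type <- match.arg(type)
  switch(type,
    score = class_scores(object, newdata),
    prob = predict_proba(object, newdata),
    class = {
      P <- predict_proba(object, newdata)
      factor(object$levels[max.col(P, ties.method = "first")],
             levels = object$levels)
    })
}

#' Leave-one-out class probabilities of the training set
#'
#' For every training sample x the probability table
#' \eqn{\tilde p_k(x) = R(x, C_k \setminus x) / R(x, C \setminus x)}:
#' how the model would classify its own training points using all other
#' points. This is the input to class-weight learning ([fit_weights]).
#'
#' @param model A fitted [lucck] model (every class needs >= 2 samples).
#' @return An m x d matrix; rows sum to 1.
#' @export
loo_probabilities <- function(model) {
  stopifnot(inherits(model, "lucck"))
  L <- log_kernel_cross(model$x, model$x,
                        model$params$lambdas, model$params$thetas)
  diag(L) <- -Inf                       # exclude the sample itself
  shift <- apply(L, 1L, max)
  E <- exp(L - shift)
  d <- length(model$levels)
  P <- matrix(NA_real_, nrow(model$x), d, dimnames = list(NULL, model$levels))
  for (k in seq_len(d)) {
    P[, k] <- rowSums(E[, model$class_ids == k, drop = FALSE])
  }
  P / rowSums(P)
}
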