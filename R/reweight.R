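#' Reweight a probability vector
#'
#' The multiplicative map \eqn{W_\omega(p)_l = \omega_l p_l / \sum_k \omega_k p_k}.
#' Weights all equal to 1 (or all scaled by a common constant) leave the
#' probabilities unchanged.
#'
#' @param p Probability vector, or matrix with one probability vector per
#'   row.
#' @param omegas Positive class weights, one per class.
#' @return Reweighted probabilities, same shape as `p`; rows sum to 1.
#' @examples
#' apply_weights(c(0.5, 0.5), c(1, 3))  # 0.25 0.75
#' @export
apply_weights <- function(p, omegas) {
  omegas <- as.numeric(omegas)
  if (any(!is.finite(omegas)) || any(omegas <= 0)) {
    stop("`omegas` must be finite and > 0")
  }
  vec <- is.null(dim(p))
  P <- if (vec) matrix(as.numeric(p), nrow = 1L) else as.matrix(p)
  if (ncol(P) != length(omegas)) {
    stop("length of `omegas` must match the number of classes")
  }
  W <- sweep(P, 2L, omegas, "*")
  denom <- rowSums(W)
  if (any(denom <= 0)) stop("reweighting denominator is zero")
  out <- W / denom
  if (vec) drop(out) else out
}

#' Linear surrogate for the total misclassification
#'
#' The reweighting objective actually optimized:
#' \deqn{\sum_j \max_k \{\omega_k \tilde p_k(x^{(j)})\} -
#'       \sum_k \omega_k \sum_{x \in C_k} \tilde p_k(x).}
#' It is a linearization of the total misclassification mass (whose exact
#' form divides by \eqn{\sum_l \omega_l \tilde p_l}; see
#' [misclassification_measure]) and is always nonnegative, reaching 0
#' when every row's own class attains the row maximum.
#'
#' @param table Leave-one-out probability matrix (m x d), e.g. from
#'   [loo_probabilities].
#' @param class_ids Integer class id (1..d) of each row.
#' @param omegas Class weights.
#' @return The surrogate objective value (>= 0).
#' @export
surrogate_objective <- function(table, class_ids, omegas) {
  P <- as.matrix(table)
  class_ids <- as.integer(class_ids)
  stopifnot(length(class_ids) == nrow(P),
            length(omegas) == ncol(P))
  W <- sweep(P, 2L, omegas, "*")
  own <- W[cbind(seq_len(nrow(P)), class_ids)]
  sum(apply(W, 1L, max)) - sum(own)
}

#' Exact (nonlinear) misclassification measure
#'
#' The quantity the linear surrogate approximates:
#' \eqn{\sum_j [\max_k \omega_k \tilde p_k - \omega_{k_j} \tilde p_{k_j}] /
#' \sum_l \omega_l \tilde p_l} with \eqn{k_j} the true class of row j.
#' Provided as a diagnostic only; it is not optimized.
#'
#' @inheritParams surrogate_objective
#' @return The misclassification mass (>= 0).
#' @export
misclassification_measure <- function(table, class_ids, omegas) {
  P <- as.matrix(table)
  class_ids <- as.integer(class_ids)
  stopifnot(length(class_ids) == nrow(P),
            length(omegas) == ncol(P))
  W <- sweep(P, 2L, omegas, "*")
  own <- W[cbind(seq_len(nrow(P)), class_ids)]
  sum((apply(W, 1L, max) - own) / rowSums(W))
}

#' Learn class weights by linear programming
#'
#' Minimizes the linear surrogate of the total misclassification over
#' weights \eqn{\omega_k \in [1, \omega_{max}]}, introducing one auxiliary
#' variable \eqn{z^{(j)} \ge \omega_k \tilde p_k(x^{(j)})} (for all k) per
#' row so the row maxima become linear constraints. The all-ones weight
#' vector is always feasible, so the returned weights never have a larger
#' surrogate objective than no reweighting.
#'
#' @param table Leave-one-out probability matrix (m x d).
#' @param class_ids Integer class id (1..d) of each row.
#' @param omega_max Upper bound on the weights. The optimal face of the LP
#'   contains unbounded scaling directions of objective value 0, so a box
#'   keeps the solver on a finite vertex. Default 100.
#' @return Numeric weight vector of length d, all entries in
#'   \eqn{[1, \omega_{max}]} (up to solver tolerance).
#' @export
fit_weights <- function(table, class_ids, omega_max = 100) {
  P <- as.matrix(table)
  class_ids <- as.integer(class_ids)
  m <- nrow(P); d <- ncol(P)
  if (m < 1L) stop("empty probability table")
  if (length(class_ids) != m) stop("`class_ids` must have one entry per row")
  if (any(class_ids < 1L | class_ids > d)) stop("class ids out of range 1..d")
  if (!is.finite(omega_max) || omega_max < 1) stop("`omega_max` must be >= 1")
  if (d == 1L) return(1)

  # Variables: (omega_1..omega_d, z_1..z_m).
  own_mass <- vapply(seq_len(d),
                     function(k) sum(P[class_ids == k, k]), numeric(1))
  objective <- c(-own_mass, rep(1, m))

  # z_j - omega_k p_jk >= 0 for all j, k; omega_k >= 1.
  A2 <- matrix(0, m * d + d, d + m)
  idx <- 0L
  for (k in seq_len(d)) {
    rows <- idx + seq_len(m)
    A2[cbind(rows, d + seq_len(m))] <- 1
    A2[rows, k] <- -P[, k]
    idx <- idx + m
  }
  A2[cbind(m * d + seq_len(d), seq_len(d))] <- 1
  b2 <- c(rep(0, m * d), rep(1, d))

  # omega_k <= omega_max.
  A1 <- matrix(0, d, d + m)
  A1[cbind(seq_len(d), seq_len(d))] <- 1
  b1 <- rep(omega_max, d)

  sol <- boot::simplex(a = objective, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                       maxi = FALSE, n.iter = 50L * (m + d))
  if (sol$solved != 1L) {
    stop(sprintf("class-weight LP did not converge (solver status %d)",
                 sol$solved))
  }
  omegas <- unname(sol$soln[seq_len(d)])
  pmin(pmax(omegas, 1), omega_max)
}
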