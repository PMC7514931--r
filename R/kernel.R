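#' Per-feature kernel parameters
#'
#' Bundles the per-feature widths \eqn{\lambda_i} and exponents
#' \eqn{\theta_i} with the global hyperparameters \eqn{\Lambda} and
#' \eqn{\Theta} that generated them. Together they fully determine the
#' product similarity function
#' \deqn{Q(x) = \prod_i (1 + \lambda_i x_i^2)^{-\theta_i}.}
#'
#' Each factor decays polynomially ("fat tail"), so a large deviation in a
#' single feature incurs only a moderate penalty — unlike a Gaussian kernel,
#' where one corrupted feature drives the whole product to zero.
#'
#' @param lambdas Positive numeric vector; \eqn{\lambda_i} controls the
#'   width of the kernel for feature i (units: 1/feature^2).
#' @param thetas Nonnegative numeric vector, same length; \eqn{\theta_i = 0}
#'   means feature i is ignored (its factor is identically 1).
#' @param capital_lambda Global width multiplier \eqn{\Lambda > 0}.
#' @param capital_theta Global mean exponent \eqn{\Theta > 0}.
#' @return An object of class `kernel_params`.
#' @examples
#' p <- kernel_params(lambdas = c(1, 0.25), thetas = c(1, 2))
#' similarity(c(0, 0), c(1, 2), p)  # 0.5 * 0.25
#' @export
kernel_params <- function(lambdas, thetas, capital_lambda = 1,
                          capital_theta = 1) {
  lambdas <- as.numeric(lambdas)
  thetas <- as.numeric(thetas)
  if (length(lambdas) != length(thetas)) {
    stop("`lambdas` and `thetas` must have the same length")
  }
  if (length(lambdas) < 1L) stop("at least one feature is required")
  if (!all(is.finite(lambdas)) || any(lambdas <= 0)) {
    stop("all `lambdas` must be finite and > 0")
  }
  if (!all(is.finite(thetas)) || any(thetas < 0)) {
    stop("all `thetas` must be finite and >= 0")
  }
  if (!is.finite(capital_lambda) || capital_lambda <= 0) {
    stop("`capital_lambda` must be finite and > 0")
  }
  if (!is.finite(capital_theta) || capital_theta <= 0) {
    stop("`capital_theta` must be finite and > 0")
  }
  structure(
    list(lambdas = lambdas, thetas = thetas,
         capital_lambda = capital_lambda, capital_theta = capital_theta),
    class = "kernel_params"
  )
}

#' @export
print.kernel_params <- function(x, ...) {
  n <- length(x$lambdas)
  cat(sprintf("Kernel parameters for %d feature%s (Lambda = %g, Theta = %g)\n",
              n, if (n == 1L) "" else "s",
              x$capital_lambda, x$capital_theta))
  cat("  lambda:", format(x$lambdas, digits = 4), "\n")
  cat("  theta: ", format(x$thetas, digits = 4), "\n")
  invisible(x)
}

#' Single-feature similarity kernel
#'
#' Evaluates \eqn{(1 + \lambda x^2)^{-\theta}} at a scalar feature
#' difference `x`. The value is 1 exactly when `x = 0` (or `theta = 0`) and
#' decreases polynomially in |x| — for `theta = 1` the shape matches a
#' Cauchy density up to normalization.
#'
#' @param x Numeric vector of feature differences.
#' @param lam Kernel width, > 0.
#' @param theta Kernel exponent, >= 0.
#' @return Similarities in (0, 1], same length as `x`.
#' @examples
#' kernel_value(1, lam = 1, theta = 1)     # 0.5
#' kernel_value(2, lam = 0.25, theta = 2)  # 0.25
#' @export
kernel_value <- function(x, lam, theta) {
  if (!all(is.finite(x))) stop("`x` must be finite")
  if (length(lam) != 1L || !is.finite(lam) || lam <= 0) {
    stop("`lam` must be a finite scalar > 0")
  }
  if (length(theta) != 1L || !is.finite(theta) || theta < 0) {
    stop("`theta` must be a finite scalar >= 0")
  }
  exp(-theta * log1p(lam * x * x))
}

# Log of the product kernel between every row of A and every row of B.
# Features with theta == 0 contribute a constant factor 1 and are skipped
# (this is also what makes constant features inert). Working in log space
# avoids underflow of long products; see the methods vignette.
log_kernel_cross <- function(A, B, lambdas, thetas) {
  L <- matrix(0, nrow(A), nrow(B))
  for (i in which(thetas > 0)) {
    D <- outer(A[, i], B[, i], "-")
    L <- L - thetas[i] * log1p(lambdas[i] * D * D)
  }
  L
}

#' Product similarity between two feature vectors
#'
#' \eqn{Q(x - y) = \prod_i (1 + \lambda_i (x_i - y_i)^2)^{-\theta_i}},
#' computed as the exponential of a sum of logarithms so that products over
#' hundreds of features do not underflow.
#'
#' @param x,y Numeric feature vectors of equal length.
#' @param params A [kernel_params] object of matching length.
#' @return A similarity in (0, 1]; 1 iff `x == y` or all exponents are 0.
#' @export
similarity <- function(x, y, params) {
  stopifnot(inherits(params, "kernel_params"))
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(params$lambdas)
  if (length(x) != n || length(y) != n) {
    stop(sprintf("expected vectors of length %d, got %d and %d",
                 n, length(x), length(y)))
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("inputs must be finite")
  d <- x - y
  exp(-sum(params$thetas * log1p(params$lambdas * d * d)))
}

#' Proximity of a point to a set of training samples
#'
#' The class score of the method: \eqn{R(x, Y) = \sum_{y \in Y} Q(x - y)}.
#' Every training sample contributes, weighted by its similarity, rather
#' than only the k nearest.
#'
#' @param x Numeric feature vector.
#' @param Y Numeric matrix, one training sample per row.
#' @param params A [kernel_params] object.
#' @return A value in (0, |Y|]; equals nrow(Y) iff every row equals `x`
#'   (or all exponents are 0).
#' @export
proximity <- function(x, Y, params) {
  stopifnot(inherits(params, "kernel_params"))
  Y <- as_feature_matrix(Y)
  if (nrow(Y) == 0L) stop("`Y` must contain at least one sample")
  x <- as.numeric(x)
  if (length(x) != ncol(Y) || length(x) != length(params$lambdas)) {
    stop("dimension mismatch between `x`, `Y` and `params`")
  }
  if (!all(is.finite(x))) stop("`x` must be finite")
  L <- log_kernel_cross(matrix(x, nrow = 1L), Y,
                        params$lambdas, params$thetas)
  sum(exp(L))
}

#' Proximity using a single feature
#'
#' The one-feature proximity used when scoring how well feature i separates
#' the classes: \eqn{R_i(x, Y) = \sum_{y \in Y} (1 + \lambda_i (x_i - y_i)^2)^{-\Theta}}.
#' Note the exponent is the global \eqn{\Theta}, not \eqn{\theta_i}: feature
#' relevance is scored before the per-feature exponents exist.
#'
#' @param x Numeric feature vector.
#' @param Y Numeric matrix of training samples.
#' @param i Feature index (1-based).
#' @param lam_i Width \eqn{\lambda_i > 0} for feature i.
#' @param capital_theta Global exponent \eqn{\Theta > 0}.
#' @return A value in (0, |Y|].
#' @export
single_feature_proximity <- function(x, Y, i, lam_i, capital_theta) {
  Y <- as_feature_matrix(Y)
  if (nrow(Y) == 0L) stop("`Y` must contain at least one sample")
  x <- as.numeric(x)
  if (length(x) != ncol(Y)) stop("dimension mismatch between `x` and `Y`")
  if (i < 1L || i > ncol(Y)) stop("feature index `i` out of range")
  if (!is.finite(lam_i) || lam_i <= 0) stop("`lam_i` must be > 0")
  if (!is.finite(capital_theta) || capital_theta <= 0) {
    stop("`capital_theta` must be > 0")
  }
  d <- x[i] - Y[, i]
  sum(exp(-capital_theta * log1p(lam_i * d * d)))
}

# Coerce tabular input to the numeric matrix the classifier works on.
as_feature_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.vector(X) && is.numeric(X)) X <- matrix(X, ncol = 1L)
  if (!is.matrix(X) || !is.numeric(X)) {
    stop("expected a numeric matrix or data frame of features")
  }
  storage.mode(X) <- "double"
  if (anyNA(X) || !all(is.finite(X))) {
    stop("feature matrix contains missing or non-finite values")
  }
  X
}
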