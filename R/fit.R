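#' Estimate per-feature kernel widths from feature spread
#'
#' Sets \eqn{\lambda_i = \Lambda / s_i^2}, where \eqn{s_i} is the standard
#' deviation of feature i over the training data. The log-kernel is most
#' sensitive to differences of size \eqn{\lambda_i^{-1/2}}, so this places
#' maximal sensitivity at about one standard deviation — and makes the whole
#' classifier invariant to per-feature rescaling.
#'
#' @param X Numeric feature matrix (m samples x n features), m >= 2.
#' @param capital_lambda Global width multiplier \eqn{\Lambda > 0}.
#' @param std Standard-deviation convention: `"population"` (divide by m,
#'   the default) or `"sample"` (divide by m - 1).
#' @return A list with `lambdas`, `stds`, and `constant` (logical flags for
#'   zero-spread features, whose lambda is a placeholder 1 and which are
#'   forced to exponent 0 downstream).
#' @export
estimate_lambdas <- function(X, capital_lambda = 1,
                             std = c("population", "sample")) {
  std <- match.arg(std)
  X <- as_feature_matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 samples to estimate feature spread")
  if (!is.finite(capital_lambda) || capital_lambda <= 0) {
    stop("`capital_lambda` must be finite and > 0")
  }
  stds <- unname(apply(X, 2L, column_std, convention = std))
  constant <- stds == 0
  lambdas <- ifelse(constant, 1, capital_lambda / stds^2)
  list(lambdas = lambdas, stds = stds, constant = constant)
}

column_std <- function(x, convention) {
  mu <- mean(x)
  if (convention == "population") {
    sqrt(mean((x - mu)^2))
  } else {
    sd(x)
  }
}

#' Score feature discriminability (alpha)
#'
#' For each feature i, compares the average leave-one-out single-feature
#' similarity of every sample to its own class against its average
#' similarity to the pooled training set:
#' \deqn{\alpha_i = \max\left(0, \sum_k \sum_{x \in C_k}
#'   \frac{R_i(x, C_k \setminus x)}{m_k - 1} -
#'   \frac{R_i(x, C \setminus x)}{m - 1}\right).}
#' Features whose values cluster within classes get large alpha; features
#' that look the same across classes get alpha near (or exactly) 0.
#'
#' @param X Numeric feature matrix.
#' @param labels Class labels, one per row; every class needs >= 2 samples.
#' @param lambdas Per-feature widths (from [estimate_lambdas]).
#' @param capital_theta Global exponent \eqn{\Theta} used in \eqn{R_i}.
#' @return Nonnegative numeric vector of length n.
#' @export
estimate_alphas <- function(X, labels, lambdas, capital_theta = 1) {
  X <- as_feature_matrix(X)
  cls <- encode_labels(labels, m = nrow(X))
  check_class_sizes(cls)
  if (length(lambdas) != ncol(X)) stop("`lambdas` length must match features")
  if (!is.finite(capital_theta) || capital_theta <= 0) {
    stop("`capital_theta` must be > 0")
  }
  m <- nrow(X)
  sizes <- tabulate(cls$ids, nbins = cls$d)
  own_size <- sizes[cls$ids]
  alphas <- numeric(ncol(X))
  for (i in seq_len(ncol(X))) {
    D <- outer(X[, i], X[, i], "-")
    K <- exp(-capital_theta * log1p(lambdas[i] * D * D))
    total <- rowSums(K) - 1        # drop the self term Q(0) = 1
    own <- numeric(m)
    for (k in seq_len(cls$d)) {
      in_k <- cls$ids == k
      own[in_k] <- rowSums(K[in_k, in_k, drop = FALSE]) - 1
    }
    alphas[i] <- max(0, sum(own / (own_size - 1) - total / (m - 1)))
  }
  alphas
}

#' Turn discriminability scores into kernel exponents
#'
#' Exponents keep the ratios of the alphas and sum to \eqn{n\Theta}, so
#' \eqn{\Theta} is the mean exponent:
#' \eqn{\theta_i = n \alpha_i \Theta / \sum_j \alpha_j}. If all alphas are 0
#' (no feature shows any class structure) the exponents fall back to the
#' uniform \eqn{\theta_i = \Theta}. Features flagged constant are excluded
#' from the normalization and pinned at \eqn{\theta_i = 0}.
#'
#' @param alphas Nonnegative discriminability scores.
#' @param capital_theta Global mean exponent \eqn{\Theta > 0}.
#' @param active Logical vector: which features participate (defaults to
#'   all). Constant features should be FALSE.
#' @return Numeric vector of exponents with
#'   `sum(thetas[active]) == sum(active) * capital_theta`.
#' @export
estimate_thetas <- function(alphas, capital_theta = 1, active = NULL) {
  alphas <- as.numeric(alphas)
  if (any(!is.finite(alphas)) || any(alphas < 0)) {
    stop("`alphas` must be finite and >= 0")
  }
  if (!is.finite(capital_theta) || capital_theta <= 0) {
    stop("`capital_theta` must be > 0")
  }
  n <- length(alphas)
  active <- active %||% rep(TRUE, n)
  if (length(active) != n) stop("`active` length must match `alphas`")
  thetas <- numeric(n)
  n_act <- sum(active)
  if (n_act == 0L) return(thetas)
  s <- sum(alphas[active])
  if (s > 0) {
    thetas[active] <- n_act * alphas[active] * capital_theta / s
  } else {
    thetas[active] <- capital_theta
  }
  thetas
}

#' Fit a LUCCK classifier
#'
#' LUCCK (Learning Using Concave and Convex Kernels) is an instance-based
#' classifier: it stores the training data and scores a test point against
#' class k by summing heavy-tailed per-feature product kernels over all of
#' class k's samples. Fitting estimates, per feature, a width
#' \eqn{\lambda_i = \Lambda / s_i^2} from the feature's spread and an
#' exponent \eqn{\theta_i} proportional to how well the feature alone
#' separates the classes (see [estimate_alphas]); irrelevant features are
#' driven toward \eqn{\theta_i = 0} and effectively ignored.
#'
#' @param x Numeric feature matrix or data frame (m samples x n features).
#' @param y Class labels (factor, character, or integer), one per sample;
#'   at least 2 classes, each with at least 2 samples.
#' @param capital_lambda Global kernel width \eqn{\Lambda > 0}. Default 1.
#' @param capital_theta Global mean exponent \eqn{\Theta > 0}. Default 1.
#' @param reweight If TRUE, also learn multiplicative class weights from
#'   the leave-one-out probability table via linear programming
#'   (see [fit_weights]); useful for imbalanced classes.
#' @param std Standard-deviation convention for the widths, `"population"`
#'   (default) or `"sample"`.
#' @param omega_max Upper bound on the learned class weights.
#' @param loo_fraction Fraction of training rows used to build the
#'   reweighting LP (1 = all rows, the default).
#' @param seed Seed used only when `loo_fraction < 1` subsamples rows.
#' @return An object of class `lucck` with components `x`, `class_ids`,
#'   `levels`, `class_sizes`, `params` ([kernel_params]), `alphas`, `stds`,
#'   `constant`, `std_convention`, `class_weights` (or NULL), and
#'   `feature_names`.
#' @examples
#' d <- simulate_dataset(sim_config(n_features = 4, n_informative = 2,
#'                                  samples_per_class = c(30, 30), seed = 1))
#' fit <- lucck(d$x, d$labels)
#' predict(fit, d$x[1:3, ])
#' @export
lucck <- function(x, y, capital_lambda = 1, capital_theta = 1,
                  reweight = FALSE, std = c("population", "sample"),
                  omega_max = 100, loo_fraction = 1, seed = 1L) {
  std <- match.arg(std)
  X <- as_feature_matrix(x)
  cls <- encode_labels(y, m = nrow(X))
  if (cls$d < 2L) stop("need at least 2 classes to fit a classifier")
  check_class_sizes(cls)

  est <- estimate_lambdas(X, capital_lambda, std = std)
  alphas <- estimate_alphas(X, cls$ids, est$lambdas, capital_theta)
  thetas <- estimate_thetas(alphas, capital_theta, active = !est$constant)
  params <- kernel_params(est$lambdas, thetas, capital_lambda, capital_theta)

  model <- structure(
    list(x = X,
         class_ids = cls$ids,
         levels = cls$levels,
         class_sizes = tabulate(cls$ids, nbins = cls$d),
         params = params,
         alphas = alphas,
         stds = est$stds,
         constant = est$constant,
         std_convention = std,
         class_weights = NULL,
         feature_names = colnames(X) %||%
           paste0("f", seq_len(ncol(X)))),
    class = "lucck")

  if (isTRUE(reweight)) {
    tab <- loo_probabilities(model)
    rows <- seq_len(nrow(tab))
    if (loo_fraction < 1) {
      n_keep <- max(cls$d, ceiling(loo_fraction * length(rows)))
      rows <- sort(with_seed(seed, sample(rows, n_keep)))
    }
    model$class_weights <- fit_weights(tab[rows, , drop = FALSE],
                                       cls$ids[rows],
                                       omega_max = omega_max)
  }
  model
}

#' @export
print.lucck <- function(x, ...) {
  cat(sprintf("LUCCK classifier: %d samples, %d features, %d classes\n",
              nrow(x$x), ncol(x$x), length(x$levels)))
  cat(sprintf("  Lambda = %g, Theta = %g (%s std)\n",
              x$params$capital_lambda, x$params$capital_theta,
              x$std_convention))
  cat("  class sizes:",
      paste(sprintf("%s=%d", x$levels, x$class_sizes), collapse = ", "), "\n")
  ord <- order(x$params$thetas, decreasing = TRUE)
  top <- utils::head(ord, 5L)
  cat("  largest exponents:",
      paste(sprintf("%s=%.3g", x$feature_names[top],
                    x$params$thetas[top]), collapse = ", "), "\n")
  if (!is.null(x$class_weights)) {
    cat("  class weights:",
        paste(sprintf("%.3g", x$class_weights), collapse = ", "), "\n")
  }
  invisible(x)
}

# Map arbitrary labels to integer ids 1..d plus the level vector.
encode_labels <- function(y, m = NULL) {
  if (!is.null(m) && length(y) != m) {
    stop(sprintf("expected %d labels, got %d", m, length(y)))
  }
  if (anyNA(y)) stop("labels contain missing values")
  f <- if (is.factor(y)) droplevels(y) else factor(y)
  list(ids = as.integer(f), levels = levels(f), d = nlevels(f))
}

check_class_sizes <- function(cls, min_size = 2L) {
  sizes <- tabulate(cls$ids, nbins = cls$d)
  bad <- which(sizes < min_size)
  if (length(bad)) {
    stop(sprintf("class '%s' has %d sample(s); at least %d are required",
                 cls$levels[bad[1L]], sizes[bad[1L]], min_size))
  }
  invisible(sizes)
}
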