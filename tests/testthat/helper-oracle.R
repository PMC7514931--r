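# Literal, unoptimized transcriptions of the method's defining formulas.
# These oracles deliberately use naive products and explicit loops — no
# log-space tricks, no matrix algebra — so they stay independent of the
# package implementation they are used to check.

oracle_kernel <- function(x, lam, theta) (1 + lam * x^2)^(-theta)

oracle_Q <- function(x, y, lambdas, thetas) {
  q <- 1
  for (i in seq_along(x)) {
    q <- q * (1 + lambdas[i] * (x[i] - y[i])^2)^(-thetas[i])
  }
  q
}

oracle_R <- function(x, Y, lambdas, thetas) {
  r <- 0
  for (j in seq_len(nrow(Y))) r <- r + oracle_Q(x, Y[j, ], lambdas, thetas)
  r
}

oracle_Ri <- function(xi, yi_set, lam_i, Theta) {
  r <- 0
  for (v in yi_set) r <- r + (1 + lam_i * (xi - v)^2)^(-Theta)
  r
}

# Full fit: population std -> lambda; leave-one-out alpha; ratio thetas.
oracle_fit <- function(X, cls, Lambda = 1, Theta = 1) {
  m <- nrow(X); n <- ncol(X); d <- max(cls)
  s <- numeric(n); lam <- numeric(n)
  for (i in seq_len(n)) {
    s[i] <- sqrt(mean((X[, i] - mean(X[, i]))^2))
    lam[i] <- Lambda / s[i]^2
  }
  mk <- tabulate(cls, d)
  alpha <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(m)) {
      k <- cls[j]
      own <- setdiff(which(cls == k), j)
      rest <- setdiff(seq_len(m), j)
      acc <- acc +
        oracle_Ri(X[j, i], X[own, i], lam[i], Theta) / (mk[k] - 1) -
        oracle_Ri(X[j, i], X[rest, i], lam[i], Theta) / (m - 1)
    }
    alpha[i] <- max(0, acc)
  }
  theta <- if (sum(alpha) > 0) n * alpha * Theta / sum(alpha) else rep(Theta, n)
  list(lambdas = lam, thetas = theta, alphas = alpha, stds = s)
}

oracle_proba <- function(fit, X, cls, x) {
  d <- max(cls)
  R <- numeric(d)
  for (k in seq_len(d)) {
    R[k] <- oracle_R(x, X[cls == k, , drop = FALSE],
                     fit$lambdas, fit$thetas)
  }
  R / sum(R)
}

oracle_predict <- function(fit, X, cls, x) {
  which.max(oracle_proba(fit, X, cls, x))   # first max = smallest class id
}

# O(N^2) discrete-Fourier-sum amplitude spectrum with the same one-sided
# conventions the package documents (mean removal, 2/N interior, 1/N
# Nyquist, DC excluded).
oracle_spectrum <- function(x, fs) {
  N <- length(x)
  xc <- x - mean(x)
  half <- floor(N / 2)
  t <- 0:(N - 1)
  amp <- vapply(seq_len(half), function(k) {
    re <- sum(xc * cos(2 * pi * k * t / N))
    im <- sum(xc * sin(2 * pi * k * t / N))
    2 * sqrt(re^2 + im^2) / N
  }, numeric(1))
  if (N %% 2 == 0) amp[half] <- amp[half] / 2
  list(frequency = seq_len(half) * fs / N, amplitude = amp)
}

# Exhaustive grid search for the reweighting LP. The surrogate objective
# is positively homogeneous in omega, so any optimum can be rescaled to
# have min(omega) = 1; the oracle therefore searches only the slices with
# one coordinate pinned at 1.
oracle_grid_weights <- function(P, cls, wmax, step) {
  d <- ncol(P)
  vals <- seq(1, wmax, by = step)
  best <- Inf
  for (pin in seq_len(d)) {
    free <- setdiff(seq_len(d), pin)
    grid <- as.matrix(expand.grid(rep(list(vals), length(free))))
    for (r in seq_len(nrow(grid))) {
      w <- numeric(d); w[pin] <- 1; w[free] <- grid[r, ]
      best <- min(best, surrogate_objective(P, cls, w))
    }
  }
  best
}

# Random probability table with row classes, for LP tests.
random_loo_table <- function(m, d) {
  P <- matrix(runif(m * d), m)
  P <- P / rowSums(P)
  list(P = P, cls = sample.int(d, m, replace = TRUE))
}

# Random labeled instance where every class has at least `min_per` rows.
random_instance <- function(m, n, d, min_per = 3L) {
  cls <- c(rep(seq_len(d), min_per),
           sample.int(d, m - d * min_per, replace = TRUE))
  X <- matrix(rnorm(m * n), m, n) + 0.8 * (cls %% 2)
  list(X = X, cls = cls)
}
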