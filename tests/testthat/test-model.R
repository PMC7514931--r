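test_that("estimate_lambdas ties widths to feature spread", {
  est <- estimate_lambdas(matrix(c(0, 2), 2, 1), capital_lambda = 1)
  expect_equal(est$stds, 1)        # population convention
  expect_equal(est$lambdas, 1)

  set.seed(7)
  X <- matrix(rnorm(40), 20, 2)
  c0 <- estimate_lambdas(X)$lambdas
  X2 <- X; X2[, 1] <- 5 * X2[, 1]
  c1 <- estimate_lambdas(X2)$lambdas
  expect_equal(c1[1], c0[1] / 25, tolerance = 1e-12)
  expect_equal(c1[2], c0[2])

  est <- estimate_lambdas(cbind(c(1, 1, 1), c(0, 1, 2)))
  expect_identical(est$constant, c(TRUE, FALSE))

  expect_equal(estimate_lambdas(matrix(c(0, 2), 2, 1), std = "sample")$stds,
               sd(c(0, 2)))
  expect_error(estimate_lambdas(matrix(1, 1, 1)), "at least 2")
})

test_that("estimate_alphas reproduces the worked example and edge cases", {
  X <- matrix(c(0, 0, 1, 1), 4, 1)
  y <- c(1, 1, 2, 2)
  expect_equal(estimate_alphas(X, y, lambdas = 1, capital_theta = 1), 4 / 3,
               tolerance = 1e-12)
  # a feature identical across samples separates nothing
  X2 <- cbind(X, 7)
  a <- estimate_alphas(X2, y, lambdas = c(1, 1), capital_theta = 1)
  expect_equal(a[2], 0)
  expect_error(estimate_alphas(X, c(1, 1, 1, 2), 1),
               "class '2' has 1 sample")
})

test_that("estimate_alphas matches the triple-loop oracle", {
  set.seed(8)
  for (rep in 1:12) {
    m <- sample(6:12, 1); n <- sample(1:4, 1)
    inst <- random_instance(m, n, d = 2, min_per = 2L)
    lam <- runif(n, 0.2, 3); Theta <- runif(1, 0.3, 2.5)
    got <- estimate_alphas(inst$X, inst$cls, lam, Theta)
    ref <- vapply(seq_len(n), function(i) {
      mk <- tabulate(inst$cls, 2)
      acc <- 0
      for (j in seq_len(m)) {
        k <- inst$cls[j]
        own <- setdiff(which(inst$cls == k), j)
        acc <- acc +
          oracle_Ri(inst$X[j, i], inst$X[own, i], lam[i], Theta) / (mk[k] - 1) -
          oracle_Ri(inst$X[j, i], inst$X[-j, i], lam[i], Theta) / (m - 1)
      }
      max(0, acc)
    }, numeric(1))
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("estimate_thetas preserves ratios and the sum constraint", {
  expect_equal(estimate_thetas(c(1, 1, 1), 2), c(2, 2, 2))
  expect_equal(estimate_thetas(c(2, 1, 1), 1), c(1.5, 0.75, 0.75))
  expect_equal(estimate_thetas(c(4 / 3, 0), 1), c(2, 0))
  # all-zero alphas fall back to the uniform exponent
  expect_equal(estimate_thetas(c(0, 0), 1.5), c(1.5, 1.5))
  # constant features are excluded from the normalization
  th <- estimate_thetas(c(3, 1, 0), 1, active = c(TRUE, TRUE, FALSE))
  expect_equal(th, c(1.5, 0.5, 0))
  expect_equal(sum(th), 2 * 1)
  expect_error(estimate_thetas(c(-1, 1)), ">= 0")
})

test_that("fit composes the estimators deterministically", {
  X <- matrix(c(0, 0, 1, 1), 4, 1)
  y <- c("a", "a", "b", "b")
  f <- lucck(X, y)
  expect_s3_class(f, "lucck")
  expect_equal(f$params$thetas, 1)          # n = 1 forces theta = Theta
  expect_equal(f$stds, 0.5)
  expect_equal(f$params$lambdas, 1 / 0.25)  # Lambda / s^2
  f2 <- lucck(X, y)
  expect_identical(f$params, f2$params)
  expect_error(lucck(X, rep("a", 4)), "at least 2 classes")
  expect_error(lucck(X, c("a", "a", "a", "b")), "class 'b'")
  expect_error(lucck(rbind(X, NA), c(y, "b")), "missing")
})

test_that("constant features are inert and flagged in the fit", {
  set.seed(9)
  X <- cbind(rnorm(20), 3, rnorm(20))
  y <- rep(c("a", "b"), 10)
  f <- lucck(X, y)
  expect_identical(f$constant, c(FALSE, TRUE, FALSE))
  expect_equal(f$params$thetas[2], 0)
  expect_equal(sum(f$params$thetas), 2 * f$params$capital_theta,
               tolerance = 1e-9)
  # predictions ignore the constant column entirely
  f2 <- lucck(X[, -2], y)
  Xnew <- cbind(rnorm(5), 3, rnorm(5))
  expect_equal(predict_proba(f, Xnew), predict_proba(f2, Xnew[, -2]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("class scores, probabilities, and predictions follow the kernels", {
  f <- lucck(matrix(c(0, 0, 1, 1), 4, 1), c(1, 1, 2, 2))
  f$params <- kernel_params(1, 1)           # pin the worked example params
  s <- class_scores(f, 0.1)
  expect_equal(drop(s), c("1" = 2 / 1.01, "2" = 2 / 1.81), tolerance = 1e-9)
  p <- predict_proba(f, 0.1)
  expect_equal(drop(p)[["1"]], 0.641844, tolerance = 1e-6)
  expect_equal(sum(p), 1)
  expect_equal(as.character(predict(f, 0.1)), "1")
  # theta -> 0: every kernel -> 1, scores -> class sizes
  f$params <- kernel_params(1, 1e-14)
  expect_equal(drop(class_scores(f, 0.37)), c("1" = 2, "2" = 2),
               tolerance = 1e-9)
  expect_error(class_scores(f, matrix(1:4, 2, 2)), "features")
})

test_that("exact ties break toward the first class level", {
  f <- lucck(matrix(c(-1, -1, 1, 1), 4, 1), c("a", "b", "a", "b"))
  # both classes are {-1, 1}: any x is exactly equidistant
  expect_equal(as.character(predict(f, 0.25)), "a")
  expect_equal(as.character(predict(f, c(0.25, -3, 0))), c("a", "a", "a"))
})

test_that("probabilities sum to one and reweighting hooks in", {
  set.seed(10)
  d <- simulate_dataset(sim_config(samples_per_class = c(20, 20), seed = 2))
  f <- lucck(d$x, d$labels)
  P <- predict_proba(f, matrix(rnorm(30), 5, 6))
  expect_equal(rowSums(P), rep(1, 5))
  expect_true(all(P >= 0))
  # uniform weights leave probabilities unchanged
  f$class_weights <- c(1, 1)
  expect_equal(predict_proba(f, d$x[1:4, ]),
               predict_proba(f, d$x[1:4, ], reweight = FALSE))
  f$class_weights <- NULL
  expect_error(predict_proba(f, d$x[1:2, ], reweight = TRUE), "no class weights")
})

test_that("leave-one-out probabilities match the hand-computed table", {
  f <- lucck(matrix(c(0, 0, 1, 1), 4, 1), c(1, 1, 2, 2))
  f$params <- kernel_params(1, 1)
  P <- loo_probabilities(f)
  expect_equal(P[1, ], c("1" = 0.5, "2" = 0.5), tolerance = 1e-12)
  expect_equal(rowSums(P), rep(1, 4))
  set.seed(11)
  d <- simulate_dataset(sim_config(samples_per_class = c(15, 15), seed = 3))
  P <- loo_probabilities(lucck(d$x, d$labels))
  expect_equal(rowSums(P), rep(1, 30))
  # widely separated classes with huge exponents: own-class prob -> 1
  Xs <- matrix(c(rnorm(10, 0, 0.01), rnorm(10, 50, 0.01)), ncol = 1)
  fs <- lucck(Xs, rep(1:2, each = 10))
  fs$params <- kernel_params(fs$params$lambdas, 50)
  Ps <- loo_probabilities(fs)
  expect_true(all(Ps[cbind(1:20, rep(1:2, each = 10))] > 0.999))
})

test_that("per-feature rescaling leaves the model invariant", {
  set.seed(12)
  for (rep in 1:10) {
    inst <- random_instance(m = 25, n = 4, d = 2)
    Xte <- matrix(rnorm(20), 5, 4)
    f1 <- lucck(inst$X, inst$cls)
    cs <- runif(4, 0.01, 100)
    f2 <- lucck(sweep(inst$X, 2, cs, "*"), inst$cls)
    expect_equal(f2$params$thetas, f1$params$thetas, tolerance = 1e-9)
    expect_equal(predict_proba(f2, sweep(Xte, 2, cs, "*")),
                 predict_proba(f1, Xte), tolerance = 1e-9)
    expect_identical(predict(f2, sweep(Xte, 2, cs, "*")), predict(f1, Xte))
  }
})

test_that("duplicating a test point inside a class never lowers its probability", {
  set.seed(13)
  for (rep in 1:10) {
    inst <- random_instance(m = 20, n = 3, d = 2)
    f <- lucck(inst$X, inst$cls)
    x <- rnorm(3)
    p0 <- drop(predict_proba(f, x))
    # append a duplicate of x to class 1, keeping the kernel params fixed
    f$x <- rbind(f$x, x)
    f$class_ids <- c(f$class_ids, 1L)
    f$class_sizes[1] <- f$class_sizes[1] + 1L
    p1 <- drop(predict_proba(f, x))
    expect_gte(p1[1] + 1e-12, p0[1])
  }
})

test_that("fit matches the full literal oracle on small instances", {
  set.seed(14)
  for (rep in 1:10) {
    m <- sample(9:20, 1); n <- sample(1:4, 1); d <- sample(2:3, 1)
    inst <- random_instance(m, n, d)
    Lam <- runif(1, 0.2, 5); The <- runif(1, 0.3, 3)
    f <- lucck(inst$X, inst$cls, capital_lambda = Lam, capital_theta = The)
    o <- oracle_fit(inst$X, inst$cls, Lam, The)
    expect_equal(f$params$thetas, o$thetas, tolerance = 1e-10)
    x <- rnorm(n)
    expect_equal(drop(predict_proba(f, x)),
                 oracle_proba(o, inst$X, inst$cls, x),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("informative features earn larger exponents than noise", {
  hits <- vapply(1:10, function(s) {
    d <- simulate_dataset(sim_config(n_features = 6, n_informative = 3,
                                     samples_per_class = c(50, 50),
                                     separation = 2, seed = s))
    f <- lucck(d$x, d$labels)
    mean(f$params$thetas[1:3]) > mean(f$params$thetas[4:6])
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
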