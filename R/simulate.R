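#' Configuration for the synthetic tabular generator
#'
#' Describes a labeled dataset with the statistical structure the
#' classifier targets: a few informative features whose class means are
#' separated, the rest pure noise; optionally heavy-tailed (Student-t)
#' noise and sporadic large single-feature corruptions emulating
#' measurement errors in wearable recordings; samples grouped into
#' subjects for group-aware cross-validation.
#'
#' @param n_features Total number of features.
#' @param n_informative How many features carry class signal
#'   (`<= n_features`).
#' @param samples_per_class Integer vector of per-class sample counts
#'   (length = number of classes, each >= 2).
#' @param separation Distance between consecutive class means on each
#'   informative feature, in units of the noise scale.
#' @param noise `"gaussian"` or `"heavy_tailed"` (Student-t).
#' @param df Degrees of freedom for the heavy-tailed family; `df = 1` is
#'   Cauchy.
#' @param noise_scale Scale of the per-feature noise (Gaussian sd, or the
#'   t scale parameter).
#' @param corruption_rate Probability that a sample has one uniformly
#'   chosen feature replaced by an extreme outlier.
#' @param corruption_scale Outlier magnitude, in noise-scale units.
#' @param n_groups Number of subject groups; samples are assigned
#'   round-robin to groups within each class, so a group can contain
#'   samples of several classes (as a patient contributes both good and
#'   bad nights).
#' @param group_effect Sd of an optional shared per-group offset added to
#'   all features (0 = off, the default).
#' @param seed Integer seed fixing all randomness.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_features = 6, n_informative = 3,
                       samples_per_class = c(100, 100), separation = 2,
                       noise = c("gaussian", "heavy_tailed"), df = 3,
                       noise_scale = 1, corruption_rate = 0,
                       corruption_scale = 10, n_groups = 10,
                       group_effect = 0, seed = 1L) {
  noise <- match.arg(noise)
  samples_per_class <- as.integer(samples_per_class)
  if (n_features < 1L || n_informative < 0L || n_informative > n_features) {
    stop("need 0 <= n_informative <= n_features, n_features >= 1")
  }
  if (length(samples_per_class) < 1L || any(samples_per_class < 2L)) {
    stop("every class needs at least 2 samples")
  }
  if (!is.finite(separation) || separation < 0) stop("`separation` must be >= 0")
  if (!is.finite(df) || df <= 0) stop("`df` must be > 0")
  if (!is.finite(noise_scale) || noise_scale <= 0) {
    stop("`noise_scale` must be > 0")
  }
  if (!is.finite(corruption_rate) || corruption_rate < 0 ||
      corruption_rate > 1) {
    stop("`corruption_rate` must be in [0, 1]")
  }
  if (!is.finite(corruption_scale) || corruption_scale < 0) {
    stop("`corruption_scale` must be >= 0")
  }
  if (n_groups < 1L) stop("`n_groups` must be >= 1")
  structure(
    list(n_features = as.integer(n_features),
         n_informative = as.integer(n_informative),
         samples_per_class = samples_per_class,
         separation = separation, noise = noise, df = df,
         noise_scale = noise_scale, corruption_rate = corruption_rate,
         corruption_scale = corruption_scale,
         n_groups = as.integer(n_groups), group_effect = group_effect,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Generate a labeled synthetic dataset
#'
#' Informative feature i of a class-k sample is drawn around the mean
#' \eqn{\mu_{ik} = \pm (k - 1) \cdot separation \cdot noise\_scale}
#' (sign alternating by feature, so classes separate in different
#' directions); non-informative features are identically distributed
#' across classes. With probability `corruption_rate` a sample has one
#' uniformly chosen feature replaced by
#' \eqn{\mu \pm corruption\_scale \cdot noise\_scale}, leaving all other
#' features untouched. Output is bit-identical for a fixed seed.
#'
#' @param config A [sim_config].
#' @return List with `x` (numeric matrix, columns `f1..fn`), `labels`
#'   (factor `c1..cd`), `groups` (integer subject ids), and `config`.
#' @examples
#' d <- simulate_dataset(sim_config(seed = 42))
#' table(d$labels, d$groups)[, 1:5]
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  d <- length(cfg$samples_per_class)
  m <- sum(cfg$samples_per_class)
  n <- cfg$n_features
  labels <- rep(seq_len(d), cfg$samples_per_class)

  with_seed(cfg$seed, {
    draw <- function(count) {
      if (cfg$noise == "gaussian") rnorm(count, sd = cfg$noise_scale)
      else cfg$noise_scale * rt(count, df = cfg$df)
    }
    X <- matrix(draw(m * n), m, n)
    # class means on informative features; sign alternates by feature
    M <- matrix(0, m, n)
    if (cfg$n_informative > 0L) {
      for (i in seq_len(cfg$n_informative)) {
        sgn <- if (i %% 2L == 1L) 1 else -1
        M[, i] <- sgn * (labels - 1L) * cfg$separation * cfg$noise_scale
      }
    }
    X <- X + M

    # sporadic single-feature corruption
    hit <- runif(m) < cfg$corruption_rate
    if (any(hit)) {
      feat <- sample.int(n, sum(hit), replace = TRUE)
      sign <- sample(c(-1, 1), sum(hit), replace = TRUE)
      X[cbind(which(hit), feat)] <-
        M[cbind(which(hit), feat)] +
        sign * cfg$corruption_scale * cfg$noise_scale

    }

    # round-robin group assignment within class
    groups <- integer(m)
    for (k in seq_len(d)) {
      idx <- which(labels == k)
      groups[idx] <- ((seq_along(idx) - 1L) %% cfg$n_groups) + 1L
    }
    if (cfg$group_effect > 0) {
      offs <- rnorm(cfg$n_groups, sd = cfg$group_effect)
      X <- X + offs[groups]
    }

    colnames(X) <- paste0("f", seq_len(n))
    list(x = X,
         labels = factor(paste0("c", labels),
                         levels = paste0("c", seq_len(d))),
         groups = groups,
         config = cfg)
  })
}

#' Generate a two-class imbalanced dataset
#'
#' Same generator as [simulate_dataset], restricted to two classes whose
#' sizes follow the requested minority/majority ratio: the majority count
#' is the first entry of `samples_per_class`, the minority count is
#' `round(ratio * majority)`.
#'
#' @param config A [sim_config] (its first per-class count is the
#'   majority size).
#' @param ratio Minority/majority ratio in (0, 1].
#' @return As [simulate_dataset]; class `c1` is the majority.
#' @export
simulate_imbalanced <- function(config, ratio) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.finite(ratio) || ratio <= 0 || ratio > 1) {
    stop("`ratio` must be in (0, 1]")
  }
  majority <- config$samples_per_class[1L]
  minority <- max(2L, as.integer(round(ratio * majority)))
  config$samples_per_class <- c(majority, minority)
  simulate_dataset(config)
}
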