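#' A uniformly sampled signal window
#'
#' Light container for a stretch of a single-channel signal (e.g. blood
#' volume pulse, electrodermal activity, or skin temperature from a wrist
#' wearable) together with its sampling rate.
#'
#' @param samples Finite numeric vector, length >= 2 (signal units).
#' @param sampling_rate Sampling frequency in Hz, > 0.
#' @return An object of class `signal_window`.
#' @export
signal_window <- function(samples, sampling_rate) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("a window needs at least 2 samples")
  if (!all(is.finite(samples))) stop("window samples must be finite")
  if (length(sampling_rate) != 1L || !is.finite(sampling_rate) ||
      sampling_rate <= 0) {
    stop("`sampling_rate` must be a positive scalar (Hz)")
  }
  structure(list(samples = samples, sampling_rate = sampling_rate),
            class = "signal_window")
}

#' @export
print.signal_window <- function(x, ...) {
  cat(sprintf("signal window: %d samples @ %g Hz (%.3g s)\n",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate))
  invisible(x)
}

as_window <- function(w) {
  if (inherits(w, "signal_window")) return(w)
  stop("expected a `signal_window` (see signal_window())")
}

#' Basic time-domain statistics of a window
#'
#' Mean, population standard deviation, variance (= std^2), power, and
#' median. Power is the *mean* of the squared samples, not the sum, so
#' windows of different lengths stay comparable.
#'
#' @param w A [signal_window].
#' @return Named numeric vector: `mean`, `std`, `var`, `power`, `median`.
#' @examples
#' basic_stats(signal_window(c(1, 2, 3, 4), 1))
#' @export
basic_stats <- function(w) {
  x <- as_window(w)$samples
  mu <- mean(x)
  v <- mean((x - mu)^2)
  c(mean = mu, std = sqrt(v), var = v, power = mean(x^2),
    median = median(x))
}

#' Extremes plus basic statistics of a window
#'
#' The bundle used for slowly varying rate-like signals: maximum, minimum,
#' range, mean, population standard deviation, and power (mean square).
#'
#' @param w A [signal_window].
#' @return Named numeric vector: `max`, `min`, `range`, `mean`, `std`,
#'   `power`.
#' @export
range_stats <- function(w) {
  x <- as_window(w)$samples
  mu <- mean(x)
  c(max = max(x), min = min(x), range = max(x) - min(x), mean = mu,
    std = sqrt(mean((x - mu)^2)), power = mean(x^2))
}

#' One-sided amplitude spectrum
#'
#' The discrete Fourier amplitude spectrum of the mean-removed window,
#' folded to one side: interior bins are scaled by 2/N, the Nyquist bin
#' (even N) by 1/N, and the DC bin is excluded (the mean is removed first,
#' so it is ~0 anyway). With these conventions a pure sinusoid of amplitude
#' A sitting exactly on a bin shows amplitude A, and the time-domain power
#' satisfies `mean(x^2) == mean(x)^2 + sum(interior amp^2)/2 + nyquist^2`.
#'
#' @param w A [signal_window] with at least 4 samples.
#' @return A data frame with columns `frequency` (Hz) and `amplitude`.
#' @export
amplitude_spectrum <- function(w) {
  w <- as_window(w)
  x <- w$samples
  N <- length(x)
  if (N < 4L) stop("need at least 4 samples for a spectrum")
  F <- fft(x - mean(x))
  half <- floor(N / 2)
  k <- seq_len(half)                     # DC (k = 0) excluded
  amp <- 2 * Mod(F[k + 1L]) / N
  if (N %% 2L == 0L) amp[half] <- Mod(F[half + 1L]) / N  # Nyquist
  data.frame(frequency = k * w$sampling_rate / N, amplitude = amp)
}

#' Spectral features of a window
#'
#' Six features of the one-sided amplitude spectrum (see
#' [amplitude_spectrum]): the frequency with the highest peak, its
#' amplitude, total spectral power (sum of squared one-sided amplitudes),
#' the mean and the median of the amplitudes, and the amplitude-weighted
#' mean frequency (spectral centroid). On an all-zero spectrum (constant
#' signal) peak frequency and centroid are reported as 0 so that every
#' feature stays finite.
#'
#' @param w A [signal_window] with at least 4 samples.
#' @return Named numeric vector: `peak_freq`, `peak_amp`, `fft_power`,
#'   `mean_amp`, `mean_freq`, `median_amp`.
#' @export
spectral_features <- function(w) {
  sp <- amplitude_spectrum(w)
  a <- sp$amplitude
  f <- sp$frequency
  total <- sum(a)
  if (total > 0) {
    peak <- which.max(a)
    peak_freq <- f[peak]
    peak_amp <- a[peak]
    centroid <- sum(f * a) / total
  } else {
    peak_freq <- 0; peak_amp <- 0; centroid <- 0
  }
  c(peak_freq = peak_freq, peak_amp = peak_amp, fft_power = sum(a^2),
    mean_amp = mean(a), mean_freq = centroid, median_amp = median(a))
}

#' Brick-wall band-pass filter
#'
#' Zeroes every Fourier bin whose frequency falls outside `[low, high]`
#' (the conjugate-symmetric bins are zeroed together, so the output is
#' real) and transforms back. Used to split a signal into low/mid/high
#' bands before feature extraction; the cutoffs are entirely up to the
#' caller.
#'
#' @param w A [signal_window].
#' @param low,high Band edges in Hz, `0 <= low < high`.
#' @return A new [signal_window] at the same sampling rate.
#' @export
bandpass_filter <- function(w, low, high) {
  w <- as_window(w)
  if (!is.finite(low) || !is.finite(high) || low < 0 || high <= low) {
    stop("need 0 <= low < high (Hz)")
  }
  x <- w$samples
  N <- length(x)
  freqs <- seq(0L, N - 1L) * w$sampling_rate / N
  freqs <- pmin(freqs, w$sampling_rate - freqs)   # fold to [0, fs/2]
  F <- fft(x)
  F[freqs < low | freqs > high] <- 0
  signal_window(Re(fft(F, inverse = TRUE)) / N, w$sampling_rate)
}

feature_bundles <- list(basic = basic_stats,
                        spectral = spectral_features,
                        range = range_stats)

#' Build a feature table from signal windows
#'
#' Applies a recipe of feature bundles to each window-set and stacks the
#' results into one row per window-set. A window-set is a named list of
#' [signal_window]s (one per signal, e.g. `list(bvp = ..., eda = ...)`);
#' the recipe names, per signal, which bundles to extract: any of
#' `"basic"` (5 features), `"spectral"` (6), `"range"` (6). Columns are
#' named `<signal>.<feature>` in deterministic recipe order. Window-sets
#' with a missing signal or a non-finite feature value are dropped with a
#' message and reported in `excluded`.
#'
#' @param windows List of window-sets; names become row ids.
#' @param recipe Named list: signal name -> character vector of bundles.
#' @return List with `x` (numeric feature matrix with column names and
#'   row ids), `ids`, and `excluded` (ids of dropped window-sets).
#' @examples
#' w <- list(s1 = list(bvp = signal_window(sin(1:64), 64)))
#' extract_table(w, list(bvp = c("basic", "spectral")))$x
#' @export
extract_table <- function(windows, recipe) {
  if (!length(windows)) stop("no windows supplied")
  if (!length(recipe) || is.null(names(recipe))) {
    stop("`recipe` must be a named list: signal -> feature bundles")
  }
  bad <- setdiff(unlist(recipe), names(feature_bundles))
  if (length(bad)) {
    stop(sprintf("unknown feature bundle(s): %s (choose from %s)",
                 paste(bad, collapse = ", "),
                 paste(names(feature_bundles), collapse = ", ")))
  }
  ids <- names(windows) %||% as.character(seq_along(windows))

  one_row <- function(ws) {
    out <- numeric(0)
    for (sig in names(recipe)) {
      if (is.null(ws[[sig]])) return(NULL)
      for (b in recipe[[sig]]) {
        v <- feature_bundles[[b]](ws[[sig]])
        names(v) <- paste(sig, names(v), sep = ".")
        out <- c(out, v)
      }
    }
    out
  }

  rows <- lapply(windows, one_row)
  ok <- !vapply(rows, is.null, logical(1))
  ok[ok] <- vapply(rows[ok], function(r) all(is.finite(r)), logical(1))
  if (any(!ok)) {
    message(sprintf("excluding %d window-set(s) with missing signals or non-finite features: %s",
                    sum(!ok), paste(ids[!ok], collapse = ", ")))
  }
  if (!any(ok)) stop("all window-sets were excluded")
  X <- do.call(rbind, rows[ok])
  rownames(X) <- ids[ok]
  list(x = X, ids = ids[ok], excluded = ids[!ok])
}
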