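test_that("signal_window validates its invariants", {
  expect_error(signal_window(1, 10), "at least 2")
  expect_error(signal_window(c(1, NA), 10), "finite")
  expect_error(signal_window(c(1, 2), 0), "positive")
  w <- signal_window(c(1, 2), 4)
  expect_s3_class(w, "signal_window")
})

test_that("basic_stats matches hand arithmetic", {
  expect_equal(basic_stats(signal_window(rep(3, 8), 1)),
               c(mean = 3, std = 0, var = 0, power = 9, median = 3))
  expect_equal(basic_stats(signal_window(c(-1, 1), 1)),
               c(mean = 0, std = 1, var = 1, power = 1, median = 0))
  got <- basic_stats(signal_window(c(1, 2, 3, 4), 1))
  expect_equal(got[["mean"]], 2.5)
  expect_equal(got[["var"]], 1.25)       # population variance
  expect_equal(got[["power"]], 7.5)
  expect_equal(got[["median"]], 2.5)     # even length: midpoint
})

test_that("range_stats matches hand arithmetic", {
  expect_equal(range_stats(signal_window(rep(2, 5), 1)),
               c(max = 2, min = 2, range = 0, mean = 2, std = 0, power = 4))
  expect_equal(range_stats(signal_window(c(-1, 1), 1)),
               c(max = 1, min = -1, range = 2, mean = 0, std = 1, power = 1))
  got <- range_stats(signal_window(c(1, 2, 3, 4), 1))
  expect_equal(got[["range"]], 3)
  expect_equal(got[["std"]], sqrt(1.25), tolerance = 1e-12)
  expect_equal(got[["power"]], 7.5)
})

test_that("an on-bin sinusoid is recovered exactly", {
  fs <- 64; N <- 128; A <- 2.5; f0 <- 8
  t <- (0:(N - 1)) / fs
  w <- signal_window(A * sin(2 * pi * f0 * t) + 1.7, fs)
  sp <- spectral_features(w)
  expect_equal(sp[["peak_freq"]], f0)
  expect_equal(sp[["peak_amp"]], A, tolerance = 1e-6)
  expect_equal(sp[["mean_freq"]], f0, tolerance = 1e-6)
})

test_that("the centroid of two equal sinusoids is their midpoint", {
  fs <- 64; N <- 256
  t <- (0:(N - 1)) / fs
  x <- sin(2 * pi * 4 * t) + sin(2 * pi * 12 * t)
  sp <- spectral_features(signal_window(x, fs))
  expect_equal(sp[["mean_freq"]], 8, tolerance = 1e-9)
})

test_that("spectral features match the O(N^2) Fourier-sum oracle", {
  set.seed(51)
  for (N in c(32, 65, 100)) {
    x <- rnorm(N)
    fs <- 10
    got <- amplitude_spectrum(signal_window(x, fs))
    ref <- oracle_spectrum(x, fs)
    expect_equal(got$frequency, ref$frequency, tolerance = 1e-12)
    expect_equal(got$amplitude, ref$amplitude, tolerance = 1e-9)
    f <- spectral_features(signal_window(x, fs))
    expect_equal(f[["fft_power"]], sum(ref$amplitude^2), tolerance = 1e-9)
    expect_equal(f[["median_amp"]], median(ref$amplitude), tolerance = 1e-9)
  }
})

test_that("the documented power identity holds (both parities)", {
  set.seed(52)
  for (N in c(64, 101)) {
    x <- rnorm(N, mean = 3)
    w <- signal_window(x, 5)
    sp <- amplitude_spectrum(w)
    a <- sp$amplitude
    spectral_side <- if (N %% 2 == 0) {
      sum(a[-length(a)]^2) / 2 + a[length(a)]^2
    } else {
      sum(a^2) / 2
    }
    expect_equal(basic_stats(w)[["power"]],
                 mean(x)^2 + spectral_side, tolerance = 1e-9)
  }
})

test_that("amplitude features are invariant to circular shifts", {
  fs <- 32; N <- 128
  t <- (0:(N - 1)) / fs
  x <- sin(2 * pi * 3 * t) + 0.4 * sin(2 * pi * 9 * t)
  f1 <- spectral_features(signal_window(x, fs))
  shifted <- c(x[40:N], x[1:39])
  f2 <- spectral_features(signal_window(shifted, fs))
  expect_equal(f2, f1, tolerance = 1e-9)
})

test_that("all features stay finite on degenerate input", {
  w <- signal_window(rep(1.5, 16), 4)
  expect_true(all(is.finite(spectral_features(w))))
  expect_true(all(is.finite(basic_stats(w))))
  expect_error(spectral_features(signal_window(c(1, 2), 1)), "at least 4")
})

test_that("bandpass_filter keeps in-band and removes out-of-band tones", {
  fs <- 64; N <- 256
  t <- (0:(N - 1)) / fs
  x <- sin(2 * pi * 4 * t) + sin(2 * pi * 20 * t)
  lo <- bandpass_filter(signal_window(x, fs), 1, 10)
  sp <- spectral_features(lo)
  expect_equal(sp[["peak_freq"]], 4)
  expect_lt(abs(sp[["peak_amp"]] - 1), 1e-9)
  expect_equal(sum(amplitude_spectrum(lo)$amplitude > 0.01), 1)
  expect_error(bandpass_filter(signal_window(x, fs), 5, 2), "low < high")
})

test_that("extract_table stacks recipe features per window-set", {
  set.seed(53)
  mk <- function(seed) {
    set.seed(seed)
    list(sigA = signal_window(rnorm(64), 8),
         sigB = signal_window(rnorm(32), 4))
  }
  windows <- list(w1 = mk(1), w2 = mk(2), w3 = mk(3))
  tab <- extract_table(windows, list(sigA = "basic"))
  expect_equal(dim(tab$x), c(3L, 5L))
  expect_identical(colnames(tab$x),
                   paste0("sigA.", c("mean", "std", "var", "power", "median")))
  # deterministic: same input gives identical matrices
  expect_identical(extract_table(windows, list(sigA = "basic"))$x, tab$x)
  # the 11-feature statistical + spectral bundle of one signal
  tab11 <- extract_table(windows, list(sigA = c("basic", "spectral")))
  expect_equal(ncol(tab11$x), 11L)
  # two signals, mixed bundles, deterministic order
  tab2 <- extract_table(windows, list(sigA = "spectral", sigB = "range"))
  expect_equal(ncol(tab2$x), 12L)
  expect_true(all(startsWith(colnames(tab2$x)[1:6], "sigA.")))
})

test_that("extract_table flags and drops incomplete window-sets", {
  windows <- list(ok = list(s = signal_window(rnorm(16), 4)),
                  bad = list(other = signal_window(rnorm(16), 4)))
  expect_message(tab <- extract_table(windows, list(s = "basic")), "bad")
  expect_equal(tab$ids, "ok")
  expect_equal(tab$excluded, "bad")
  expect_error(extract_table(windows, list(s = "nope")), "unknown feature")
  expect_error(extract_table(list(), list(s = "basic")), "no windows")
})
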