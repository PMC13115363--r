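# Expected differential-entropy values frozen from numerical quadrature of
# the definition -integral f ln f with a Gaussian density (see the
# quadrature oracle in test-acceptance.R):
#   sigma^2 = 1  ->  1.41893853  (= 0.5 * ln(2*pi*e))

test_that("differential entropy matches the Gaussian closed form", {
  set.seed(1)
  # closed-form zero point: variance 1/(2*pi*e)
  x <- rnorm(4096)
  x0 <- x / sd(x) * sqrt(1 / (2 * pi * exp(1)))
  expect_equal(differential_entropy(x0), 0, tolerance = 1e-8)
  x1 <- x / sd(x)
  expect_equal(differential_entropy(x1), 1.41893853, tolerance = 1e-6)
  # scaling by c adds ln|c|
  expect_equal(differential_entropy(3.7 * x1),
               differential_entropy(x1) + log(3.7), tolerance = 1e-8)
  # strictly increasing in variance
  de <- vapply(c(0.1, 0.5, 1, 2, 10),
               function(s2) differential_entropy(x1 * sqrt(s2)), numeric(1))
  expect_true(all(diff(de) > 0))
  # degenerate window: floored with a warning
  expect_warning(v <- differential_entropy(rep(2, 64), floor = -20),
                 "constant")
  expect_equal(v, -20)
  expect_error(differential_entropy(1), "at least 2")
})

test_that("band-pass keeps in-band tones and rejects far-out tones", {
  fs <- 128
  t <- seq_len(5 * fs) / fs
  tone <- sin(2 * pi * 10 * t)             # 10 Hz, inside alpha
  a <- bandpass(tone, 8, 13, fs)
  g <- bandpass(tone, 31, 45, fs)
  expect_gte(sd(a), 0.9 * sd(tone))
  expect_lte(sd(g), 0.05 * sd(tone))
  expect_error(bandpass(tone, 31, 70, fs), "Nyquist")
})

test_that("per-band power of filtered white noise matches the periodogram integral", {
  set.seed(42)
  fs <- 128; n <- 16384
  x <- rnorm(n)
  per <- Mod(stats::fft(x))^2 / n
  freqs <- (0:(n - 1)) * fs / n
  pos <- freqs > 0 & freqs <= fs / 2
  bands <- eeg_bands()
  for (i in seq_len(nrow(bands))) {
    inb <- freqs >= bands$low[i] & freqs <= bands$high[i]
    oracle <- sum(per[inb & pos]) / sum(per[pos])
    filt <- bandpass(x, bands$low[i], bands$high[i], fs)
    got <- sum(filt^2) / sum(x^2)
    expect_equal(got, oracle, tolerance = 0.1,
                 label = paste0(bands$name[i], " band power fraction"))
  }
})

test_that("windowing is a contiguous order-preserving partition", {
  fs <- 128
  w <- window_segments(rnorm(60 * fs), fs, 0.5)
  expect_length(w, 120L)
  expect_true(all(lengths(w) == 64L))
  x <- seq_len(3 * fs)
  w2 <- window_segments(x, fs, 0.5)
  expect_identical(unlist(w2), x)          # partition, order preserved
  expect_length(window_segments(rnorm(64), fs, 0.5), 1L)
  expect_warning(w0 <- window_segments(rnorm(51), fs, 0.5), "shorter")
  expect_length(w0, 0L)
  expect_error(window_segments(rnorm(100), fs, 0.3), "whole number")
})

test_that("baseline DE averages the six preparation windows", {
  set.seed(5)
  fs <- 128
  prep <- matrix(rnorm(2 * 3 * fs), 2)
  b <- baseline_de(prep, fs = fs)
  expect_equal(dim(b), c(2L, 4L))
  # stationary signal: baseline close to any single window's DE
  filt <- bandpass(prep[1, ], 14, 30, fs)
  w <- window_segments(filt, fs, 0.5)
  des <- vapply(w, differential_entropy, numeric(1))
  expect_equal(b[1, 3], mean(des), tolerance = 1e-10)
  expect_lt(abs(b[1, 3] - des[1]), 0.5)
  expect_error(baseline_de(prep[, 1:100], fs = fs), "expected")
})

test_that("baseline correction is element-wise subtraction", {
  m <- matrix(rnorm(8), 2)
  b <- matrix(rnorm(8), 2)
  expect_equal(correct_baseline(m, m), matrix(0, 2, 4))
  expect_equal(correct_baseline(m, matrix(0, 2, 4)), m)
  a2 <- matrix(rnorm(8), 2)
  expect_equal(correct_baseline(m + a2, b), correct_baseline(m, b) + a2)
  expect_error(correct_baseline(m, matrix(0, 4, 2)), "shapes")
})

test_that("grid mapping conserves totals and zero-fills empty cells", {
  lay <- deap_layout()
  v <- rnorm(32)
  g <- map_to_grid(v, lay)
  expect_equal(dim(g), c(8L, 9L))
  expect_equal(sum(g), sum(v))
  expect_equal(sum(g == 0), 72L - 32L)
  expect_equal(map_to_grid(rep(0, 32), lay), matrix(0, 8, 9))
  expect_error(map_to_grid(rnorm(30), lay), "32")
  # values land at their layout positions
  i <- 17L
  expect_equal(g[lay$entries$row[i] + 1L, lay$entries$col[i] + 1L], v[i])
})

test_that("sample extraction yields 20 tensors of shape (6,4,8,9) per trial", {
  set.seed(9)
  proto <- protocol_spec(n_channels = 8L)
  rec <- generate_eeg(proto, class_spec(channels = 1:2), n_trials = 2)
  lay <- tiny_layout()
  samples <- extract_samples(rec$trials[[1]], lay)
  expect_length(samples, 20L)
  expect_equal(dim(samples[[1]]), c(6L, 4L, 8L, 9L))
  expect_length(as.vector(samples[[1]]), 1728L)
  expect_equal(attr(samples[[1]], "label"), rec$labels[1])
  # window grouping partitions the 120 task windows in order
  spans <- t(vapply(samples, attr, numeric(2), "step_span"))
  expect_equal(spans[, 1], seq(1, 115, by = 6))
  expect_equal(spans[, 2], seq(6, 120, by = 6))
  # non-electrode cells are zero in every step and band
  grid_occ <- matrix(FALSE, 8, 9)
  grid_occ[cbind(lay$entries$row + 1, lay$entries$col + 1)] <- TRUE
  for (s in samples[1:3]) {
    empty_ok <- apply(s, c(1, 2), function(g) all(g[!grid_occ] == 0))
    expect_true(all(empty_ok))
  }
  expect_error(extract_samples(rec$trials[[1]], deap_layout()), "match")
})

test_that("the feature pipeline is deterministic", {
  set.seed(11)
  proto <- protocol_spec(n_channels = 4L)
  rec <- generate_eeg(proto, class_spec(channels = 1L), n_trials = 1)
  lay <- electrode_layout(data.frame(channel = paste0("c", 1:4),
                                     row = 0:3, col = 0:3))
  s1 <- extract_samples(rec$trials[[1]], lay)
  s2 <- extract_samples(rec$trials[[1]], lay)
  expect_identical(s1, s2)
})

test_that("a channel with elevated beta power has the largest beta-band DE", {
  set.seed(13)
  fs <- 128
  n <- round(63 * fs)
  sig <- matrix(rnorm(4 * n), 4)
  t <- seq_len(n) / fs
  task_span <- (3 * fs + 1):n
  # beta tone on channel 3, task span only (the baseline must not carry it,
  # or baseline correction would cancel the effect)
  sig[3, task_span] <- sig[3, task_span] + 3 * sin(2 * pi * 20 * t[task_span])
  lay <- electrode_layout(data.frame(channel = paste0("c", 1:4),
                                     row = 0:3, col = 0:3))
  trial <- eeg_trial(sig, fs)
  samples <- extract_samples(trial, lay)
  beta_mean <- Reduce(`+`, lapply(samples, function(s)
    apply(s[, 3, , ], c(2, 3), mean))) / length(samples)
  occupied <- cbind(lay$entries$row + 1, lay$entries$col + 1)
  vals <- beta_mean[occupied]
  expect_equal(which.max(vals), 3L)
})
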