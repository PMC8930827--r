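test_that("band-pass removes slow drift and preserves in-band tones", {
  fs <- 400
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  drift <- sin(2 * pi * 0.1 * t)
  rec <- lfp_recording(cbind(drift, drift), fs, c("a", "b"))
  out <- bandpass(rec, 1, 150)
  expect_equal(nrow(out$data), nrow(rec$data))
  expect_lt(var(out$data[, 1]), 0.05 * var(rec$data[, 1]))
  tone <- sin(2 * pi * 30 * t)
  rec30 <- lfp_recording(cbind(tone, tone), fs, c("a", "b"))
  out30 <- bandpass(rec30, 1, 150)
  mid <- seq_along(t) > fs & seq_along(t) < length(t) - fs
  expect_lt(abs(rms(out30$data[mid, 1]) / rms(tone[mid]) - 1), 0.01)
})

test_that("band corners beyond Nyquist are rejected", {
  rec <- tone_recording(10, fs = 400, duration = 5)
  expect_error(bandpass(rec, 1, 200), "fs/2")
  expect_error(bandpass(rec, 0, 150), "fs/2")
})

test_that("notch attenuates the line tone >= 30 dB and spares 35 Hz < 1 dB", {
  rec60 <- tone_recording(60, fs = 400, duration = 20)
  out60 <- notch(rec60, 60)
  mid <- 2001:6000
  expect_lt(rms(out60$data[mid, 1]), 0.032 * rms(rec60$data[mid, 1]))
  rec35 <- tone_recording(35, fs = 400, duration = 20)
  out35 <- notch(rec35, c(60, 120))
  ratio_db <- 20 * log10(rms(out35$data[mid, 1]) / rms(rec35$data[mid, 1]))
  expect_lt(abs(ratio_db), 1)
})

test_that("notch frequencies at or above Nyquist are skipped with a warning", {
  rec <- tone_recording(10, fs = 400, duration = 5)
  expect_warning(out <- notch(rec, c(60, 240)), "Nyquist")
  expect_warning(notch(rec, numeric(0)), "empty")
})

test_that("zero-phase filters introduce no lag", {
  fs <- 400
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 20 * t)
  rec <- lfp_recording(cbind(x, x), fs, c("a", "b"))
  for (out in list(bandpass(rec, 1, 150), notch(rec, 60))) {
    cc <- ccf(out$data[2001:3000, 1], x[2001:3000], lag.max = 5, plot = FALSE)
    expect_equal(cc$lag[which.max(cc$acf)], 0)
  }
})

test_that("filtering is near-idempotent in the passband", {
  spec <- study_spec(couplings = list(), seed = 12,
                     noise = nuisance_spec(line_amp = 0, artifact_prob = 0))
  rec <- simulate_recording(build_state_var(spec, "naive"), 30,
                            nuisance = spec$noise, seed = 1)
  once <- bandpass(rec, 1, 150)
  twice <- bandpass(once, 1, 150)
  mid <- 1001:11000
  rel <- rms(twice$data[mid, 1] - once$data[mid, 1]) / rms(once$data[mid, 1])
  expect_lt(rel, 0.05)
})

test_that("resampling anti-aliases at 45% of the target rate", {
  # integer ratio: length and rate arithmetic
  rec <- tone_recording(100, fs = 1200, duration = 1)
  out <- resample_recording(rec, 400)
  expect_equal(out$fs, 400)
  expect_equal(nrow(out$data), 400)
  # 100 Hz tone is far below the 180 Hz cutoff: amplitude preserved
  rec2 <- tone_recording(100, fs = 1200, duration = 10)
  out2 <- resample_recording(rec2, 400)
  mid <- 1001:3000
  expect_lt(abs(rms(out2$data[mid, 1]) / rms(rec2$data[, 1]) - 1), 0.05)
  # 190 Hz tone is above the cutoff: attenuated >= 20 dB
  rec3 <- tone_recording(190, fs = 1200, duration = 10)
  out3 <- resample_recording(rec3, 400)
  att_db <- 20 * log10(rms(out3$data[mid, 1]) / rms(rec3$data[, 1]))
  expect_lt(att_db, -20)
  expect_error(resample_recording(out, 400), "below")
})

test_that("non-integer resampling ratios are supported", {
  rec <- tone_recording(50, fs = 1000, duration = 10)
  out <- resample_recording(rec, 400)   # ratio 2/5
  expect_equal(out$fs, 400)
  expect_equal(nrow(out$data), 4000, tolerance = 2)
  mid <- 1001:3000
  expect_lt(abs(rms(out$data[mid, 1]) / rms(rec$data[, 1]) - 1), 0.05)
})

test_that("segmentation partitions the recording and discards the remainder", {
  fs <- 100
  rec <- lfp_recording(matrix(rnorm(2 * 2760 * fs), ncol = 2), fs,
                       c("a", "b"), state = "naive", session_id = "s1")
  segs <- split_segments(rec, 300)
  expect_length(segs, 9)            # floor(2760 / 300)
  expect_equal(vapply(segs, function(s) s$index, integer(1)), 0:8)
  recon <- do.call(rbind, lapply(segs, function(s) s$data))
  expect_identical(recon, rec$data[1:(9 * 300 * fs), ])
  expect_length(split_segments(rec, 2760), 1)
  short <- lfp_recording(matrix(rnorm(2 * 299 * fs), ncol = 2), fs,
                         c("a", "b"))
  expect_warning(empty <- split_segments(short, 300), "shorter")
  expect_length(empty, 0)
})

test_that("normalization yields zero mean and unit variance per channel", {
  rec <- tone_recording(c(10, 25), fs = 200, duration = 5, amp = 3)
  seg <- split_segments(rec, 5)[[1]]
  nseg <- normalize_segment(seg)
  expect_lt(max(abs(colMeans(nseg$data))), 1e-10)
  expect_lt(max(abs(apply(nseg$data, 2, var) - 1)), 1e-10)
  const <- lfp_recording(cbind(rnorm(100), rep(1, 100)), 10, c("a", "b"))
  expect_error(normalize_segment(const), "'b'")
})

test_that("GC is invariant to channel scaling and to normalization", {
  set.seed(55)
  m <- random_var2(coef_sd = 0.3)
  L <- chol(m$sigma)
  X <- lfpgc:::.var_simulate_cpp(m$A, matrix(rnorm(2 * 12000), ncol = 2) %*% L,
                                 2000)
  F1 <- time_gc(X, mode = "bivariate", p = 2)
  Xs <- X; Xs[, 1] <- 40 * Xs[, 1]; Xs[, 2] <- 0.01 * Xs[, 2]
  F2 <- time_gc(Xs, mode = "bivariate", p = 2)
  expect_lt(max(abs(F1 - F2), na.rm = TRUE), 1e-6)
  Xn <- scale(X)
  F3 <- time_gc(Xn, mode = "bivariate", p = 2)
  expect_lt(max(abs(F1 - F3), na.rm = TRUE), 1e-6)
})
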