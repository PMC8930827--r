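test_that("oscillator pole placement follows the closed form", {
  a <- place_oscillator_poles(15, 0.95, 400)
  expect_equal(a[1], 2 * 0.95 * cos(2 * pi * 15 / 400), tolerance = 1e-12)
  expect_equal(a[1], 1.84754, tolerance = 1e-4)
  expect_equal(a[2], -0.9025, tolerance = 1e-12)
  # degenerate radius gives white noise
  expect_equal(place_oscillator_poles(15, 0, 400), c(0, 0))
  # cos term vanishes at quarter-Nyquist
  a4 <- place_oscillator_poles(100, 0.8, 400)
  expect_equal(a4[1], 0, tolerance = 1e-12)
  expect_equal(a4[2], -0.64)
  expect_error(place_oscillator_poles(15, 1, 400), "stable")
  expect_error(place_oscillator_poles(250, 0.9, 400), "Nyquist|inside")
})

test_that("the placed AR(2) spectrum peaks near the target frequency", {
  a <- place_oscillator_poles(35, 0.9, 400)
  m <- var_model(array(a, c(1, 1, 2)), matrix(1), fs = 400)
  f <- seq(1, 199, by = 0.5)
  H <- lfpgc:::transfer_function(m, f)
  S <- Mod(H[1, 1, ])^2
  expect_true(abs(f[which.max(S)] - 35) < 3)
})

test_that("state models are stable and block-diagonal without couplings", {
  spec0 <- study_spec(couplings = list(), seed = 1)
  m <- build_state_var(spec0, "naive")
  expect_lt(m$radius, 1)
  off <- m$A
  for (j in seq_len(m$p)) diag(off[, , j]) <- 0
  expect_equal(max(abs(off)), 0)
  # analytic GC of the generating model is exactly zero for every pair
  F <- time_gc(m, mode = "conditional", q_max = 150)
  expect_lt(max(F, na.rm = TRUE), 1e-6)
})

test_that("planted couplings produce the expected ground-truth signs", {
  spec <- study_spec(seed = 2)
  for (st in spec$states) expect_lt(build_state_var(spec, st)$radius, 1)
  gt <- generate_study(
    study_spec(sessions_per_state = 1, session_duration = 30,
               seed = 2))$ground_truth$signs
  pick <- function(src, tgt, band, tr)
    gt$sign[gt$source == src & gt$target == tgt & gt$band == band &
              gt$transition == tr]
  expect_equal(pick("L-PMC", "L-STN", "peakA", "naive -> mild"), -1)
  expect_equal(pick("L-STN", "L-PMC", "peakB", "naive -> mild"), 1)
  expect_equal(pick("R-M1", "R-PMC", "peakB", "naive -> mild"), 1)
  expect_equal(pick("R-M1", "R-PMC", "peakB", "mild -> moderate"), 1)
  expect_equal(pick("L-PMC", "L-STN", "peakA", "mild -> moderate"), 0)
})

test_that("a coupling multiplier active only in mild yields a + sign", {
  cp <- coupling_spec("L-STN", "L-PMC", 35, 0.1,
                      c(naive = 0, mild = 1, moderate = 1))
  spec <- study_spec(couplings = list(cp), sessions_per_state = 1,
                     session_duration = 30, seed = 3)
  gt <- lfpgc:::ground_truth_signs(spec)
  expect_equal(gt$sign[gt$band == "peakB" &
                         gt$transition == "naive -> mild"], 1)
})

test_that("simulated recordings have the contracted length and determinism", {
  spec <- study_spec(seed = 4)
  m <- build_state_var(spec, "naive")
  r1 <- simulate_recording(m, duration = 30, fs = 400,
                           nuisance = spec$noise, seed = 9)
  expect_equal(nrow(r1$data), 30 * 400)
  r2 <- simulate_recording(m, duration = 30, fs = 400,
                           nuisance = spec$noise, seed = 9)
  expect_identical(r1$data, r2$data)
  r3 <- simulate_recording(m, duration = 30, fs = 400,
                           nuisance = spec$noise, seed = 10)
  expect_false(identical(r1$data, r3$data))
})

test_that("line noise shows as a local PSD maximum at 60 Hz before notching", {
  spec <- study_spec(couplings = list(),
                     noise = nuisance_spec(line_amp = 2, artifact_prob = 0),
                     seed = 5)
  m <- build_state_var(spec, "naive")
  rec <- simulate_recording(m, 60, nuisance = spec$noise, seed = 6)
  ps <- welch_psd(rec, window_len = 2)
  i60 <- which(ps$freqs == 60)
  expect_true(all(ps$values[i60, ] > ps$values[i60 - 2, ]))
  expect_true(all(ps$values[i60, ] > ps$values[i60 + 2, ]))
})

test_that("clean simulated spectra peak inside both analysis bands", {
  spec <- study_spec(couplings = list(),
                     noise = nuisance_spec(pink_amp = 0, line_amp = 0,
                                           artifact_prob = 0),
                     seed = 7)
  m <- build_state_var(spec, "naive")
  rec <- simulate_recording(m, 120, nuisance = spec$noise, seed = 8)
  ps <- welch_psd(rec)
  for (ch in 1:5) {
    inA <- ps$freqs >= 5 & ps$freqs <= 20
    inB <- ps$freqs >= 25 & ps$freqs <= 45
    fA <- ps$freqs[inA][which.max(ps$values[inA, ch])]
    fB <- ps$freqs[inB][which.max(ps$values[inB, ch])]
    expect_true(fA > 5 && fA < 20)
    expect_true(fB > 25 && fB < 45)
  }
})

test_that("generate_study tags recordings by state and is reproducible", {
  spec <- study_spec(sessions_per_state = c(3, 2, 1), session_duration = 10,
                     seed = 11)
  st <- generate_study(spec)
  states <- vapply(st$recordings, function(r) r$state, character(1))
  expect_equal(as.numeric(table(states)[spec$states]), c(3, 2, 1))
  expect_equal(length(st$recordings), 6)
  st2 <- generate_study(spec)
  expect_identical(lapply(st$recordings, `[[`, "data"),
                   lapply(st2$recordings, `[[`, "data"))
})

test_that("study specs reject inconsistent inputs", {
  expect_error(study_spec(channels = c("a", "a", "b")), "unique")
  expect_error(coupling_spec("x", "x", 15, 0.1, c(naive = 1)), "differ")
  expect_error(coupling_spec("x", "y", 15, -0.1, c(naive = 1)), ">= 0")
  expect_error(study_spec(oscillator_freqs = c(15, 300)), "Nyquist")
  bad <- coupling_spec("L-PMC", "L-M1", 15, 0.1, c(naive = 1))
  expect_error(study_spec(couplings = list(bad)), "multipliers")
})
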