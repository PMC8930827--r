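#' Specify a planted directed coupling
#'
#' A coupling injects band-limited influence from one channel onto another
#' in the generating VAR model. The coupling acts through a short FIR filter
#' on the source channel whose gain is normalized to `strength` at
#' `center_freq` and which nulls the other oscillator frequency, so the
#' induced Granger-causal spectrum peaks near `center_freq`. Per-state
#' multipliers scale the coupling so that connectivity differences between
#' disease states can be planted with a known sign.
#'
#' @param source,target Channel labels (must differ).
#' @param center_freq Coupling center frequency in Hz.
#' @param strength Coupling gain at `center_freq` (dimensionless, >= 0).
#' @param state_multipliers Named numeric vector mapping each state label to
#'   a multiplier >= 0.
#' @return A `coupling_spec` object.
#' @export
coupling_spec <- function(source, target, center_freq, strength,
                          state_multipliers) {
  if (identical(source, target)) stop("coupling source must differ from target")
  if (strength < 0) stop("coupling strength must be >= 0")
  if (center_freq <= 0) stop("center_freq must be positive")
  if (is.null(names(state_multipliers)) || any(state_multipliers < 0))
    stop("state_multipliers must be a named vector of nonnegative values")
  structure(list(source = source, target = target,
                 center_freq = center_freq, strength = strength,
                 state_multipliers = state_multipliers),
            class = "coupling_spec")
}

#' Specify the nuisance (non-neural) signal components
#'
#' @param pink_exponent Exponent alpha of the 1/f^alpha background.
#' @param pink_amp Standard deviation of the pink-noise component, relative
#'   to the unit innovation scale of the VAR process.
#' @param line_freq Mains frequency in Hz.
#' @param line_amp Amplitude of the mains sinusoid (its 2nd and 3rd
#'   harmonics are added at 1/2 and 1/3 of this amplitude). Set 0 to disable.
#' @param artifact_prob Probability that a whole recording is inflated by a
#'   movement-artifact gain.
#' @param artifact_gain Multiplicative gain applied to artifact recordings.
#' @return A `nuisance_spec` object.
#' @export
nuisance_spec <- function(pink_exponent = 1, pink_amp = 0.5,
                          line_freq = 60, line_amp = 0.5,
                          artifact_prob = 0.05, artifact_gain = 10) {
  if (pink_exponent < 0) stop("pink_exponent must be >= 0")
  if (artifact_prob < 0 || artifact_prob > 1)
    stop("artifact_prob must be in [0, 1]")
  structure(list(pink_exponent = pink_exponent, pink_amp = pink_amp,
                 line_freq = line_freq, line_amp = line_amp,
                 artifact_prob = artifact_prob, artifact_gain = artifact_gain),
            class = "nuisance_spec")
}

#' Default planted coupling network
#'
#' The three directed couplings planted by default in synthetic studies,
#' mirroring the headline disease pattern: the descending cortico-
#' subthalamic drive (L-PMC to L-STN, 15 Hz) weakens at disease onset,
#' the ascending subthalamo-cortical drive (L-STN to L-PMC, 35 Hz)
#' strengthens, and the right cortico-cortical drive (R-M1 to R-PMC,
#' 35 Hz) strengthens across both state transitions.
#'
#' @return A list of [coupling_spec()] objects.
#' @export
default_couplings <- function() {
  list(
    # descending cortico-subthalamic coupling, low band: drops at disease onset
    coupling_spec("L-PMC", "L-STN", center_freq = 15, strength = 0.15,
                  state_multipliers = c(naive = 1, mild = 0.3, moderate = 0.3)),
    # ascending subthalamo-cortical coupling, high band: rises at disease onset
    coupling_spec("L-STN", "L-PMC", center_freq = 35, strength = 0.15,
                  state_multipliers = c(naive = 0.2, mild = 1, moderate = 1)),
    # right cortico-cortical coupling, high band: rises across both transitions
    coupling_spec("R-M1", "R-PMC", center_freq = 35, strength = 0.15,
                  state_multipliers = c(naive = 0.2, mild = 0.9, moderate = 1.8))
  )
}

#' Specify a synthetic multi-state LFP study
#'
#' Defines the generating model for a study with multiple disease states and
#' multiple recording sessions per state. Each channel carries damped
#' oscillators at `oscillator_freqs` (AR(2) resonators multiplied into one
#' AR polynomial), directed couplings are planted per [coupling_spec()], and
#' nuisance components per [nuisance_spec()].
#'
#' @param channels Ordered channel labels (default: the five-node montage
#'   L-PMC, L-M1, R-PMC, R-M1, L-STN).
#' @param fs Sampling rate in Hz.
#' @param states Ordered state labels.
#' @param sessions_per_state Integer vector (recycled) of session counts per
#'   state; the default mirrors a 15/16/5-session design.
#' @param session_duration Session length in seconds.
#' @param couplings List of [coupling_spec()] objects.
#' @param oscillator_freqs Oscillator center frequencies in Hz.
#' @param oscillator_radii Pole radii of the resonators (one per frequency,
#'   recycled); closer to 1 means a sharper spectral peak.
#' @param noise A [nuisance_spec()].
#' @param seed Integer seed controlling every random draw of the study.
#' @return A `study_spec` object.
#' @export
study_spec <- function(channels = LFPGC_CHANNELS, fs = 400,
                       states = LFPGC_STATES,
                       sessions_per_state = c(15L, 16L, 5L),
                       session_duration = 1800,
                       couplings = default_couplings(),
                       oscillator_freqs = c(15, 35),
                       oscillator_radii = c(0.95, 0.95),
                       noise = nuisance_spec(), seed = 1L) {
  if (anyDuplicated(channels)) stop("channel labels must be unique")
  sessions_per_state <- rep_len(as.integer(sessions_per_state), length(states))
  oscillator_radii <- rep_len(oscillator_radii, length(oscillator_freqs))
  line_max <- if (noise$line_amp > 0) 3 * noise$line_freq else 0
  cf <- vapply(couplings, function(cc) cc$center_freq, numeric(1))
  if (length(cf) && fs <= 2 * max(cf))
    stop("fs must exceed twice the largest coupling frequency")
  if (any(oscillator_freqs >= fs / 2))
    stop("oscillator frequencies must lie below Nyquist")
  for (cc in couplings) {
    if (!cc$source %in% channels || !cc$target %in% channels)
      stop("coupling references unknown channel")
    missing <- setdiff(states, names(cc$state_multipliers))
    if (length(missing))
      stop("coupling lacks multipliers for state(s): ",
           paste(missing, collapse = ", "))
  }
  structure(list(channels = channels, fs = fs, states = states,
                 sessions_per_state = sessions_per_state,
                 session_duration = session_duration,
                 couplings = couplings,
                 oscillator_freqs = oscillator_freqs,
                 oscillator_radii = oscillator_radii,
                 noise = noise, seed = as.integer(seed)),
            class = "study_spec")
}

#' Place an AR(2) resonator at a target frequency
#'
#' Returns the coefficients `(a1, a2) = (2 r cos(2 pi f0 / fs), -r^2)` of an
#' AR(2) process with complex-conjugate poles at radius `r` and angle
#' `2 pi f0 / fs`; its spectrum has a local maximum near `f0`.
#'
#' @param center_freq Resonance frequency in Hz, in `(0, fs/2)`.
#' @param pole_radius Pole radius in `[0, 1)`.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector `c(a1, a2)`.
#' @export
place_oscillator_poles <- function(center_freq, pole_radius, fs) {
  if (pole_radius < 0 || pole_radius >= 1)
    stop("pole_radius must be in [0, 1) for a stable oscillator")
  if (center_freq <= 0 || center_freq >= fs / 2)
    stop("center_freq must lie strictly inside (0, fs/2)")
  w <- 2 * pi * center_freq / fs
  c(2 * pole_radius * cos(w), -pole_radius^2)
}

# multiply AR polynomials: coefficients a_j of (1 - sum a_j L^j)
ar_poly_multiply <- function(a, b) {
  pa <- c(1, -a); pb <- c(1, -b)
  conv <- rep(0, length(pa) + length(pb) - 1)
  for (i in seq_along(pa)) conv[i:(i + length(pb) - 1)] <-
      conv[i:(i + length(pb) - 1)] + pa[i] * pb
  -conv[-1]
}

# FIR coupling filter on the source channel: taps at lags 1..L, gain
# `strength` at the coupling frequency, exact nulls at the other oscillator
# frequencies (so the transmitted energy concentrates near center_freq).
coupling_taps <- function(center_freq, strength, fs, null_freqs) {
  b <- 1
  for (f in null_freqs) {
    w <- 2 * pi * f / fs
    b <- convolve_taps(b, c(1, -2 * cos(w), 1))
  }
  wc <- 2 * pi * center_freq / fs
  gain <- abs(sum(b * exp(-1i * wc * (seq_along(b) - 1))))
  if (gain < 1e-12) stop("degenerate coupling filter (center on a null)")
  b * strength / gain
}

convolve_taps <- function(a, b) {
  out <- rep(0, length(a) + length(b) - 1)
  for (i in seq_along(a)) out[i:(i + length(b) - 1)] <-
      out[i:(i + length(b) - 1)] + a[i] * b
  out
}

#' Build the generating VAR model for one study state
#'
#' Diagonal dynamics are the product of the AR(2) resonators placed at the
#' study's oscillator frequencies; each coupling contributes its FIR taps,
#' scaled by `strength * state_multipliers[state]`, to the off-diagonal
#' coefficients. If the assembled model is unstable, all cross-couplings are
#' shrunk uniformly (factor 0.7 per iteration) until the companion spectral
#' radius falls below 1; any rescaling is recorded in the returned model's
#' `rescale` attribute.
#'
#' @param spec A [study_spec()].
#' @param state State label present in `spec$states`.
#' @return A stable `var_model` for the requested state.
#' @export
build_state_var <- function(spec, state) {
  stopifnot(inherits(spec, "study_spec"))
  if (!state %in% spec$states) stop("unknown state: ", state)
  n <- length(spec$channels)
  diag_poly <- 1
  for (i in seq_along(spec$oscillator_freqs)) {
    osc <- place_oscillator_poles(spec$oscillator_freqs[i],
                                  spec$oscillator_radii[i], spec$fs)
    diag_poly <- if (identical(diag_poly, 1)) osc
                 else ar_poly_multiply(diag_poly, osc)
  }
  p_diag <- length(diag_poly)
  tap_list <- lapply(spec$couplings, function(cc) {
    nulls <- setdiff(spec$oscillator_freqs, cc$center_freq)
    coupling_taps(cc$center_freq,
                  cc$strength * cc$state_multipliers[[state]],
                  spec$fs, nulls)
  })
  p <- max(p_diag, vapply(tap_list, length, integer(1)), 1L)
  A_diag <- array(0, dim = c(n, n, p))
  for (j in seq_len(p_diag)) A_diag[, , j] <- diag(diag_poly[j], n)
  A_cross <- array(0, dim = c(n, n, p))
  for (i in seq_along(spec$couplings)) {
    cc <- spec$couplings[[i]]
    taps <- tap_list[[i]]
    si <- match(cc$source, spec$channels)
    ti <- match(cc$target, spec$channels)
    for (j in seq_along(taps))
      A_cross[ti, si, j] <- A_cross[ti, si, j] + taps[j]
  }
  scale <- 1
  for (iter in 0:25) {
    A <- A_diag + scale * A_cross
    m <- var_model(A, diag(n), fs = spec$fs, channels = spec$channels)
    if (m$radius < 1 - 1e-6) {
      attr(m, "rescale") <- scale
      attr(m, "state") <- state
      return(m)
    }
    scale <- scale * 0.7
  }
  stop("could not stabilize the state model after 25 rescale iterations")
}

# seedable pink noise: spectrally shape white noise with 1/f^(alpha/2) gain
pink_noise <- function(n, alpha) {
  if (alpha == 0) return(rnorm(n))
  w <- rnorm(n)
  W <- fft(w)
  freqs <- c(0, seq_len(n - 1))
  freqs <- pmin(freqs, n - freqs)     # symmetric frequency index
  gain <- c(0, freqs[-1]^(-alpha / 2))
  x <- Re(fft(W * gain, inverse = TRUE)) / n
  x / sd(x)
}

#' Simulate one LFP recording from a state model
#'
#' Draws a stationary VAR realization (burn-in `max(1000, 10 p)` samples
#' discarded), then adds nuisance components: pink noise, a mains sinusoid
#' at `line_freq` plus its 2nd and 3rd harmonics (random phase per channel),
#' and, with probability `artifact_prob`, a whole-recording amplitude
#' inflation by `artifact_gain` emulating a movement artifact. Identical
#' `(model, seed)` pairs reproduce identical samples.
#'
#' @param model A stable `var_model`.
#' @param duration Recording length in seconds.
#' @param fs Sampling rate in Hz (defaults to the model's).
#' @param nuisance A [nuisance_spec()].
#' @param seed Integer seed.
#' @param state,session_id Metadata attached to the returned recording.
#' @return An [lfp_recording()] with an `artifact` attribute flagging
#'   whether the artifact gain was applied.
#' @export
simulate_recording <- function(model, duration, fs = model$fs,
                               nuisance = nuisance_spec(), seed = 1L,
                               state = NA_character_,
                               session_id = NA_character_) {
  stopifnot(inherits(model, "var_model"))
  if (model$radius >= 1) stop("refusing to simulate from an unstable model")
  T <- floor(duration * fs)
  if (T < 10 * model$p) stop("duration too short for the model order")
  burnin <- max(1000L, 10L * model$p)
  set.seed(seed)
  L <- chol(model$sigma)
  noise <- matrix(rnorm((T + burnin) * model$n), T + burnin, model$n) %*% L
  X <- .var_simulate_cpp(model$A, noise, burnin)
  if (nuisance$pink_amp > 0 && nuisance$pink_exponent > 0) {
    for (j in seq_len(model$n))
      X[, j] <- X[, j] + nuisance$pink_amp *
        pink_noise(T, nuisance$pink_exponent)
  }
  if (nuisance$line_amp > 0) {
    tt <- seq_len(T) / fs
    for (j in seq_len(model$n)) {
      for (h in 1:3) {
        f <- h * nuisance$line_freq
        if (f >= fs / 2) next
        X[, j] <- X[, j] + (nuisance$line_amp / h) *
          sin(2 * pi * f * tt + runif(1, 0, 2 * pi))
      }
    }
  }
  artifact <- runif(1) < nuisance$artifact_prob
  if (artifact) X <- X * nuisance$artifact_gain
  rec <- lfp_recording(X, fs = fs, channels = model$channels,
                       state = state, session_id = session_id)
  attr(rec, "artifact") <- artifact
  rec
}

# expected sign map: for each coupling, band of its center frequency, and
# state transition, the sign of the planted multiplier change
ground_truth_signs <- function(spec, bands = default_bands("gc")) {
  transitions <- state_transitions(spec$states)
  rows <- list()
  for (cc in spec$couplings) {
    in_band <- vapply(bands, function(b)
      cc$center_freq >= b$lo && cc$center_freq <= b$hi, logical(1))
    for (bi in which(in_band)) {
      for (tr in transitions) {
        d <- cc$state_multipliers[[tr[2]]] - cc$state_multipliers[[tr[1]]]
        rows[[length(rows) + 1L]] <- data.frame(
          source = cc$source, target = cc$target,
          band = bands[[bi]]$name,
          transition = paste(tr[1], "->", tr[2]),
          sign = sign(d) * (cc$strength > 0),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

state_transitions <- function(states) {
  idx <- utils::combn(seq_along(states), 2, simplify = FALSE)
  lapply(idx, function(ij) states[ij])
}

#' Generate a complete synthetic study with ground truth
#'
#' Builds one generating VAR model per state, simulates every
#' `(state, session)` recording with a seed derived deterministically from
#' the study seed, and returns the recordings together with the ground
#' truth needed to score the downstream pipeline (per-state models and the
#' expected sign of every planted band-limited connectivity change).
#'
#' @param spec A [study_spec()].
#' @return A list of class `lfp_study` with fields `recordings` (list of
#'   [lfp_recording()]), `ground_truth` (list with `models` and `signs`),
#'   and `spec`.
#' @export
generate_study <- function(spec) {
  stopifnot(inherits(spec, "study_spec"))
  models <- lapply(spec$states, function(s) build_state_var(spec, s))
  names(models) <- spec$states
  recordings <- list()
  for (si in seq_along(spec$states)) {
    state <- spec$states[si]
    for (k in seq_len(spec$sessions_per_state[si])) {
      sid <- sprintf("%s-%02d", state, k)
      seed_k <- (spec$seed + 7919L * si + 104729L * k) %% .Machine$integer.max
      recordings[[sid]] <- simulate_recording(
        models[[state]], duration = spec$session_duration, fs = spec$fs,
        nuisance = spec$noise, seed = seed_k,
        state = state, session_id = sid)
    }
  }
  structure(list(recordings = recordings,
                 ground_truth = list(models = models,
                                     signs = ground_truth_signs(spec)),
                 spec = spec),
            class = "lfp_study")
}

#' @export
print.lfp_study <- function(x, ...) {
  states <- vapply(x$recordings, function(r) r$state, character(1))
  cat(sprintf("<lfp_study> %d recordings @ %g Hz (%s)\n",
              length(x$recordings), x$spec$fs,
              paste(sprintf("%s: %d", names(table(states)), table(states)),
                    collapse = ", ")))
  invisible(x)
}
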