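#' @name preprocess
#' @title Signal conditioning for LFP recordings
#' @description
#' Deterministic preprocessing chain applied before spectral and Granger
#' causality analysis: zero-phase Butterworth band-pass, zero-phase notch at
#' the mains frequency and harmonics, anti-aliased resampling, segmentation
#' into fixed non-overlapping analysis trials, and per-segment
#' normalization. All filters are applied forward-backward (two-pass), so
#' the net phase response is zero; edges are protected by odd-reflection
#' padding of three filter lengths.
NULL

# zero-phase (IIR or FIR) filtering with odd-reflection padding
filtfilt_pad <- function(b, a, x) {
  b <- as.numeric(b); a <- as.numeric(a)
  nfilt <- max(length(b), length(a))
  pad <- 3 * (nfilt - 1)
  if (length(x) <= pad) stop("signal too short for the filter edge padding")
  pre <- 2 * x[1] - x[seq(pad + 1, 2)]
  post <- 2 * x[length(x)] - x[seq(length(x) - 1, length(x) - pad)]
  xp <- c(pre, x, post)
  y <- signal::filter(b, a, xp)
  y <- rev(signal::filter(b, a, rev(y)))
  y[(pad + 1):(pad + length(x))]
}

apply_channelwise <- function(rec, fun) {
  out <- rec
  for (j in seq_len(ncol(rec$data))) out$data[, j] <- fun(rec$data[, j])
  out
}

#' Zero-phase Butterworth band-pass filter
#'
#' @param rec An [lfp_recording()] (or segment).
#' @param lo,hi Corner frequencies in Hz, `0 < lo < hi < fs/2`.
#' @param order Butterworth order per pass (the default, 2, gives a
#'   fourth-order magnitude response after the forward-backward pass).
#' @return The filtered recording; length is unchanged.
#' @export
bandpass <- function(rec, lo = 1, hi = 150, order = 2) {
  stopifnot(inherits(rec, "lfp_recording"))
  nyq <- rec$fs / 2
  if (!(lo > 0 && lo < hi && hi < nyq))
    stop("band corners must satisfy 0 < lo < hi < fs/2 (fs/2 = ", nyq, ")")
  bf <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  apply_channelwise(rec, function(x) filtfilt_pad(bf$b, bf$a, x))
}

# best rational approximation p/q to a ratio, by continued fractions
rational_approx <- function(x, max_den = 10000L, tol = 1e-9) {
  h0 <- 0L; h1 <- 1L; k0 <- 1L; k1 <- 0L
  r <- x
  repeat {
    a <- floor(r)
    h2 <- a * h1 + h0; k2 <- a * k1 + k0
    if (k2 > max_den) break
    h0 <- h1; h1 <- h2; k0 <- k1; k1 <- k2
    if (abs(x - h1 / k1) < tol) break
    if (abs(r - a) < 1e-12) break
    r <- 1 / (r - a)
  }
  c(as.integer(h1), as.integer(k1))
}

# RBJ biquad notch at f0 with quality factor Q
design_notch <- function(f0, fs, Q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Zero-phase notch filter at mains frequency and harmonics
#'
#' Applies a narrow IIR band-stop (biquad, quality factor `Q`) at each
#' requested frequency, forward-backward. Frequencies at or above Nyquist
#' are skipped with a warning rather than an error, since harmonics can
#' legitimately fall above Nyquist after downsampling.
#'
#' @param rec An [lfp_recording()].
#' @param freqs Notch center frequencies in Hz (default 60 Hz and its
#'   harmonics at 120 and 240 Hz).
#' @param Q Quality factor; the -3 dB notch width is roughly `f0 / Q` Hz.
#' @return The filtered recording.
#' @export
notch <- function(rec, freqs = c(60, 120, 240), Q = 35) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (length(freqs) == 0) {
    warning("empty notch frequency list; returning input unchanged")
    return(rec)
  }
  nyq <- rec$fs / 2
  keep <- freqs < nyq
  if (any(!keep))
    warning("skipping notch frequencies at/above Nyquist (", nyq, " Hz): ",
            paste(freqs[!keep], collapse = ", "))
  for (f0 in freqs[keep]) {
    flt <- design_notch(f0, rec$fs, Q)
    rec <- apply_channelwise(rec, function(x) filtfilt_pad(flt$b, flt$a, x))
  }
  rec
}

#' Resample a recording with anti-aliasing at 45% of the target rate
#'
#' A sharp zero-phase FIR (Hamming-windowed sinc) low-pass with cutoff
#' `0.45 * target_fs` is applied before rate conversion, matching the
#' acquisition hardware's anti-aliasing convention. Integer downsampling
#' ratios then decimate exactly; non-integer ratios use windowed-sinc
#' interpolation at the output sample times (the signal is already
#' band-limited well below both Nyquist rates at that point).
#'
#' @param rec An [lfp_recording()].
#' @param target_fs Target sampling rate in Hz, strictly below `rec$fs`.
#' @param transition Anti-aliasing transition bandwidth as a fraction of
#'   `target_fs`; the default 0.04 puts the stopband edge at
#'   `(0.45 + 0.02) * target_fs`.
#' @return The resampled recording with `fs = target_fs`.
#' @export
resample_recording <- function(rec, target_fs, transition = 0.04) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (target_fs >= rec$fs)
    stop("target_fs (", target_fs, ") must be below the current rate (",
         rec$fs, ")")
  cutoff <- 0.45 * target_fs
  # Hamming-windowed FIR: transition width ~ 3.3 * fs / ntaps
  ntaps <- 2L * ceiling(1.65 * rec$fs / (transition * target_fs)) + 1L
  ntaps <- min(ntaps, 2001L)
  b <- signal::fir1(ntaps - 1L, cutoff / (rec$fs / 2), type = "low")
  rec <- apply_channelwise(rec, function(x) filtfilt_pad(b, 1, x))
  ratio <- rec$fs / target_fs
  if (abs(ratio - round(ratio)) < 1e-9) {
    idx <- seq(1, nrow(rec$data), by = round(ratio))
    rec$data <- rec$data[idx, , drop = FALSE]
  } else {
    rec$data <- apply(rec$data, 2, sinc_interp, ratio = ratio)
  }
  rec$fs <- target_fs
  rec
}

# windowed-sinc interpolation of x at output spacing `ratio` input samples;
# valid for signals band-limited comfortably below the input Nyquist
sinc_interp <- function(x, ratio, L = 16L) {
  n <- length(x)
  n_out <- floor(n / ratio)
  xp <- c(rev(x[2:(L + 1)]), x, rev(x[(n - L):(n - 1)]))
  tm <- (seq_len(n_out) - 1) * ratio          # 0-based input-sample times
  k0 <- floor(tm)
  frac <- tm - k0
  y <- numeric(n_out)
  for (j in (-L + 1):L) {
    u <- frac - j
    h <- ifelse(abs(u) < 1e-12, 1, sin(pi * u) / (pi * u)) *
      (0.54 + 0.46 * cos(pi * u / L))
    y <- y + xp[k0 + j + L + 1] * h
  }
  y
}

#' Split a recording into consecutive non-overlapping segments
#'
#' Segments start at sample 1 and are contiguous; a trailing remainder
#' shorter than `duration` is discarded.
#'
#' @param rec An [lfp_recording()].
#' @param duration Segment length in seconds (300 s for GC analysis, 30 s
#'   for PSD/coherence, by convention).
#' @return A list of `lfp_segment` objects (empty, with a warning, when the
#'   recording is shorter than one segment).
#' @export
split_segments <- function(rec, duration) {
  stopifnot(inherits(rec, "lfp_recording"))
  len <- floor(duration * rec$fs)
  if (len < 1) stop("duration * fs must be >= 1 sample")
  k <- nrow(rec$data) %/% len
  if (k == 0) {
    warning("recording (", nrow(rec$data) / rec$fs,
            " s) shorter than one segment (", duration, " s); empty list")
    return(list())
  }
  lapply(seq_len(k), function(i) {
    rows <- ((i - 1) * len + 1):(i * len)
    lfp_segment(rec$data[rows, , drop = FALSE], rec$fs, rec$channels,
                rec$state, rec$session_id, index = i - 1L,
                duration = duration)
  })
}

#' Normalize a segment to zero mean and unit variance per channel
#'
#' Granger causality is scale-invariant, but normalizing each channel
#' within each analysis trial removes scale bias from the MVAR estimation.
#'
#' @param seg An `lfp_segment` (or recording).
#' @return The normalized segment.
#' @export
normalize_segment <- function(seg) {
  stopifnot(inherits(seg, "lfp_recording"))
  out <- seg
  for (j in seq_len(ncol(seg$data))) {
    x <- seg$data[, j]
    s <- sd(x)
    if (!is.finite(s) || s < 1e-12)
      stop("channel '", seg$channels[j], "' has zero variance; ",
           "cannot normalize")
    out$data[, j] <- (x - mean(x)) / s
  }
  out
}

#' Run the full preprocessing chain on one recording
#'
#' Band-pass, notch, resample (only when the recording is above the target
#' rate), then split into GC segments which are normalized.
#'
#' @param rec An [lfp_recording()].
#' @param band Band-pass corners in Hz.
#' @param notch_freqs Notch frequencies in Hz.
#' @param target_fs Analysis sampling rate in Hz.
#' @param seg_dur Segment duration in seconds.
#' @param normalize Normalize each segment (TRUE for GC trials; FALSE for
#'   the PSD/coherence trials where absolute power matters).
#' @return A list of segments.
#' @export
preprocess_recording <- function(rec, band = c(1, 150),
                                 notch_freqs = c(60, 120, 240),
                                 target_fs = 400, seg_dur = 300,
                                 normalize = TRUE) {
  rec <- bandpass(rec, band[1], band[2])
  rec <- withCallingHandlers(
    notch(rec, notch_freqs),
    warning = function(w) invokeRestart("muffleWarning"))
  if (rec$fs > target_fs) rec <- resample_recording(rec, target_fs)
  segs <- split_segments(rec, seg_dur)
  if (normalize) segs <- lapply(segs, normalize_segment)
  segs
}
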