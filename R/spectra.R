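#' Frequency band definition
#'
#' The analysis uses three bands: `overall` (0-50 Hz for Granger causality,
#' 5-50 Hz for power and coherence), `peakA` (5-20 Hz; theta/alpha/low
#' beta) and `peakB` (25-45 Hz; high beta/low gamma). Band edges are
#' inclusive on the discrete frequency grid.
#'
#' @param name Band name.
#' @param lo,hi Band edges in Hz, `lo < hi`.
#' @return A `freq_band` object.
#' @export
freq_band <- function(name, lo, hi) {
  if (!(lo < hi)) stop("band requires lo < hi")
  structure(list(name = name, lo = lo, hi = hi), class = "freq_band")
}

#' Default band set
#'
#' @param metric `"gc"` (overall band 0-50 Hz) or `"power"` (overall band
#'   5-50 Hz, also used for coherence).
#' @return Named list of [freq_band()] objects.
#' @export
default_bands <- function(metric = c("gc", "power")) {
  metric <- match.arg(metric)
  overall_lo <- if (metric == "gc") 0 else 5
  list(overall = freq_band("overall", overall_lo, 50),
       peakA = freq_band("peakA", 5, 20),
       peakB = freq_band("peakB", 25, 45))
}

# Hann-windowed Welch cross-spectral density matrix.
# Returns freqs and a complex n x n x F array (one-sided density, 1/Hz).
welch_csd <- function(x, fs, window_len = 1, overlap = 0.5) {
  x <- as.matrix(x)
  nper <- floor(window_len * fs)
  if (nper > nrow(x)) stop("Welch window longer than the segment")
  if (nper < 8) stop("Welch window too short")
  step <- max(1L, floor(nper * (1 - overlap)))
  starts <- seq(1, nrow(x) - nper + 1, by = step)
  n <- ncol(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1))  # Hann
  U <- sum(w^2) * fs                       # density scaling
  nf <- nper %/% 2 + 1
  S <- array(0 + 0i, dim = c(n, n, nf))
  for (s in starts) {
    seg <- x[s:(s + nper - 1), , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg))
    Fx <- mvfft(seg * w)[1:nf, , drop = FALSE]
    for (i in seq_len(n)) for (j in i:n) {
      cs <- Fx[, i] * Conj(Fx[, j])
      S[i, j, ] <- S[i, j, ] + cs
      if (j > i) S[j, i, ] <- S[j, i, ] + Conj(cs)
    }
  }
  S <- S / (length(starts) * U)
  # one-sided: double everything except DC (and Nyquist for even nper)
  sc <- rep(2, nf); sc[1] <- 1
  if (nper %% 2 == 0) sc[nf] <- 1
  for (k in seq_len(nf)) S[, , k] <- S[, , k] * sc[k]
  freqs <- (seq_len(nf) - 1) * fs / nper
  list(freqs = freqs, S = S, n_windows = length(starts))
}

#' Welch power spectral density of a segment
#'
#' Averaged modified periodogram with Hann windows. Frequency resolution is
#' `1 / window_len` Hz.
#'
#' @param seg An `lfp_segment` (or recording, or plain matrix with `fs`).
#' @param window_len Welch window length in seconds.
#' @param overlap Window overlap fraction in `[0, 1)`.
#' @param fs Sampling rate, required when `seg` is a bare matrix.
#' @return A `psd_spectrum`: list with `freqs` (Hz) and `values`
#'   (frequencies x channels, nonnegative, units 1/Hz).
#' @export
welch_psd <- function(seg, window_len = 1, overlap = 0.5, fs = NULL) {
  if (inherits(seg, "lfp_recording")) { fs <- seg$fs }
  if (is.null(fs)) stop("fs is required for matrix input")
  x <- as_data_matrix(seg)
  cs <- welch_csd(x, fs, window_len, overlap)
  vals <- t(apply(cs$S, 3, function(m) pmax(Re(diag(m)), 0)))
  if (ncol(x) == 1) vals <- matrix(vals, ncol = 1)
  colnames(vals) <- if (inherits(seg, "lfp_recording")) seg$channels
                    else colnames(x)
  structure(list(freqs = cs$freqs, values = vals),
            class = "psd_spectrum")
}

#' Magnitude-squared coherence spectra of a segment
#'
#' `C_xy(f) = |S_xy(f)|^2 / (S_xx(f) S_yy(f))` from Welch cross-spectra;
#' symmetric in the channel pair with unit diagonal, values in `[0, 1]`.
#' Coherence is upward-biased by roughly `1 / n_windows`, so at least 8
#' averaging windows are required (a single window would give coherence
#' identically 1 and is an error).
#'
#' @inheritParams welch_psd
#' @return A `coherence_spectra`: list with `freqs` and `values`
#'   (channel x channel x frequency array in `[0, 1]`).
#' @export
coherence_spectra <- function(seg, window_len = 1, overlap = 0.5, fs = NULL) {
  if (inherits(seg, "lfp_recording")) { fs <- seg$fs }
  if (is.null(fs)) stop("fs is required for matrix input")
  x <- as_data_matrix(seg)
  cs <- welch_csd(x, fs, window_len, overlap)
  if (cs$n_windows < 2)
    stop("coherence from a single window is identically 1; use a shorter ",
         "window or longer segment")
  if (cs$n_windows < 8)
    warning("only ", cs$n_windows,
            " averaging windows; coherence will be upward-biased")
  n <- ncol(x); nf <- length(cs$freqs)
  C <- array(0, dim = c(n, n, nf))
  for (k in seq_len(nf)) {
    Sk <- cs$S[, , k]
    d <- pmax(Re(diag(Sk)), .Machine$double.xmin)
    C[, , k] <- pmin(pmax(Mod(Sk)^2 / outer(d, d), 0), 1)
    diag(C[, , k]) <- 1
  }
  chans <- if (inherits(seg, "lfp_recording")) seg$channels else colnames(x)
  dimnames(C) <- list(chans, chans, NULL)
  structure(list(freqs = cs$freqs, values = C),
            class = "coherence_spectra")
}

#' Band-limited average of a spectrum
#'
#' Arithmetic mean over the grid frequencies `f` with
#' `band$lo <= f <= band$hi` (edges inclusive).
#'
#' @param spec A `psd_spectrum`, `coherence_spectra`, `gc_spectra`, or a
#'   list with `freqs` and `values`.
#' @param band A [freq_band()].
#' @return For per-channel spectra, a named numeric vector; for
#'   channel x channel x frequency arrays, a matrix averaged over the band.
#' @export
band_mean <- function(spec, band) {
  stopifnot(inherits(band, "freq_band"))
  freqs <- spec$freqs
  idx <- which(freqs >= band$lo & freqs <= band$hi)
  if (length(idx) == 0)
    stop("band [", band$lo, ", ", band$hi,
         "] Hz does not overlap the frequency grid")
  v <- spec$values
  if (is.matrix(v)) {
    colMeans(v[idx, , drop = FALSE])
  } else if (length(dim(v)) == 3L) {
    out <- apply(v[, , idx, drop = FALSE], c(1, 2), mean)
    dimnames(out) <- dimnames(v)[1:2]
    out
  } else {
    mean(v[idx])
  }
}
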