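#' @name granger
#' @title MVAR-based Granger causality
#' @description
#' Time-domain and frequency-domain (Geweke) Granger causality over the
#' pairwise model of an n-channel montage. Time-domain GC is
#' `F_{y->x} = ln(Sigma_red[x,x] / Sigma_full[x,x])`: the log ratio of the
#' innovation variance of a reduced model that omits the source channel to
#' that of the full model. In `conditional` mode the reduced model retains
#' all remaining channels (solved from the full model's autocovariance via
#' Whittle's recursion); in `bivariate` mode full and reduced models involve
#' the channel pair alone. Spectral GC uses the Geweke decomposition of the
#' cross-power spectrum implied by the fitted model; for the bivariate
#' estimator its average over `[0, fs/2]` equals the time-domain GC.
NULL

# transfer function H(f) = (I - sum_j A_j e^{-i 2 pi f j / fs})^{-1},
# returned as an n x n x F complex array
transfer_function <- function(model, freqs) {
  n <- model$n; p <- model$p
  H <- array(0 + 0i, dim = c(n, n, length(freqs)))
  I <- diag(n)
  for (k in seq_along(freqs)) {
    w <- 2 * pi * freqs[k] / model$fs
    Abar <- I + 0i
    for (j in seq_len(p)) Abar <- Abar - model$A[, , j] * exp(-1i * w * j)
    H[, , k] <- solve(Abar)
  }
  H
}

# guarded log-ratio for GC: tiny negative excursions are clamped, real
# negatives are a numerical failure
gc_log_ratio <- function(num, den, tol = 1e-10) {
  if (any(den < -tol * pmax(num, 1)))
    stop("numerical failure in GC: reduced variance exceeds full variance ",
         "beyond tolerance")
  log(num / pmax(den, 1e-12 * pmax(num, .Machine$double.xmin)))
}

new_gc_matrix <- function(F, channels) {
  dimnames(F) <- list(source = channels, target = channels)
  diag(F) <- NA_real_
  structure(F, class = "gc_matrix")
}

#' Time-domain Granger causality matrix
#'
#' For every ordered channel pair `(source, target)`, the causality
#' `F_{source -> target}`. Entry `[i, j]` of the returned matrix is the GC
#' from channel `i` to channel `j`; the diagonal is undefined (`NA`), so a
#' five-channel montage has exactly 20 defined entries.
#'
#' @param x A `var_model` or data (segment / matrix). For a model, the
#'   reduced models are solved analytically from the model-implied
#'   autocovariance via [whittle_var()]. For data, full and reduced models
#'   are fitted by nested ordinary least squares on a shared lag matrix,
#'   which guarantees nonnegative estimates even when heavy pre-filtering
#'   leaves the innovation variances tiny.
#' @param mode `"conditional"` (reduced model keeps all channels but the
#'   source; the default) or `"bivariate"` (models on the pair alone).
#' @param p Model order used when `x` is data; selected by BIC when `NULL`.
#' @param fs Sampling rate for matrix input.
#' @param q Autocovariance lags used to solve the reduced models; `NULL`
#'   chooses by the decay rule of [var_to_autocov()].
#' @param q_max Cap on the autocovariance lags.
#' @return A `gc_matrix` (n x n, nonnegative off-diagonal, `NA` diagonal).
#' @export
time_gc <- function(x, mode = c("conditional", "bivariate"), p = NULL,
                    fs = NULL, q = NULL, q_max = 200L) {
  mode <- match.arg(mode)
  if (inherits(x, "var_model")) {
    return(time_gc_model(x, mode, q = q, q_max = q_max))
  }
  if (inherits(x, "lfp_recording")) fs <- x$fs
  if (is.null(fs)) fs <- 1
  xm <- as_data_matrix(x)
  if (is.null(p)) p <- select_order(xm, p_max = min(30L, nrow(xm) %/%
                                    (ncol(xm)^2 + 1) - 1L))$order
  time_gc_data(xm, mode, p)
}

# Sample estimator: nested ordinary least squares. The reduced regression
# omits the source channel's lag columns, so its residual sum of squares is
# never below the full regression's and the GC estimate is nonnegative by
# construction -- important because heavy pre-filtering (notch nulls, band
# edges) drives some innovation variances very small and makes the
# autocovariance route ill-conditioned.
time_gc_data <- function(xm, mode, p) {
  n <- ncol(xm)
  chans <- colnames(xm)
  if (is.null(chans)) chans <- paste0("ch", seq_len(n))
  F <- matrix(0, n, n)
  if (mode == "conditional") {
    lag <- build_lag_matrix(xm, p)
    ZZ <- crossprod(lag$Z); ZY <- crossprod(lag$Z, lag$Y)
    YY <- crossprod(lag$Y)
    sse <- function(cols, targets) {
      B <- tryCatch(solve(ZZ[cols, cols], ZY[cols, targets, drop = FALSE]),
                    error = function(e)
                      stop("rank-deficient lag matrix; lower p"))
      diag(YY)[targets] -
        diag(crossprod(ZY[cols, targets, drop = FALSE], B))
    }
    all_cols <- seq_len(n * p)
    sse_full <- sse(all_cols, seq_len(n))
    for (y in seq_len(n)) {
      keep <- all_cols[rep(seq_len(n), p) != y]
      targets <- setdiff(seq_len(n), y)
      sse_red <- sse(keep, targets)
      F[y, targets] <- pmax(0, log(sse_red / sse_full[targets]))
    }
  } else {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      lag <- build_lag_matrix(xm[, c(i, j), drop = FALSE], p)
      ZZ <- crossprod(lag$Z); ZY <- crossprod(lag$Z, lag$Y)
      YY <- crossprod(lag$Y)
      for (tgt in 1:2) {
        src <- 3 - tgt
        own <- seq(tgt, 2 * p, by = 2)
        B_f <- solve(ZZ, ZY[, tgt])
        sse_f <- YY[tgt, tgt] - sum(ZY[, tgt] * B_f)
        B_r <- solve(ZZ[own, own], ZY[own, tgt])
        sse_r <- YY[tgt, tgt] - sum(ZY[own, tgt] * B_r)
        ii <- c(i, j)
        F[ii[src], ii[tgt]] <- max(0, log(sse_r / sse_f))
      }
    }
  }
  new_gc_matrix(F, chans)
}

# conditional / bivariate time GC from a fitted full model
time_gc_model <- function(model, mode, q = NULL, q_max = 200L) {
  n <- model$n
  G <- var_to_autocov(model, q = q, q_max = q_max)
  qq <- dim(G)[3] - 1L
  F <- matrix(0, n, n)
  if (mode == "conditional") {
    for (y in seq_len(n)) {
      r <- setdiff(seq_len(n), y)
      red <- whittle_var(G[r, r, , drop = FALSE], p = qq)
      for (xi in seq_along(r)) {
        x <- r[xi]
        F[y, x] <- log(red$sigma[xi, xi] / model$sigma[x, x])
      }
    }
    # Whittle rounding at high solve orders on near-unit-radius models
    # reaches ~1e-8 on the log scale; anything worse signals real failure
    if (any(F[row(F) != col(F)] < -1e-6))
      stop("numerical failure: reduced innovation variance below the full ",
           "model's beyond tolerance")
    F[F < 0] <- 0
  } else {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      sub <- G[c(i, j), c(i, j), , drop = FALSE]
      pair <- whittle_var(sub, p = qq)
      fpair <- bivariate_time_gc_from_autocov(sub, pair)
      F[i, j] <- fpair[1, 2]; F[j, i] <- fpair[2, 1]
    }
  }
  new_gc_matrix(F, model$channels)
}

# bivariate time GC given a fitted pair model: reduced univariate models are
# solved from the pair model's implied autocovariance
bivariate_time_gc <- function(pair_model, q = NULL, q_max = 200L) {
  G <- var_to_autocov(pair_model, q = q, q_max = q_max)
  bivariate_time_gc_from_autocov(G, pair_model)
}

bivariate_time_gc_from_autocov <- function(G, pair_model) {
  qq <- dim(G)[3] - 1L
  F <- matrix(0, 2, 2)
  for (tgt in 1:2) {
    src <- 3 - tgt
    uni <- whittle_var(G[tgt, tgt, , drop = FALSE], p = qq)
    v <- log(uni$sigma[1, 1] / pair_model$sigma[tgt, tgt])
    if (v < -1e-6)
      stop("numerical failure: reduced innovation variance below the full ",
           "model's beyond tolerance")
    F[src, tgt] <- max(0, v)
  }
  F
}

#' Spectral (Geweke) Granger causality
#'
#' Frequency-resolved directed influence for every ordered channel pair.
#' In `bivariate` mode (the default) each pair is modelled alone:
#' with transfer function `H`, residual covariance `Sigma` and the
#' normalization transform removing the residual correlation,
#' `f_{y->x}(f) = ln( S_xx / (S_xx - (Sigma_yy - Sigma_xy^2/Sigma_xx)
#' |Htilde_xy|^2) )`. In `conditional` mode the reduced model keeps the
#' remaining channels and the Geweke conditional decomposition is used.
#'
#' @inheritParams time_gc
#' @param freqs Frequency grid in Hz within `[0, fs/2]`; defaults to
#'   0 to Nyquist in 0.5 Hz steps.
#' @param mode `"bivariate"` (default) or `"conditional"`.
#' @return A `gc_spectra` object: list with `freqs` and `values`, an
#'   n x n x F nonnegative array indexed `[source, target, frequency]`
#'   (diagonal `NA`).
#' @export
spectral_gc <- function(x, mode = c("bivariate", "conditional"), p = NULL,
                        freqs = NULL, fs = NULL, q = NULL, q_max = 200L) {
  mode <- match.arg(mode)
  if (inherits(x, "var_model")) {
    fs <- x$fs
    if (is.null(freqs)) freqs <- seq(0, fs / 2, by = 0.5)
    if (any(freqs < 0 | freqs > fs / 2)) stop("freqs must lie in [0, fs/2]")
    vals <- if (mode == "bivariate" && x$n == 2L)
      spectral_gc_pair_array(x, freqs)
    else if (mode == "bivariate")
      spectral_gc_marginal(x, freqs, q = q, q_max = q_max)
    else
      spectral_gc_conditional(x, freqs, q = q, q_max = q_max)
    return(structure(list(freqs = freqs, values = vals, mode = mode),
                     class = "gc_spectra"))
  }
  if (inherits(x, "lfp_recording")) fs <- x$fs
  if (is.null(fs)) fs <- 1
  xm <- as_data_matrix(x)
  if (is.null(freqs)) freqs <- seq(0, fs / 2, by = 0.5)
  if (any(freqs < 0 | freqs > fs / 2)) stop("freqs must lie in [0, fs/2]")
  if (is.null(p)) p <- select_order(xm, p_max = min(30L, nrow(xm) %/%
                                    (ncol(xm)^2 + 1) - 1L))$order
  n <- ncol(xm)
  chans <- colnames(xm); if (is.null(chans)) chans <- paste0("ch", seq_len(n))
  if (mode == "conditional") {
    full <- fit_var(xm, p, fs = fs)
    vals <- spectral_gc_conditional(full, freqs, q = q, q_max = q_max)
  } else {
    vals <- array(NA_real_, dim = c(n, n, length(freqs)),
                  dimnames = list(source = chans, target = chans, NULL))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      pm <- fit_var(xm[, c(i, j), drop = FALSE], p, fs = fs)
      sp <- spectral_gc_pair_array(pm, freqs)
      vals[i, j, ] <- sp[1, 2, ]
      vals[j, i, ] <- sp[2, 1, ]
    }
  }
  structure(list(freqs = freqs, values = vals, mode = mode),
            class = "gc_spectra")
}

# Geweke spectral GC for a bivariate model, both directions: 2 x 2 x F.
# Vectorized over frequency via the closed-form 2x2 inverse of
# Abar(f) = I - sum_j A_j e^{-i 2 pi f j / fs}.
spectral_gc_pair_array <- function(model, freqs) {
  stopifnot(model$n == 2L)
  S <- model$sigma
  w <- 2 * pi * freqs / model$fs
  a11 <- 1 + 0i; a12 <- 0i; a21 <- 0i; a22 <- 1 + 0i
  for (j in seq_len(model$p)) {
    ph <- exp(-1i * w * j)
    a11 <- a11 - model$A[1, 1, j] * ph
    a12 <- a12 - model$A[1, 2, j] * ph
    a21 <- a21 - model$A[2, 1, j] * ph
    a22 <- a22 - model$A[2, 2, j] * ph
  }
  det <- a11 * a22 - a12 * a21
  H11 <- a22 / det; H12 <- -a12 / det
  H21 <- -a21 / det; H22 <- a11 / det
  H <- list(list(H11, H12), list(H21, H22))
  out <- array(NA_real_, dim = c(2, 2, length(freqs)),
               dimnames = list(source = model$channels,
                               target = model$channels, NULL))
  for (tgt in 1:2) {
    src <- 3 - tgt
    # residual rotation removing the correlation between the target and
    # source innovations: Hxx_tilde = Hxx + (Sigma_xy / Sigma_xx) Hxy.
    # Then S_xx = Sigma_xx |Hxx_tilde|^2 + Sigma_{yy|x} |Hxy|^2 exactly,
    # so numerator and denominator are both nonnegative by construction.
    sig_cond <- S[src, src] - S[tgt, src]^2 / S[tgt, tgt]
    Hxx <- H[[tgt]][[tgt]]; Hxy <- H[[tgt]][[src]]
    Hxx_t <- Hxx + (S[tgt, src] / S[tgt, tgt]) * Hxy
    intr <- S[tgt, tgt] * Mod(Hxx_t)^2
    caus <- sig_cond * Mod(Hxy)^2
    out[src, tgt, ] <- pmax(0, gc_log_ratio(intr + caus, intr))
  }
  out
}

# bivariate spectral GC for every pair of an n-channel model, each pair
# model obtained by marginalizing the full model's autocovariance
spectral_gc_marginal <- function(model, freqs, q = NULL, q_max = 200L) {
  n <- model$n
  G <- var_to_autocov(model, q = q, q_max = q_max)
  qq <- dim(G)[3] - 1L
  vals <- array(NA_real_, dim = c(n, n, length(freqs)),
                dimnames = list(source = model$channels,
                                target = model$channels, NULL))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pm <- whittle_var(G[c(i, j), c(i, j), , drop = FALSE], p = qq)
    sp <- spectral_gc_pair_array(pm, freqs)
    vals[i, j, ] <- sp[1, 2, ]
    vals[j, i, ] <- sp[2, 1, ]
  }
  vals
}

# Geweke conditional spectral GC from the full model: for source y the
# reduced model keeps the remaining channels r; the full transfer is
# premultiplied by the inverse reduced transfer and the standard
# normalization is applied in the [r, y] arrangement.
spectral_gc_conditional <- function(model, freqs, q = NULL, q_max = 200L) {
  n <- model$n
  G <- var_to_autocov(model, q = q, q_max = q_max)
  qq <- dim(G)[3] - 1L
  H <- transfer_function(model, freqs)
  vals <- array(NA_real_, dim = c(n, n, length(freqs)),
                dimnames = list(source = model$channels,
                                target = model$channels, NULL))
  for (y in seq_len(n)) {
    r <- setdiff(seq_len(n), y)
    m <- length(r)
    red <- whittle_var(G[r, r, , drop = FALSE], p = qq)
    GR <- transfer_function(red, freqs)
    perm <- c(r, y)
    Sp <- model$sigma[perm, perm]
    Srr <- Sp[1:m, 1:m, drop = FALSE]
    # Sigma_{yr} Sigma_{rr}^{-1}, used to rotate away the residual
    # correlation between the source and the reduced subsystem
    Syr_Srr_inv <- drop(solve(Srr, Sp[1:m, m + 1]))
    sig_y_cond <- Sp[m + 1, m + 1] - sum(Sp[m + 1, 1:m] * Syr_Srr_inv)
    intr <- matrix(0, m, length(freqs))
    caus <- matrix(0, m, length(freqs))
    for (k in seq_along(freqs)) {
      Hp <- H[perm, perm, k]
      Q <- Hp
      Q[1:m, ] <- solve(GR[, , k], Hp[1:m, , drop = FALSE])
      Qt_r <- Q[1:m, 1:m, drop = FALSE] +
        Q[1:m, m + 1] %o% Syr_Srr_inv
      # intrinsic power: quadratic form in the PD reduced-block covariance
      intr[, k] <- pmax(Re(diag(Qt_r %*% Srr %*% Conj(t(Qt_r)))), 0)
      caus[, k] <- sig_y_cond * Mod(Q[1:m, m + 1])^2
    }
    for (xi in seq_len(m)) {
      vals[y, r[xi], ] <- pmax(0, gc_log_ratio(intr[xi, ] + caus[xi, ],
                                               intr[xi, ]))
    }
  }
  vals
}

#' Check the minimum-phase condition for Geweke integral equality
#'
#' For a bivariate model, the average of the spectral GC over frequency
#' equals the time-domain GC exactly when the residual-rotated transfer
#' element of the target channel, `Hxx + (Sigma_xy/Sigma_xx) Hxy`, is
#' minimum phase (all zeros outside the unit circle). For strongly coupled
#' systems the condition can fail, in which case the spectral average is
#' strictly below the time-domain value -- a property of the decomposition
#' itself, not an estimation error. This predicate lets callers restrict
#' integral-equality checks to their domain of validity.
#'
#' @param model A bivariate `var_model`.
#' @return Logical: `TRUE` when the condition holds for both directions.
#' @export
geweke_integral_valid <- function(model) {
  stopifnot(inherits(model, "var_model"), model$n == 2L)
  ok <- TRUE
  for (tgt in 1:2) {
    src <- 3 - tgt
    c_rot <- model$sigma[tgt, src] / model$sigma[tgt, tgt]
    # for a 2x2 system, Hxx + c Hxy = (Abar[src,src] - c Abar[tgt,src]) / det,
    # so the zeros are the roots of the numerator polynomial in the lag
    # variable: 1 - sum_j (A_j[src,src] - c A_j[tgt,src]) L^j
    coefs <- c(1, -(model$A[src, src, ] - c_rot * model$A[tgt, src, ]))
    rts <- polyroot(coefs)
    if (any(Mod(rts) <= 1 + 1e-8)) ok <- FALSE
  }
  ok
}

#' Band-limited Granger causality matrices
#'
#' Averages a GC spectrum over each requested band (inclusive band edges on
#' the discrete grid), returning one `gc_matrix` per band.
#'
#' @param spectra A `gc_spectra` from [spectral_gc()].
#' @param bands List of [freq_band()]s; default [default_bands("gc")].
#' @return Named list of `gc_matrix` objects.
#' @export
band_gc <- function(spectra, bands = default_bands("gc")) {
  stopifnot(inherits(spectra, "gc_spectra"))
  out <- lapply(bands, function(b) {
    m <- band_mean(spectra, b)
    class(m) <- "gc_matrix"
    m
  })
  names(out) <- vapply(bands, function(b) b$name, character(1))
  out
}

#' @export
print.gc_spectra <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<gc_spectra> %d x %d channels, %d frequencies (%g-%g Hz), %s mode\n",
              d[1], d[2], d[3], min(x$freqs), max(x$freqs), x$mode))
  invisible(x)
}
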