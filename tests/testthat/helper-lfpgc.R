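# shared fixtures, all built in code

# random stable bivariate VAR(2); optionally restricted to the domain where
# the Geweke integral equality is exact (minimum-phase rotated transfer)
random_var2 <- function(coef_sd = 0.35, max_radius = 0.9, fs = 100,
                        require_min_phase = FALSE) {
  repeat {
    A <- array(rnorm(8, sd = coef_sd), c(2, 2, 2))
    S <- crossprod(matrix(rnorm(4), 2)) + diag(2) * 0.3
    m <- try(var_model(A, S, fs = fs), silent = TRUE)
    if (inherits(m, "try-error") || m$radius >= max_radius) next
    if (require_min_phase && !geweke_integral_valid(m)) next
    return(m)
  }
}

# trapezoidal average of a spectrum over its frequency grid
trap_mean <- function(v, f) {
  sum(diff(f) * (head(v, -1) + v[-1]) / 2) / (max(f) - min(f))
}

# small synthetic study used by the heavier end-to-end tests: two sessions
# per state, 300 s each, 60 s GC trials -> 10 trials per state
small_study_spec <- function(seed, couplings = default_couplings(),
                             artifact_prob = 0) {
  study_spec(sessions_per_state = c(2, 2, 2), session_duration = 300,
             couplings = couplings,
             noise = nuisance_spec(artifact_prob = artifact_prob),
             seed = seed)
}

small_config <- function() {
  pipeline_config(gc_seglen = 60, psd_seglen = 30, p_max = 8L, q_max = 100L)
}

# pure-tone recording for filter contract probes
tone_recording <- function(freqs_hz, fs, duration = 10, amp = 1) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  dat <- vapply(freqs_hz, function(f) amp * sin(2 * pi * f * t),
                numeric(length(t)))
  if (ncol(dat) == 1) dat <- cbind(dat, dat)  # recordings need >= 2 channels
  lfp_recording(dat, fs = fs,
                channels = paste0("ch", seq_len(ncol(dat))),
                state = "naive", session_id = "probe")
}

rms <- function(x) sqrt(mean(x^2))

# independent brute-force Benjamini-Hochberg step-up:
# p_adj_(i) = min_{j >= i} (m / j) p_(j), computed literally
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(ps[i:m] * m / seq(i, m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
mwu_enum <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  U_obs <- sum(rank(pooled)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  Us <- apply(combs, 2, function(ix) {
    sum(rank(pooled)[ix]) - n1 * (n1 + 1) / 2
  })
  mu <- n1 * length(y) / 2
  mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-9)
}

# Kolmogorov innovation variance of a single channel of a VAR model:
# exp of the mean log spectral density over the full circle
kolmogorov_sigma2 <- function(model, channel, ngrid = 8192) {
  w <- 2 * pi * (seq_len(ngrid) - 1) / ngrid
  n <- model$n
  Sxx <- numeric(ngrid)
  for (k in seq_len(ngrid)) {
    Ab <- diag(n) + 0i
    for (j in seq_len(model$p))
      Ab <- Ab - model$A[, , j] * exp(-1i * w[k] * j)
    H <- solve(Ab)
    Sk <- H %*% model$sigma %*% Conj(t(H))
    Sxx[k] <- Re(Sk[channel, channel])
  }
  exp(mean(log(Sxx)))
}
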