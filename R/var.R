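#' Construct a VAR model object
#'
#' Container for a vector autoregressive model
#' \eqn{X_t = \sum_{j=1}^p A_j X_{t-j} + e_t}, \eqn{e_t \sim (0, \Sigma)}.
#'
#' @param A Coefficient array `n x n x p` (or a list of p `n x n` matrices).
#'   `A[, , j]` maps the state at lag `j` onto the present.
#' @param sigma Residual (innovation) covariance, `n x n`, symmetric
#'   positive-definite.
#' @param fs Sampling rate in Hz of the process the model describes.
#' @param channels Optional channel labels.
#' @return An object of class `var_model` with fields `A`, `sigma`, `p`,
#'   `n`, `fs`, `channels` and `radius` (companion spectral radius).
#' @export
var_model <- function(A, sigma, fs = 1, channels = NULL) {
  if (is.list(A)) A <- array(unlist(A), dim = c(dim(A[[1]]), length(A)))
  if (is.matrix(A)) A <- array(A, dim = c(dim(A), 1L))
  stopifnot(length(dim(A)) == 3L, dim(A)[1] == dim(A)[2])
  n <- dim(A)[1]
  p <- dim(A)[3]
  sigma <- as.matrix(sigma)
  stopifnot(nrow(sigma) == n, ncol(sigma) == n)
  if (max(abs(sigma - t(sigma))) > 1e-8 * max(1, max(abs(sigma))))
    stop("sigma must be symmetric")
  sigma <- 0.5 * (sigma + t(sigma))
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("sigma must be positive-definite")
  if (is.null(channels)) channels <- paste0("ch", seq_len(n))
  m <- structure(
    list(A = A, sigma = sigma, p = p, n = n, fs = fs,
         channels = channels),
    class = "var_model")
  m$radius <- companion_radius(m)
  m
}

#' Spectral radius of the companion matrix of a VAR model
#'
#' The model is stable (stationary) iff the radius is < 1.
#'
#' @param model A `var_model` (or an `n x n x p` coefficient array).
#' @return The largest eigenvalue modulus of the companion matrix.
#' @export
companion_radius <- function(model) {
  A <- if (inherits(model, "var_model")) model$A else model
  n <- dim(A)[1]; p <- dim(A)[3]
  F <- companion_matrix(A)
  if (p == 1L && n == 1L) return(abs(A[1, 1, 1]))
  max(Mod(eigen(F, only.values = TRUE)$values))
}

companion_matrix <- function(A) {
  n <- dim(A)[1]; p <- dim(A)[3]
  F <- matrix(0, n * p, n * p)
  for (j in seq_len(p)) F[1:n, ((j - 1) * n + 1):(j * n)] <- A[, , j]
  if (p > 1) {
    idx <- (n + 1):(n * p)
    F[cbind(idx, idx - n)] <- 1
  }
  F
}

is_stable <- function(model, margin = 1e-6) {
  companion_radius(model) < 1 - margin
}

#' @export
print.var_model <- function(x, ...) {
  cat(sprintf("<var_model> n = %d channels, order p = %d, fs = %g Hz\n",
              x$n, x$p, x$fs))
  cat(sprintf("  companion spectral radius: %.6f (%s)\n", x$radius,
              if (x$radius < 1) "stable" else "UNSTABLE"))
  invisible(x)
}

# demeaned data matrix and stacked lag matrix on a common effective span.
# Returns Y ((T - p_lead) x n) and Z ((T - p_lead) x (n*p)) where column
# block j holds the series at lag j.
build_lag_matrix <- function(x, p, p_lead = p) {
  x <- as_data_matrix(x)
  x <- sweep(x, 2, colMeans(x))
  T <- nrow(x); n <- ncol(x)
  stopifnot(p_lead >= p, T > p_lead)
  Y <- x[(p_lead + 1):T, , drop = FALSE]
  Z <- matrix(0, T - p_lead, n * p)
  for (j in seq_len(p))
    Z[, ((j - 1) * n + 1):(j * n)] <- x[(p_lead + 1 - j):(T - j), , drop = FALSE]
  list(Y = Y, Z = Z, n = n, T_eff = T - p_lead)
}

#' Select the VAR model order by BIC
#'
#' Fits VAR(p) by ordinary least squares for every order `1..p_max` on the
#' same effective sample span (all regressions start at sample
#' `p_max + 1`, so the criteria are comparable) and returns the order
#' minimizing the Bayesian information criterion
#' `BIC(p) = log det(Sigma_hat(p)) + p * n^2 * log(T_eff) / T_eff`.
#'
#' @param x Segment, recording, or numeric matrix (samples x channels).
#' @param p_max Largest order to consider.
#' @return A list with `order` (the argmin), `bic` (criterion curve over
#'   `1..p_max`) and `criterion = "BIC"`.
#' @export
select_order <- function(x, p_max = 30L) {
  x <- as_data_matrix(x)
  T <- nrow(x); n <- ncol(x)
  need <- p_max * (n^2 + 1)
  if (T <= need)
    stop("insufficient samples for order selection: have ", T,
         ", need > ", need, " (= p_max * (n^2 + 1))")
  lag <- build_lag_matrix(x, p_max, p_lead = p_max)
  Y <- lag$Y; Z <- lag$Z; T_eff <- lag$T_eff
  ZZ <- crossprod(Z); ZY <- crossprod(Z, Y); YY <- crossprod(Y)
  bic <- numeric(p_max)
  for (p in seq_len(p_max)) {
    k <- n * p
    B <- tryCatch(solve(ZZ[1:k, 1:k], ZY[1:k, , drop = FALSE]),
                  error = function(e)
                    stop("rank-deficient lag matrix at order ", p,
                         "; lower p_max or provide more data"))
    sse <- YY - crossprod(ZY[1:k, , drop = FALSE], B)
    sig <- (sse + t(sse)) / (2 * T_eff)     # ML covariance estimate
    ld <- determinant(sig, logarithm = TRUE)
    if (ld$sign <= 0) { bic[p] <- Inf; next }
    bic[p] <- as.numeric(ld$modulus) + p * n^2 * log(T_eff) / T_eff
  }
  list(order = which.min(bic), bic = bic, criterion = "BIC")
}

#' Fit a VAR model by ordinary least squares
#'
#' Regresses each sample on `p` stacked lags of all channels (data are
#' demeaned first; no intercept is carried in the model). The residual
#' covariance uses the degrees-of-freedom denominator
#' `T_eff - n*p - 1`.
#'
#' @inheritParams select_order
#' @param p Model order (number of lags).
#' @param fs Sampling rate attached to the fitted model; taken from the
#'   segment when `x` carries one.
#' @return A `var_model` with the OLS coefficients and residual covariance;
#'   its companion spectral radius is reported in the `radius` field.
#' @export
fit_var <- function(x, p, fs = NULL) {
  if (is.null(fs)) fs <- if (inherits(x, "lfp_recording")) x$fs else 1
  chans <- if (inherits(x, "lfp_recording")) x$channels else colnames(as.matrix(x))
  xm <- as_data_matrix(x)
  T <- nrow(xm); n <- ncol(xm)
  if (T <= n * p + 1)
    stop("too few samples (", T, ") for VAR(", p, ") on ", n, " channels")
  lag <- build_lag_matrix(xm, p)
  ZZ <- crossprod(lag$Z)
  R <- tryCatch(chol(ZZ), error = function(e)
    stop("rank-deficient lag matrix; lower p or provide more data"))
  B <- backsolve(R, forwardsolve(t(R), crossprod(lag$Z, lag$Y)))
  E <- lag$Y - lag$Z %*% B
  dof <- lag$T_eff - n * p - 1
  if (dof <= 0) stop("non-positive residual degrees of freedom")
  sigma <- crossprod(E) / dof
  A <- array(0, dim = c(n, n, p))
  for (j in seq_len(p))
    A[, , j] <- t(B[((j - 1) * n + 1):(j * n), , drop = FALSE])
  var_model(A, sigma, fs = fs, channels = chans)
}

# solve M = F M F' + Q for stable F by doubling (Smith iteration)
dlyap_doubling <- function(F, Q, tol = 1e-14, max_iter = 80L) {
  X <- Q; A <- F
  for (i in seq_len(max_iter)) {
    X_new <- X + A %*% X %*% t(A)
    A <- A %*% A
    delta <- max(abs(X_new - X))
    X <- X_new
    if (delta <= tol * max(1, max(abs(X))) && max(abs(A)) < 1e-8) break
  }
  0.5 * (X + t(X))
}

#' Autocovariance sequence implied by a VAR model
#'
#' Solves the companion-form discrete Lyapunov equation for lags
#' `0..p-1` and extends by the recursion
#' \eqn{\Gamma_k = \sum_j A_j \Gamma_{k-j}} for `k >= p`. The convention is
#' \eqn{\Gamma_k = E[X_t X_{t-k}']}, with \eqn{\Gamma_{-k} = \Gamma_k'}.
#'
#' @param model A stable `var_model`.
#' @param q Number of lags to return. When `NULL` (default), lags are added
#'   until `||Gamma_q|| / ||Gamma_0|| < tol` (Frobenius) or `q_max` is hit.
#' @param tol Relative decay tolerance for automatic `q`.
#' @param q_max Hard cap on the number of lags.
#' @return An `n x n x (q+1)` array; slice `k+1` holds `Gamma_k`.
#' @export
var_to_autocov <- function(model, q = NULL, tol = 1e-8, q_max = 1000L) {
  stopifnot(inherits(model, "var_model"))
  if (model$radius >= 1)
    stop("model is unstable (companion radius ", format(model$radius),
         "); Lyapunov solution invalid")
  n <- model$n; p <- model$p
  F <- companion_matrix(model$A)
  Q <- matrix(0, n * p, n * p)
  Q[1:n, 1:n] <- model$sigma
  M <- dlyap_doubling(F, Q)
  auto_q <- is.null(q)
  q_end <- if (auto_q) q_max else q
  G <- array(0, dim = c(n, n, q_end + 1L))
  for (k in 0:min(p - 1, q_end))
    G[, , k + 1L] <- M[1:n, (k * n + 1):((k + 1) * n)]
  g0norm <- sqrt(sum(G[, , 1]^2))
  q_used <- min(p - 1, q_end)
  k <- p
  while (k <= q_end) {
    Gk <- matrix(0, n, n)
    for (j in seq_len(p)) Gk <- Gk + model$A[, , j] %*% G[, , k - j + 1L]
    G[, , k + 1L] <- Gk
    q_used <- k
    if (auto_q && sqrt(sum(Gk^2)) / g0norm < tol) break
    k <- k + 1L
  }
  G <- G[, , 1:(q_used + 1L), drop = FALSE]
  dimnames(G) <- list(model$channels, model$channels, NULL)
  attr(G, "fs") <- model$fs
  G
}

#' Solve the Yule-Walker system by Whittle's recursion
#'
#' Multivariate Levinson-Durbin: given autocovariances `Gamma_0..Gamma_q`,
#' returns the coefficients and innovation covariance of the best linear
#' predictor of order `p <= q`.
#'
#' @param autocov `n x n x (q+1)` array as returned by [var_to_autocov()]
#'   (slice `k+1` = `Gamma_k`).
#' @param p Predictor order; defaults to all available lags `q`.
#' @return A `var_model` with the solved coefficients and innovation
#'   covariance.
#' @export
whittle_var <- function(autocov, p = dim(autocov)[3] - 1L) {
  stopifnot(length(dim(autocov)) == 3L, dim(autocov)[1] == dim(autocov)[2])
  q <- dim(autocov)[3] - 1L
  if (p > q) stop("autocov provides ", q, " lags; cannot solve order ", p)
  if (p < 1L) stop("order must be >= 1")
  G0 <- autocov[, , 1]
  ev <- eigen(0.5 * (G0 + t(G0)), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev)) stop("Gamma_0 is singular")
  res <- .whittle_cpp(autocov, as.integer(p))
  fs <- attr(autocov, "fs"); if (is.null(fs)) fs <- 1
  chans <- dimnames(autocov)[[1]]
  var_model(res$A, res$V, fs = fs, channels = chans)
}
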