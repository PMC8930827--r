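#' @name stats_compile
#' @title Trial compilation and between-state inference
#' @description
#' Trial-level metrics tables are long data frames with one row per
#' (state, session, segment, metric). GC tables carry `source`, `target`,
#' `band` and `value`; power tables carry `channel`, `band`, `value`;
#' coherence tables carry `chan1`, `chan2`, `band`, `value`. The functions
#' here filter artifact trials, summarize each state, and test state
#' transitions with linear mixed-effects models (GC) or Mann-Whitney tests
#' (power/coherence), with Benjamini-Hochberg adjustment over each table.
NULL

metric_id <- function(table) {
  if (all(c("source", "target") %in% names(table)))
    paste(table$source, "->", table$target, "|", table$band)
  else if (all(c("chan1", "chan2") %in% names(table)))
    paste(table$chan1, "&", table$chan2, "|", table$band)
  else paste(table$channel, "|", table$band)
}

trial_key <- function(table) {
  paste(table$state, table$session, table$segment, sep = "/")
}

#' Filter outlier trials by a robust per-state rule
#'
#' A trial (segment) is excluded, with all its metrics, when its
#' overall-band summary statistic falls outside `median +/- k * MAD` within
#' its state. For GC tables the summary is the mean overall-band GC across
#' all directed pairs; for power tables it is the total overall-band power
#' across channels. Exclusion is all-or-nothing per trial. When the MAD is
#' (near) zero, no trials are excluded.
#'
#' @param table A trial metrics table (see [stats_compile]).
#' @param k Threshold in MAD units (default 3).
#' @param summary `"gc"` or `"power"`: which summary statistic to use.
#' @return A list with `kept` (the filtered table) and `excluded`
#'   (character vector of `state/session/segment` trial keys).
#' @export
filter_outliers <- function(table, k = 3, summary = c("gc", "power")) {
  summary <- match.arg(summary)
  ov <- table[table$band == "overall", , drop = FALSE]
  if (nrow(ov) == 0) stop("table has no overall-band rows")
  key <- trial_key(ov)
  stat <- if (summary == "gc")
    tapply(ov$value, key, mean) else tapply(ov$value, key, sum)
  key_state <- tapply(ov$state, key, function(s) s[1])
  excluded <- character(0)
  for (st in unique(key_state)) {
    idx <- which(key_state == st)
    if (length(idx) < 5)
      warning("state '", st, "' has fewer than 5 trials; outlier rule weak")
    v <- stat[idx]
    med <- median(v); m <- mad(v)
    if (m < 1e-12 * max(1, abs(med))) next
    out <- abs(v - med) > k * m
    excluded <- c(excluded, names(v)[out])
  }
  kept <- table[!(trial_key(table) %in% excluded), , drop = FALSE]
  if (nrow(kept) == 0) stop("all trials excluded by the outlier filter")
  list(kept = kept, excluded = excluded)
}

#' Per-state summary of each metric
#'
#' Mean, standard error of the mean, trial count and the 95% confidence
#' half-width (`1.96 * SEM`) for every metric within every state.
#'
#' @param table A trial metrics table.
#' @return A data frame with columns `metric`, `band`, `state`, `mean`,
#'   `sem`, `n_trials`, `ci95`.
#' @export
compile_state <- function(table) {
  if (nrow(table) == 0) stop("empty metrics table")
  id <- metric_id(table)
  grp <- interaction(id, table$state, drop = TRUE)
  res <- do.call(rbind, lapply(split(seq_len(nrow(table)), grp), function(ix) {
    v <- table$value[ix]
    n <- length(v)
    sem <- if (n > 1) sd(v) / sqrt(n) else NA_real_
    data.frame(metric = id[ix][1], band = table$band[ix][1],
               state = table$state[ix][1],
               mean = mean(v), sem = sem, n_trials = n,
               ci95 = 1.96 * sem, stringsAsFactors = FALSE)
  }))
  if (any(res$n_trials == 1))
    warning("metrics with a single trial: SEM reported as NA")
  rownames(res) <- NULL
  res
}

# fit one two-state contrast; returns estimate (mean difference state2 -
# state1 adjusted for session clustering) and Wald p-value
fit_transition_lmm <- function(df, s1, s2) {
  df <- df[df$state %in% c(s1, s2), , drop = FALSE]
  df$state <- factor(df$state, levels = c(s1, s2))
  df$session <- factor(df$session)
  singleton <- all(tapply(df$value, df$session, length) == 1)
  if (singleton || nlevels(df$session) < 3) {
    # random-intercept variance unidentified: reduces exactly to OLS
    fit <- lm(value ~ state, data = df)
    sm <- summary(fit)$coefficients
    return(list(estimate = sm[2, 1], p = sm[2, 4], converged = TRUE,
                method = "ols"))
  }
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(value ~ state + (1 | session), data = df, REML = TRUE,
                     control = lme4::lmerControl(calc.derivs = FALSE)))),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(estimate = NA_real_, p = NA_real_, converged = FALSE,
                method = "lmm"))
  sm <- suppressMessages(suppressWarnings(summary(fit)))$coefficients
  list(estimate = sm[2, 1], p = sm[2, 5], converged = TRUE, method = "lmm")
}

#' Between-state comparison with linear mixed-effects models
#'
#' For each metric and state transition, fits a model with a fixed state
#' effect and exchangeable within-session correlation (session random
#' intercept, the compound-symmetry-equivalent structure) by REML; the unit
#' of analysis is one trial-level GC value nested within its recording
#' session. Returns the mean difference and its Wald p-value. When every
#' session contributes a single trial the random-intercept variance is
#' unidentified and the fit reduces exactly to ordinary least squares.
#'
#' @param table A trial metrics table (normally the outlier-filtered GC
#'   table).
#' @param transitions List of 2-element state vectors; defaults to all
#'   ordered state pairs found in the table (in factor order
#'   naive/mild/moderate when applicable).
#' @return A `state_comparison` data frame: `metric`, `band`, `transition`,
#'   `estimate`, `p`, `direction`, `test`, `converged`.
#' @export
lmm_compare <- function(table, transitions = NULL) {
  states <- intersect(LFPGC_STATES, unique(table$state))
  if (length(states) == 0) states <- unique(table$state)
  if (is.null(transitions)) transitions <- state_transitions(states)
  for (tr in transitions) {
    cnt <- table(unique(table[table$state %in% tr, c("state", "session")])$state)
    if (any(cnt < 2))
      warning("fewer than 2 sessions per state in transition ",
              paste(tr, collapse = " -> "))
  }
  id <- metric_id(table)
  rows <- list()
  for (mid in unique(id)) {
    sub <- table[id == mid, , drop = FALSE]
    for (tr in transitions) {
      res <- fit_transition_lmm(sub, tr[1], tr[2])
      rows[[length(rows) + 1L]] <- data.frame(
        metric = mid, band = sub$band[1],
        transition = paste(tr[1], "->", tr[2]),
        estimate = res$estimate, p = res$p,
        direction = if (is.na(res$estimate)) NA_character_
                    else if (res$estimate >= 0) "increase" else "decrease",
        test = res$method, converged = res$converged,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (any(!out$converged))
    warning(sum(!out$converged), " model(s) did not converge; their rows ",
            "carry NA and are excluded from the BH family")
  class(out) <- c("state_comparison", class(out))
  out
}

#' Between-state comparison with Mann-Whitney U tests
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test per metric and
#' transition. P-values are exact when both groups have at most
#' `exact_max` observations and tie-free data; otherwise the normal
#' approximation with tie correction is used. Groups larger than `cap`
#' (when `cap` is finite) are randomly subsampled with the recorded
#' `subsample_seed`.
#'
#' @param table A trial metrics table (power or coherence).
#' @param transitions As in [lmm_compare()].
#' @param cap Maximum group size before subsampling; `Inf` (default)
#'   disables the cap. A cap of 512 mirrors tooling that limits sample
#'   size.
#' @param exact_max Largest group size for which the exact null
#'   distribution is enumerated.
#' @param subsample_seed Seed recorded and used for the subsampling draws.
#' @return A `state_comparison` data frame (see [lmm_compare()]).
#' @export
mwu_compare <- function(table, transitions = NULL, cap = Inf,
                        exact_max = 8L, subsample_seed = 1L) {
  states <- intersect(LFPGC_STATES, unique(table$state))
  if (length(states) == 0) states <- unique(table$state)
  if (is.null(transitions)) transitions <- state_transitions(states)
  id <- metric_id(table)
  rows <- list()
  for (mid in unique(id)) {
    sub <- table[id == mid, , drop = FALSE]
    for (tr in transitions) {
      x <- sub$value[sub$state == tr[1]]
      y <- sub$value[sub$state == tr[2]]
      if (length(x) < 3 || length(y) < 3)
        stop("need >= 3 values per group for metric ", mid)
      if (is.finite(cap)) {
        set.seed(subsample_seed)
        if (length(x) > cap) x <- sample(x, cap)
        if (length(y) > cap) y <- sample(y, cap)
      }
      est <- mean(y) - mean(x)
      if (max(c(x, y)) - min(c(x, y)) < .Machine$double.eps^0.5) {
        warning("all values tied for metric ", mid, "; p = 1")
        p <- 1
      } else {
        exact <- length(x) <= exact_max && length(y) <= exact_max
        wt <- suppressWarnings(
          wilcox.test(y, x, alternative = "two.sided", exact = exact,
                      correct = !exact))
        p <- wt$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        metric = mid, band = sub$band[1],
        transition = paste(tr[1], "->", tr[2]),
        estimate = est, p = p,
        direction = if (est >= 0) "increase" else "decrease",
        test = "mwu", converged = TRUE, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("state_comparison", class(out))
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate:
#' after sorting ascending, `p_adj_(i) = min_{j >= i} (m / j) p_(j)`,
#' capped at 1. Order-preserving and never below the raw p-value.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]` (NAs pass through).
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Adjust a comparison table and flag significance
#'
#' Applies [bh_adjust()] over all (metric, transition) cells of one
#' comparison table (the BH family is the whole table) and adds
#' `p_adj` and `significant` columns.
#'
#' @param comparison A `state_comparison` from [lmm_compare()] or
#'   [mwu_compare()].
#' @param alpha Significance level for the adjusted p-values.
#' @return The comparison table with `p_adj` and `significant` added.
#' @export
adjust_comparison <- function(comparison, alpha = 0.05) {
  comparison$p_adj <- bh_adjust(comparison$p)
  comparison$significant <- !is.na(comparison$p_adj) &
    comparison$p_adj < alpha
  comparison
}

#' Build the state-transition delta report
#'
#' Emits, per transition and band, the matrix of significant directed
#' changes: `+1` for a significant increase, `-1` for a significant
#' decrease, `0` otherwise (non-significant entries are suppressed). Only
#' applicable to pairwise (GC) comparison tables.
#'
#' @param comparison An adjusted comparison table (see
#'   [adjust_comparison()]); if `p_adj` is missing it is added first.
#' @param channels Channel order for the matrices.
#' @param alpha Significance level.
#' @return A list of class `delta_report`: `table` (the adjusted
#'   comparison) and `deltas`, a nested list `deltas[[transition]][[band]]`
#'   of signed channel x channel matrices.
#' @export
build_delta_report <- function(comparison, channels = LFPGC_CHANNELS,
                               alpha = 0.05) {
  if (!"p_adj" %in% names(comparison))
    comparison <- adjust_comparison(comparison, alpha)
  parts <- regmatches(comparison$metric,
                      regexec("^(.*) -> (.*) \\|", comparison$metric))
  src <- vapply(parts, function(x) if (length(x)) x[2] else NA_character_,
                character(1))
  tgt <- vapply(parts, function(x) if (length(x)) x[3] else NA_character_,
                character(1))
  deltas <- list()
  for (tr in unique(comparison$transition)) {
    deltas[[tr]] <- list()
    for (b in unique(comparison$band)) {
      m <- matrix(0, length(channels), length(channels),
                  dimnames = list(source = channels, target = channels))
      diag(m) <- NA_real_
      sel <- which(comparison$transition == tr & comparison$band == b &
                     comparison$significant & !is.na(src))
      for (i in sel)
        m[src[i], tgt[i]] <- if (comparison$direction[i] == "increase") 1 else -1
      deltas[[tr]][[b]] <- m
    }
  }
  structure(list(table = comparison, deltas = deltas, alpha = alpha),
            class = "delta_report")
}

#' @export
print.delta_report <- function(x, ...) {
  nsig <- sum(x$table$significant, na.rm = TRUE)
  cat(sprintf("<delta_report> %d comparisons, %d significant at alpha = %g\n",
              nrow(x$table), nsig, x$alpha))
  invisible(x)
}
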