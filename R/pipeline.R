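#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with the conventional
#' defaults: band-pass 1-150 Hz, notch at 60/120/240 Hz, analysis rate
#' 400 Hz, 300 s GC trials and 30 s spectral trials, Welch 1 s Hann
#' windows at 50% overlap, BIC order selection up to `p_max`, bivariate
#' spectral GC with conditional time-domain GC, median +/- 3 MAD outlier
#' filtering on the overall-band GC summary, mixed-model inference for GC
#' and Mann-Whitney for power/coherence, and BH adjustment per table at
#' alpha 0.05.
#'
#' @param band Band-pass corners in Hz.
#' @param notch_freqs Notch frequencies in Hz.
#' @param target_fs Analysis sampling rate in Hz.
#' @param gc_seglen,psd_seglen Trial lengths in seconds.
#' @param welch_window,welch_overlap Welch estimator parameters.
#' @param p_max Maximum MVAR order for BIC selection.
#' @param gc_freq_step Spectral GC grid step in Hz (grid spans 0 to
#'   Nyquist).
#' @param spectral_mode `"bivariate"` or `"conditional"` spectral GC.
#' @param time_mode `"conditional"` or `"bivariate"` time-domain GC.
#' @param q_max Autocovariance lag cap for reduced-model solving.
#' @param k_mad Outlier threshold in MAD units.
#' @param mwu_cap Group-size cap for Mann-Whitney subsampling (`Inf`
#'   disables).
#' @param alpha Significance level on adjusted p-values.
#' @param seed Seed for the (few) random choices in the analysis, e.g.
#'   Mann-Whitney subsampling.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(band = c(1, 150), notch_freqs = c(60, 120, 240),
                            target_fs = 400, gc_seglen = 300,
                            psd_seglen = 30, welch_window = 1,
                            welch_overlap = 0.5, p_max = 30L,
                            gc_freq_step = 0.5,
                            spectral_mode = c("bivariate", "conditional"),
                            time_mode = c("conditional", "bivariate"),
                            q_max = 200L, k_mad = 3, mwu_cap = Inf,
                            alpha = 0.05, seed = 1L) {
  structure(list(band = band, notch_freqs = notch_freqs,
                 target_fs = target_fs, gc_seglen = gc_seglen,
                 psd_seglen = psd_seglen, welch_window = welch_window,
                 welch_overlap = welch_overlap, p_max = as.integer(p_max),
                 gc_freq_step = gc_freq_step,
                 spectral_mode = match.arg(spectral_mode),
                 time_mode = match.arg(time_mode),
                 q_max = as.integer(q_max), k_mad = k_mad, mwu_cap = mwu_cap,
                 alpha = alpha, seed = as.integer(seed)),
            class = "pipeline_config")
}

# per-trial GC metrics for one normalized segment -> long rows
gc_trial_rows <- function(seg, config) {
  sel <- select_order(seg, p_max = config$p_max)
  p <- sel$order
  freqs <- seq(0, seg$fs / 2, by = config$gc_freq_step)
  Ft <- time_gc(seg$data, mode = config$time_mode, p = p, fs = seg$fs,
                q_max = config$q_max)
  sp <- spectral_gc(seg$data, mode = config$spectral_mode, p = p,
                    freqs = freqs, fs = seg$fs, q_max = config$q_max)
  bands <- band_gc(sp, default_bands("gc"))
  n <- length(seg$channels)
  src <- rep(seg$channels, times = n)
  tgt <- rep(seg$channels, each = n)
  off <- src != tgt
  rows <- list()
  for (b in names(bands))
    rows[[b]] <- data.frame(state = seg$state, session = seg$parent_session,
                            segment = seg$index, source = src[off],
                            target = tgt[off], band = b,
                            value = as.numeric(bands[[b]])[off],
                            stringsAsFactors = FALSE)
  rows[["time"]] <- data.frame(state = seg$state, session = seg$parent_session,
                               segment = seg$index, source = src[off],
                               target = tgt[off], band = "time",
                               value = as.numeric(Ft)[off],
                               stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  attr(out, "order") <- p
  attr(out, "spectrum") <- sp
  out
}

spectral_trial_rows <- function(seg, config) {
  psd <- welch_psd(seg, config$welch_window, config$welch_overlap)
  coh <- coherence_spectra(seg, config$welch_window, config$welch_overlap)
  bands <- default_bands("power")
  n <- length(seg$channels)
  power_rows <- do.call(rbind, lapply(bands, function(b) {
    v <- band_mean(psd, b)
    data.frame(state = seg$state, session = seg$parent_session,
               segment = seg$index, channel = seg$channels,
               band = b$name, value = as.numeric(v),
               stringsAsFactors = FALSE)
  }))
  pair_idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  coh_rows <- do.call(rbind, lapply(bands, function(b) {
    m <- band_mean(coh, b)
    data.frame(state = seg$state, session = seg$parent_session,
               segment = seg$index,
               chan1 = seg$channels[pair_idx[, 1]],
               chan2 = seg$channels[pair_idx[, 2]],
               band = b$name, value = m[pair_idx],
               stringsAsFactors = FALSE)
  }))
  list(power = power_rows, coherence = coh_rows,
       psd = psd, coh = coh)
}

#' Run the full analysis pipeline
#'
#' Executes preprocess -> spectra -> Granger causality -> compilation and
#' statistics on every recording of a study, and (optionally) writes all
#' result tables, the delta report, and the resolved configuration to an
#' output directory. The run is deterministic given the study and the
#' configuration seed.
#'
#' @param study An `lfp_study`, a list of [lfp_recording()]s, or a path to
#'   a study container directory.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @param keep_spectra Keep the per-trial GC spectra and per-state mean
#'   spectra in the result (memory permitting).
#' @return A list of class `lfp_pipeline_result` with the trial tables
#'   (`gc_trials`, `power_trials`, `coherence_trials`), excluded trial
#'   keys, state summaries, the three adjusted comparison tables, the
#'   `delta_report`, the selected model orders, and the resolved config.
#' @export
run_pipeline <- function(study, config = pipeline_config(), out_dir = NULL,
                         keep_spectra = FALSE) {
  if (is.character(study)) study <- read_study(study)
  recs <- if (inherits(study, "lfp_study")) study$recordings else study
  if (length(recs) == 0) stop("pipeline stage [input]: no recordings")
  states <- unique(vapply(recs, function(r) r$state, character(1)))
  gc_rows <- list(); pw_rows <- list(); ch_rows <- list()
  orders <- list()
  mean_psd <- list(); mean_coh <- list(); mean_gcsp <- list()
  nseg_state <- list()
  for (r in recs) {
    gc_segs <- tryCatch(
      preprocess_recording(r, band = config$band,
                           notch_freqs = config$notch_freqs,
                           target_fs = config$target_fs,
                           seg_dur = config$gc_seglen, normalize = TRUE),
      error = function(e) stop("pipeline stage [preprocess]: ",
                               conditionMessage(e)))
    sp_segs <- suppressWarnings(
      preprocess_recording(r, band = config$band,
                           notch_freqs = config$notch_freqs,
                           target_fs = config$target_fs,
                           seg_dur = config$psd_seglen, normalize = FALSE))
    for (seg in gc_segs) {
      rows <- tryCatch(gc_trial_rows(seg, config),
                       error = function(e) stop("pipeline stage [gc]: ",
                                                conditionMessage(e)))
      orders[[paste(r$session_id, seg$index)]] <- attr(rows, "order")
      st <- seg$state
      sp <- attr(rows, "spectrum")
      if (is.null(mean_gcsp[[st]])) {
        mean_gcsp[[st]] <- sp
        mean_gcsp[[st]]$values[is.na(mean_gcsp[[st]]$values)] <- 0
        nseg_state[[st]] <- 1L
      } else {
        v <- sp$values; v[is.na(v)] <- 0
        mean_gcsp[[st]]$values <- mean_gcsp[[st]]$values + v
        nseg_state[[st]] <- nseg_state[[st]] + 1L
      }
      attr(rows, "spectrum") <- NULL
      gc_rows[[length(gc_rows) + 1L]] <- rows
    }
    for (seg in sp_segs) {
      res <- tryCatch(spectral_trial_rows(seg, config),
                      error = function(e) stop("pipeline stage [spectra]: ",
                                               conditionMessage(e)))
      pw_rows[[length(pw_rows) + 1L]] <- res$power
      ch_rows[[length(ch_rows) + 1L]] <- res$coherence
      st <- seg$state
      if (is.null(mean_psd[[st]])) {
        mean_psd[[st]] <- res$psd
        mean_coh[[st]] <- res$coh
        attr(mean_psd[[st]], "n") <- 1L
      } else {
        mean_psd[[st]]$values <- mean_psd[[st]]$values + res$psd$values
        mean_coh[[st]]$values <- mean_coh[[st]]$values + res$coh$values
        attr(mean_psd[[st]], "n") <- attr(mean_psd[[st]], "n") + 1L
      }
    }
  }
  gc_trials <- do.call(rbind, gc_rows)
  power_trials <- do.call(rbind, pw_rows)
  coherence_trials <- do.call(rbind, ch_rows)
  for (st in names(mean_psd)) {
    nn <- attr(mean_psd[[st]], "n")
    mean_psd[[st]]$values <- mean_psd[[st]]$values / nn
    mean_coh[[st]]$values <- mean_coh[[st]]$values / nn
  }
  for (st in names(mean_gcsp))
    mean_gcsp[[st]]$values <- mean_gcsp[[st]]$values / nseg_state[[st]]

  filt <- tryCatch(filter_outliers(gc_trials, k = config$k_mad,
                                   summary = "gc"),
                   error = function(e) stop("pipeline stage [filter]: ",
                                            conditionMessage(e)))
  summaries <- list(gc = compile_state(filt$kept),
                    power = compile_state(power_trials),
                    coherence = compile_state(coherence_trials))
  cmp_stage <- function(expr, what) tryCatch(expr, error = function(e)
    stop("pipeline stage [", what, "]: ", conditionMessage(e)))
  gc_cmp <- cmp_stage(adjust_comparison(
    suppressWarnings(lmm_compare(filt$kept)), config$alpha), "stats-gc")
  pw_cmp <- cmp_stage(adjust_comparison(
    mwu_compare(power_trials, cap = config$mwu_cap,
                subsample_seed = config$seed), config$alpha), "stats-power")
  ch_cmp <- cmp_stage(adjust_comparison(
    mwu_compare(coherence_trials, cap = config$mwu_cap,
                subsample_seed = config$seed), config$alpha),
    "stats-coherence")
  chans <- recs[[1]]$channels
  report <- build_delta_report(gc_cmp, channels = chans,
                               alpha = config$alpha)
  out <- structure(
    list(gc_trials = gc_trials, power_trials = power_trials,
         coherence_trials = coherence_trials,
         excluded_trials = filt$excluded, gc_trials_kept = filt$kept,
         summaries = summaries,
         comparisons = list(gc = gc_cmp, power = pw_cmp, coherence = ch_cmp),
         report = report, orders = unlist(orders),
         mean_spectra = if (keep_spectra)
           list(psd = mean_psd, coherence = mean_coh, gc = mean_gcsp)
         else NULL,
         config = config),
    class = "lfp_pipeline_result")
  if (!is.null(out_dir)) write_pipeline_results(out, out_dir)
  out
}

#' Write pipeline result tables to a directory
#'
#' @param result An `lfp_pipeline_result`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_results <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name)
    write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wr(result$gc_trials, "gc_trials.csv")
  wr(result$power_trials, "power_trials.csv")
  wr(result$coherence_trials, "coherence_trials.csv")
  wr(result$summaries$gc, "gc_state_summary.csv")
  wr(result$summaries$power, "power_state_summary.csv")
  wr(result$summaries$coherence, "coherence_state_summary.csv")
  wr(result$comparisons$gc, "gc_comparison.csv")
  wr(result$comparisons$power, "power_comparison.csv")
  wr(result$comparisons$coherence, "coherence_comparison.csv")
  writeLines(result$excluded_trials, file.path(out_dir, "excluded_trials.txt"))
  jsonlite::write_json(
    lapply(result$report$deltas, function(tr) lapply(tr, function(m) {
      m[is.na(m)] <- 0; unname(as.data.frame(m))
    })),
    file.path(out_dir, "delta_report.json"), digits = NA)
  cfg <- result$config
  cfg$mwu_cap <- if (is.finite(cfg$mwu_cap)) cfg$mwu_cap else "Inf"
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.lfp_pipeline_result <- function(x, ...) {
  cat("<lfp_pipeline_result>\n")
  cat(sprintf("  GC trials: %d rows (%d excluded trials)\n",
              nrow(x$gc_trials), length(x$excluded_trials)))
  cat(sprintf("  spectral trials: %d power rows, %d coherence rows\n",
              nrow(x$power_trials), nrow(x$coherence_trials)))
  nsig <- sum(x$comparisons$gc$significant, na.rm = TRUE)
  cat(sprintf("  GC comparisons: %d cells, %d significant (alpha = %g)\n",
              nrow(x$comparisons$gc), nsig, x$config$alpha))
  invisible(x)
}
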