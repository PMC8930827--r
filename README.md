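# lfpgc

Directed spectral connectivity analysis for multichannel local field
potential (LFP) networks across disease states.

## What this is for

Chronic LFP recordings from a five-node cortico-subthalamic motor
network — left subthalamic nucleus (L-STN), bilateral primary motor
cortex (L-M1, R-M1), and bilateral premotor cortex (L-PMC, R-PMC) —
collected in multiple sessions per disease state (naive, mild, moderate
parkinsonism). The scientific question is which **directed**
interactions change between states, in which frequency band, and in
which direction. `lfpgc` implements the full analysis chain:

1. **Preprocessing** — zero-phase Butterworth band-pass (1–150 Hz),
   zero-phase notch at 60 Hz and harmonics, anti-aliased resampling to
   400 Hz (cutoff 0.45 × target rate), segmentation into 300 s GC
   trials / 30 s spectral trials, per-trial normalization.
2. **Spectra** — Welch PSD and magnitude-squared coherence (1 s Hann
   windows, 50% overlap), with band summaries over *overall*
   (0–50 Hz GC / 5–50 Hz power), *Peak A* (5–20 Hz) and *Peak B*
   (25–45 Hz).
3. **Granger causality** — MVAR models fitted by OLS at a BIC-selected
   order; time-domain GC `F_{y→x} = ln(Σ_red[x,x] / Σ_full[x,x])` in
   conditional or bivariate mode; frequency-domain GC by the Geweke
   decomposition `f_{y→x}(f) = ln( S_xx / (Σ_xx |H̃_xx|²) )` with
   `H̃_xx = H_xx + (Σ_xy/Σ_xx) H_xy`; band-limited GC matrices over the
   5 × 5 pairwise model (20 directed entries).
4. **Statistics** — robust per-state outlier filtering
   (median ± 3 MAD on an overall-band trial summary), per-state
   mean/SEM/95% CI, linear mixed-effects models with a session random
   intercept (compound-symmetry equivalent, REML) for GC,
   Mann–Whitney U for power/coherence, Benjamini–Hochberg adjustment
   per table, and a signed delta report of significant transitions.
5. **Synthetic studies** — a seeded generator of multi-state,
   multi-session studies from stable VAR processes with oscillators at
   15/35 Hz, planted directed couplings with per-state multipliers,
   1/f background, line noise and artifact trials — with exact ground
   truth for validating every stage.

## Worked example

Generate a small synthetic study with the default planted disease
pattern (descending L-PMC→L-STN 15 Hz coupling weakens at disease
onset; ascending L-STN→L-PMC 35 Hz coupling strengthens; R-M1→R-PMC
35 Hz coupling strengthens across both transitions), run the pipeline,
and inspect the report:

```r
library(lfpgc)

spec <- study_spec(sessions_per_state = c(2, 2, 2),
                   session_duration = 300,
                   noise = nuisance_spec(artifact_prob = 0),
                   seed = 11)
study <- generate_study(spec)
cfg <- pipeline_config(gc_seglen = 60, psd_seglen = 30,
                       p_max = 8, q_max = 100)
res <- run_pipeline(study, cfg)
print(res)
#> <lfp_pipeline_result>
#>   GC trials: 2400 rows (2 excluded trials)
#>   spectral trials: 900 power rows, 1800 coherence rows
#>   GC comparisons: 240 cells, 32 significant (alpha = 0.05)

subset(res$comparisons$gc,
       metric == "L-STN -> L-PMC | peakB" & transition == "naive -> mild")
#>                     metric  band    transition estimate          p direction
#> 130 L-STN -> L-PMC | peakB peakB naive -> mild   1.6763 0.00074549  increase
#>     test converged     p_adj significant
#> 130  lmm      TRUE 0.0061696        TRUE

res$report$deltas[["naive -> mild"]][["peakB"]]["L-STN", "L-PMC"]
#> [1] 1    # significant increase, as planted
```

The per-trial band value for a directed pair is the mean of its Geweke
GC spectrum over the band; `estimate` is the between-state mean
difference of that value after adjusting for session clustering, and
`p_adj` is its BH-adjusted Wald p-value. The delta report holds one
signed matrix (+1 increase / −1 decrease / 0 not significant) per band
and state transition.

Real recordings enter the same way via the plain-text study container
(`write_study()` / `read_study()` / `read_recording()`), or through the
thin CLI in `inst/cli/lfpgc.R` (`simulate` and `analyze` subcommands).

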