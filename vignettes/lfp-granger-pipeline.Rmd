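---
title: "Directed connectivity analysis of a cortico-subthalamic LFP network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed connectivity analysis of a cortico-subthalamic LFP network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

`lfpgc` analyses directed effective connectivity in a five-node motor
network recorded with chronic LFP electrodes: left subthalamic nucleus
(L-STN), bilateral primary motor cortex (L-M1, R-M1), and bilateral
premotor cortex (L-PMC, R-PMC). Recordings are grouped into disease
states (naive, mild, moderate parkinsonism), each state contributing
several recording sessions. The question is which directed interactions
change between states, in which frequency band, and in which direction.

Two empirical bands organize the analysis: **Peak A** (5--20 Hz:
theta/alpha/low beta) and **Peak B** (25--45 Hz: high beta/low gamma),
with an **overall** band of 0--50 Hz for Granger causality and 5--50 Hz
for power and coherence. Parkinsonian physiology in this network
concentrates in exactly these ranges, with oscillatory peaks near 15 and
35 Hz.

## The model

Connectivity is estimated from a multivariate autoregressive (MVAR) model

$$X_t = \sum_{j=1}^{p} A_j X_{t-j} + \varepsilon_t,
  \qquad \varepsilon_t \sim (0, \Sigma),$$

fitted per analysis trial by ordinary least squares after BIC order
selection (`select_order()`, `fit_var()`). Granger causality (GC) from
channel $y$ to channel $x$ is the log ratio of innovation variances

$$F_{y \to x} = \ln \frac{\Sigma^{(R)}_{xx}}{\Sigma_{xx}},$$

where the reduced model omits $y$'s past. In **conditional** mode the
reduced model retains all other channels; in **bivariate** mode both
models involve the pair alone. The frequency-domain (Geweke)
decomposition writes the target's spectrum as an intrinsic plus a causal
part via the transfer function $H(f) = (I - \sum_j A_j e^{-2\pi i f j /
f_s})^{-1}$ and the residual rotation
$\tilde H_{xx} = H_{xx} + (\Sigma_{xy}/\Sigma_{xx}) H_{xy}$:

$$f_{y \to x}(f) =
  \ln \frac{\Sigma_{xx} |\tilde H_{xx}|^2 + \Sigma_{yy|x} |H_{xy}|^2}
           {\Sigma_{xx} |\tilde H_{xx}|^2}.$$

Computing numerator and denominator in this additive form keeps both
nonnegative by construction, which matters near spectral nulls.

### Two estimator routes and why both exist

For an *analytic* model (`var_model` input), reduced models are solved
from the model-implied autocovariance sequence: the companion-form
discrete Lyapunov equation gives $\Gamma_0,\dots,\Gamma_{p-1}$
(`var_to_autocov()`, solved by a doubling iteration), the recursion
$\Gamma_k = \sum_j A_j \Gamma_{k-j}$ extends it until
$\|\Gamma_q\|/\|\Gamma_0\| < 10^{-8}$ (capped at `q_max`), and Whittle's
multivariate Levinson-Durbin recursion (`whittle_var()`, implemented in
C++) solves the Yule-Walker system for the reduced predictor. This route
is exact for ground-truth models and is what the analytic zero-coupling
and Geweke-equality checks use.

For *data*, `time_gc()` instead fits full and reduced models by **nested
OLS on a shared lag matrix**: the reduced regression uses a column
subset of the full one, so `SSE_red >= SSE_full` holds by linear
algebra and the estimate is nonnegative without any clamping. This
choice is deliberate: the preprocessing chain (band-pass edges, notch
nulls) leaves the analysed process nearly deterministic in parts of the
spectrum, with innovation variances around $10^{-6}$ on normalized
data. In that regime the truncated-autocovariance route accumulates
relative errors around $10^{-3}$ on the log scale -- larger than real
null-GC values -- while the nested-OLS route stays exact by
construction.

### The Geweke integral identity and its domain

For bivariate models the average of $f_{y\to x}$ over $[0, f_s/2]$
equals $F_{y \to x}$ **when** the rotated transfer element
$\tilde H_{xx}$ is minimum phase. For strongly coupled systems the
condition can fail, and then the spectral average falls strictly below
the time-domain value -- a property of the decomposition, not an
estimation error. `geweke_integral_valid()` checks the condition by
locating the zeros of the rotated numerator polynomial; the package's
consistency checks draw random stable VAR(2) models and verify the
identity to within 1% on the models where it is mathematically
guaranteed (empirically, the predicate separates the two regimes
exactly, with agreement at $10^{-7}$ relative on valid models).

## Preprocessing

The conditioning chain is fixed as band-pass, then notch, then
resampling, then segmentation, then per-segment normalization:

* **Band-pass** 1--150 Hz, Butterworth order 2 per pass, applied
  forward-backward (zero phase). Edge transients are suppressed by
  odd-reflection padding of three filter lengths.
* **Notch** at 60 Hz and harmonics (120, 240 Hz) as a zero-phase biquad
  with quality factor 35 (notch width roughly $f_0/35$ Hz);
  frequencies at or above Nyquist after downsampling are skipped with a
  warning. The design achieves more than 30 dB attenuation at the notch
  center and under 1 dB five Hertz away.
* **Resampling** to 400 Hz with a zero-phase FIR (Hamming-windowed
  sinc) anti-aliasing low-pass cut off at 45% of the target rate -- the
  same convention the acquisition hardware uses -- with a transition
  band of 4% of the target rate, then exact decimation for integer
  ratios or windowed-sinc interpolation at the output sample times
  otherwise. The FIR design keeps the passband flat to a fraction of a
  percent while attenuating above-cutoff probe tones by far more than
  the 20 dB contract.
* **Segmentation** into consecutive non-overlapping trials from sample
  one; the trailing remainder is discarded. Conventional lengths are
  300 s for GC and 30 s for PSD/coherence.
* **Normalization** of each channel within each GC trial to zero mean
  and unit variance. GC is scale-invariant, so this changes estimates
  only at numerical precision, but it removes scale bias from the MVAR
  fit. Normalization is per segment (not per session): each analysis
  trial is self-contained, which is the more conservative reading when
  gain drifts within a session.

## Spectra

PSD and magnitude-squared coherence use Welch averaging with 1 s Hann
windows at 50% overlap (1 Hz resolution, matching the band-edge
granularity), computed per 30 s trial and averaged within state.
Coherence needs at least 8 averaging windows (upward bias is roughly
one over the window count); a single window is refused outright. Band
summaries are arithmetic means over grid frequencies with inclusive
edges -- stated explicitly because a half-open convention would move
band means on a 1 Hz grid.

## The synthetic study generator

Because the original recordings are not deposited, validation runs on a
generator whose ground truth is known exactly:

* Each channel carries damped AR(2) resonators at 15 and 35 Hz (pole
  radius 0.95 at 400 Hz, multiplied into one AR(4) diagonal),
  reproducing the two-peak spectral structure.
* Directed couplings are short FIR filters on the source channel with
  unit gain at the coupling frequency and exact nulls at the other
  oscillator frequency, so the induced GC peaks where intended. The
  default network plants the headline disease pattern: the descending
  L-PMC to L-STN coupling at 15 Hz weakens at disease onset
  (multipliers 1, 0.3, 0.3 across naive/mild/moderate), the ascending
  L-STN to L-PMC coupling at 35 Hz strengthens (0.2, 1, 1), and the
  right cortico-cortical R-M1 to R-PMC coupling at 35 Hz strengthens
  across both transitions (0.2, 0.9, 1.8). Coupling gain defaults to
  0.15; no generative effect sizes exist to copy, so these are chosen
  to give band-limited GC changes of order 0.1--1, comparable to the
  across-band contrasts the method is meant to resolve.
* Nuisances: $1/f$ pink noise (spectrally shaped white noise, amplitude
  0.5 relative to unit innovations), a 60 Hz mains sinusoid with 2nd
  and 3rd harmonics, and -- with probability 0.05 per recording -- a
  whole-recording amplitude inflation by a factor 10 emulating a
  movement artifact, the simplest mechanism the outlier filter can
  detect.
* Stability is enforced: every state model must have companion spectral
  radius below 1, with uniform shrinkage of cross-couplings (factor 0.7
  per iteration, recorded in the model) if assembly overshoots.
* Determinism: every draw flows from the study seed through fixed
  per-session sub-seeds, so a `(spec, seed)` pair reproduces the
  dataset bit for bit.

The default design mirrors a 15/16/5 sessions-per-state study. What the
generator does **not** emulate: volume conduction and shared references
(which inflate zero-lag correlations in real ECoG), nonstationarity
within sessions, state-dependent artifact rates, and non-Gaussian
innovations. Passing tests therefore demonstrate correctness of the
estimators and the inference layer under the stated generative model,
not robustness to those real-data effects.

## Trial compilation and statistics

* **Outlier filter**: a trial is excluded -- with all its metrics --
  when its overall-band summary (mean overall-band GC across the 20
  directed pairs, or total overall-band power for the spectral
  pipeline) falls outside median $\pm$ 3 MAD within its state (MAD with
  the usual 1.4826 consistency constant; no exclusions when the MAD is
  numerically zero). On default synthetic studies this retains roughly
  90% of trials. Power/coherence trials are not filtered: their much
  larger trial counts make the state means robust.
* **State summaries**: mean, SEM, and a 95% interval of 1.96 SEM per
  metric and state, computed from per-trial band values (band-limiting
  happens before averaging, never on an averaged spectrum).
* **GC inference**: one linear mixed-effects model per metric and state
  transition, with a fixed state effect and a session random intercept
  -- the exchangeable (compound-symmetry) correlation structure --
  fitted by REML via `lmer`; p-values are Wald tests with Satterthwaite
  degrees of freedom. When every session contributes one trial the
  random intercept is unidentified and the model reduces exactly to
  OLS, which the implementation does explicitly.
* **Power/coherence inference**: two-sided Mann-Whitney U tests, exact
  for group sizes up to 8, normal approximation with tie correction
  otherwise. A group-size cap with seeded subsampling is available
  (mirroring tools limited to 512 samples) but off by default, since
  the cap was a tool limitation rather than a method.
* **Multiplicity**: Benjamini-Hochberg step-up over all
  metric-by-transition cells of one comparison table (one family per
  table, mirroring a per-table presentation); adjusted p-values below
  0.05 are flagged, and the delta report shows only significant cells
  as signed (increase/decrease) entries in channel-by-channel matrices
  per band and transition.

## Numerical choices

* Stability margin: companion radius must stay below $1 - 10^{-6}$.
* GC log arguments are floored at $10^{-12}$ relative scale. In the
  analytic route, negative excursions smaller than $10^{-6}$ in
  magnitude are clamped to zero -- Whittle solves at orders of several
  hundred on near-unit-radius models carry rounding around $10^{-8}$ on
  the log scale -- and anything worse raises an error. The data route
  is nonnegative by construction and needs no tolerance.
* Autocovariance decay tolerance $10^{-8}$ with a lag cap (`q_max`,
  default 200) because fitted models on oscillatory data sit close to
  the stability boundary.
* Spectral GC grid: 0 to Nyquist in 0.5 Hz steps; band summaries use
  0--50 Hz, and 0 Hz is included in the overall GC band.
* BIC uses the maximum-likelihood residual covariance on a common
  effective sample span (all candidate orders start at `p_max + 1`), so
  criteria are comparable across orders; the OLS residual covariance
  for the reported model uses the `T - n p - 1` denominator.

## Problem sizes used in validation

The test suite and the acceptance script exercise the full pipeline on
scaled study designs chosen to keep whole-suite wall time modest while
leaving every stage statistically meaningful: two to five sessions per
state of 120--300 s, 60 s GC trials (so 8--10 GC trials per state),
30 s spectral trials, `p_max` 8, and replicate counts of 6--10 for the
null-calibration and sign-recovery studies. The planted effects are the
package defaults; detection rates at these sizes are at or near 100%,
so the scaled designs do not sit near the decision boundary.

## Known limitations

* The pipeline assumes the montage channels are already derived bipolar
  signals; no re-referencing is performed.
* Conditional *spectral* GC is provided and validated against the
  bivariate reduction at $n = 2$, but the pipeline default pairs
  bivariate spectral GC with conditional time-domain GC; the paired
  choice is configurable.
* Mixed-model p-values rely on Satterthwaite approximations; with very
  few sessions per state they are approximate, and the type-I error is
  verified by simulation to sit near nominal rather than derived
  exactly.
* Heavy pre-filtering is part of the standard conditioning chain, but
  users adding deeper notches or narrower bands should expect GC
  numerics to degrade first near the filtered-out frequencies.
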