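---
title: "Ensemble noise and kinetic analysis of AMPA-receptor currents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble noise and kinetic analysis of AMPA-receptor currents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampanoise)
```

## The problem

Fast excitatory transmission is carried by AMPA-type glutamate receptors
(AMPARs), tetramers of GluA1–4 subunits whose single-channel behaviour is
reshaped by auxiliary TARP subunits such as stargazin (γ2). A receptor can
carry zero, two or four TARPs, and the stoichiometry matters: conductance,
desensitization, recovery from desensitization and polyamine block all
change with TARP number and, in GluA2-containing heteromers, with *which*
subunit the TARP sits on. None of these single-channel quantities is
observed directly in a macroscopic patch-clamp recording; they are inferred
from the statistics of repeated agonist-evoked responses.

This package implements that inference chain for sweep ensembles recorded
from outside-out patches — non-stationary fluctuation analysis (NSFA),
bi-exponential desensitization fitting, two-pulse recovery analysis and
rectification-index computation — together with a stochastic sweep
simulator whose presets encode seven AMPAR/TARP conditions
(calcium-permeable GluA1 homomers with 0/2/4 TARPs; calcium-impermeable
GluA2/GluA4c heteromers with the TARP on neither, either, or both
subunits). Because the simulator's generative parameters are the reported
condition means, parameter recovery on synthetic ensembles is a direct,
quantitative validation of each estimator.

## The generative model

A patch holds `N` identical channels of single-channel conductance `g`
(pS). At holding potential `V` (mV, after liquid-junction correction) each
open channel passes `i = g·|V|/1000` pA. At every sample time channels
gate independently:

$$n_\text{open}(t) \sim \mathrm{Binomial}\big(N,\, p(t)\big), \qquad
I(t) = i\, n_\text{open}(t) + \varepsilon(t),\quad
\varepsilon \sim \mathcal N(0, \sigma_B^2),$$

with draws independent across sweeps and time points. The open-probability
waveform `p(t)` rises exponentially (time constant `tau_rise`, complete at
`5·tau_rise`), peaks at `po_peak`, then desensitizes bi-exponentially
toward a plateau `ss_fraction·po_peak`:

$$p(t) = p_o\left[s + (1-s)\left(f e^{-t'/\tau_f} +
(1-f) e^{-t'/\tau_s}\right)\right]$$

where `t'` counts from the peak. Starting the decay clock at the peak is a
deliberate choice: the amplitude shares seen by a peak-to-end fit are then
exactly `f` and `1−f`, so the generative weighted time constant
`τ_w = f·τ_f + (1−f)·τ_s` is the quantity the analysis should recover.
Gating is binomial-independent occupancy around a deterministic `p(t)`
rather than a Markov chain — precisely the model under which the NSFA
parabola below is unbiased, which keeps recovery tests interpretable.
Markov/Gillespie gating, agonist-binding schemes and mechanistic polyamine
permeation are out of scope.

Under this model the ensemble variance at each time point is

$$\sigma^2(t) = \sigma_B^2 + i\,\bar I(t) - \bar I(t)^2/N,$$

the parabola NSFA fits.

Two protocol extensions reuse the same waveform. The two-pulse protocol
scales the second pulse by the recovered fraction
`1 − (1 − ss)·exp(−Δt/τ_rec)` (intervals are onset-to-onset; the
desensitization depth remaining at the end of pulse 1 is taken to be the
plateau fraction — the choice only offsets the recovery curve, not its
time constant). The current–voltage family scales the driving current
linearly with `V` and, for `V > 0`, multiplies it by an empirical Boltzmann
block factor `b(V) = 1/(1 + exp((V − V₅₀)/k))` emulating intracellular
polyamine block; `V₅₀` is calibrated so `b(+60 mV)` equals the condition's
target rectification index. This is an empirical calibration, not a
permeation model: the rectification index is defined operationally and no
block equation is assumed.

## Presets and defaults

```{r presets}
preset_truth()
```

Each preset's conductance, peak open probability, weighted desensitization
tau, steady-state percentage, recovery tau and (for the calcium-permeable
conditions) the RI calibration are the per-condition means; everything the
condition summaries leave unquantified uses documented defaults chosen
once:

* `n_channels = 400` and `sigma_b2 = 1` pA² — typical of macroscopic
  outside-out responses of a few hundred pA with ~1 pA baseline noise;
* `tau_rise = 0.2` ms, consistent with sub-millisecond (≲0.4–0.7 ms) rise
  times of rapid-perfusion responses;
* the decay is split as `f = 0.85`, `τ_s = 4·τ_f`, solved so the weighted
  tau matches the condition mean (only `τ_w` is reported per condition);
* for the calcium-impermeable heteromers, Po (0.55), plateau (5%) and
  recovery tau (30 ms; 60 ms for the GluA2-TARP placement, which recovers
  more slowly) are representative defaults, and the fully TARPed heteromer
  conductance (16.5 pS) is synthetic — these are not recovery targets.

## The estimators

**Run-down screening.** Excised-patch responses run down; NSFA needs a
stationary epoch. `select_stable_epoch()` returns the longest contiguous
window of 50–350 sweeps whose peak amplitudes show no significant monotone
trend by a two-sided Spearman rank test (default α = 0.05), ties broken by
the earliest start — a declared convention where several stable windows
coexist. Finding no epoch is an explicit outcome, not an error.

**Pairwise ensemble variance.** `pairwise_variance()` uses successive
differences, `var(t) = Σ_k d_k(t)²/(2K)` — the local estimator implied by
"variance of successive pairs", insensitive to residual slow drift. No
peak scaling is applied (scaled NSFA is a different method and a
non-goal). The background variance is the baseline-window average of the
variance trace.

**Parabolic fit.** `fit_parabola()` restricts to the decay phase (peak to
pulse end; the rising phase is excluded because opening-latency
correlations violate the binomial assumption there), bins points into 10
equal-count bins of mean current, and solves the parabola by weighted
linear least squares — the model is linear in `(i, 1/N)`, so no iterative
optimiser is needed and "non-convergence" reduces to a sign check on the
fitted curvature, which is flagged rather than silently returned. One
numerical subtlety matters: with equal-count bins most of a strongly
desensitizing decay sits near the plateau and the top bin spans nearly the
whole current range; evaluating the parabola at the bin-mean current
would bias the curvature (a Jensen effect, up to ~2× on `N`). Both
regressors (`I` and `I²`) are therefore averaged within bins, which makes
the aggregation exact for this model at any bin width. Background
variance is subtracted by default (`fix_background = TRUE`); a free-
background mode is provided since either reading of the method is
defensible, and the two agree on simulated data.

Derived quantities: `g = 1000·i/|V|` at the corrected holding potential
(−55 mV in the presets) and `P_o,peak = I_peak/(i·N)`; a `P_o` above 1 is
flagged.

**Kinetics.** `fit_desensitization()` fits
`A_f e^{−t/τ_f} + A_s e^{−t/τ_s} + C` from peak to pulse end
(Levenberg–Marquardt via minpack.lm) and reports the amplitude-weighted
τ_w; when the two components degenerate (τ ratio < 1.2 or a share < 2% —
conventions recorded in the output) it falls back to a single exponential.
Rise time defaults to the 10–90% definition with onset-to-peak as an
alternate mode, since summaries of "time to peak" are ambiguous between
the two; both are emitted by the pipeline. The steady-state percentage
uses the last 10 ms of the 100-ms pulse, a window chosen once (the
measurement window is otherwise unspecified).

**Recovery.** `fit_recovery()` fits `P2/P1 = 1 − A·exp(−Δt/τ)` by default;
a double-exponential mode summarised by the same weighted-τ formula is
available, but a single recovery constant is what per-condition summaries
report, so single is the default. Ratios indistinguishable from 1 at all
intervals are flagged as below the protocol's resolution.

**Rectification.** `build_iv()` assembles peak current against voltage and
computes `RI = |I(+60)|/|I(−60)|`; the 0.7 cut point used to call
heteromer-dominated patches is exposed as a named constant with a
classification helper — it is an analysis rule, not physics. No leak
subtraction is performed.

## Worked example

```{r example}
m <- ampar_preset("CP_0T")
s <- simulate_sweeps(m, n_sweeps = 100, seed = 1)
nsfa(s)
```

```{r kinetics}
mt <- mean_trace(s)
fit_desensitization(s$time_ms, mt, t_end = s$t0_agonist + s$pulse_dur)
```

## Numerical choices and degenerate inputs

* Sampling uses `dt = 0.05` ms (20 kHz); analyses are grid-based, so any
  even sampling works.
* All simulation is seeded and bit-reproducible given
  `(model, protocol, seed)`.
* Zero-variance (identical) sweeps yield a zero variance trace, not an
  error; a variance–mean relation with non-negative curvature (no channel
  signal) yields a flagged failed fit.
* Two-pulse intervals shorter than the pulse are rejected (pulses would
  overlap); `V = 0` is a valid I-V point with zero expected current;
  an I-V family missing ±60 mV still builds, with the RI flagged absent.
* The end-to-end `run_condition()` records per-stage errors and continues
  with the stages that do not depend on the failure.

## What the simulations do and do not show

Validation problem sizes are chosen to mirror the experimental protocol:
100-sweep ensembles for NSFA (within the 50–350 stable-response range used
for epoch selection), 200-sweep averages for kinetics, 20 sweeps per
recovery interval over 20–720 ms, and ~30 sweeps per voltage for I-V
families, each repeated over 20 seeds where a mean is quoted. At these
sizes the recovered conductances sit within ~1% of the generative truths
(SEM ≈ 0.15%), comfortably inside the 5–10% acceptance bands.

Passing these tests shows the estimators are unbiased *under the
generative model* — binomial gating around a deterministic waveform with
white Gaussian baseline noise. Real recordings violate this in ways the
simulator deliberately does not emulate: correlated gating and modal
behaviour, multiple conductance sublevels, series-resistance and filtering
artefacts, non-white noise, and solution-exchange limitations. The
recovery tests are also circular by design where the generative truth is
itself a reported mean: they validate the implemented estimators, not the
underlying biology. Group-level hypothesis testing between conditions is
out of scope.
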