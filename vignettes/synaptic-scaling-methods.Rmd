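---
title: "Quantal synaptic scaling analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantal synaptic scaling analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Neurons that lose synaptic drive for long periods can compensate by
*synaptic scaling*: a slow, global increase of excitatory synaptic strength
in which every synapse is multiplied by a common factor. The experimental
signature is read from miniature excitatory postsynaptic currents (mEPSCs)
— the quantal responses to single-vesicle release recorded under TTX in
voltage clamp. If a treated population of neurons has scaled
multiplicatively relative to controls, then pairing the two amplitude
distributions rank by rank (an equal-count quantile–quantile pairing)
produces a straight line whose slope *is* the scaling factor; dividing the
treated distribution by that slope should collapse it onto the control
distribution. Synapse-specific potentiation (LTP-like changes) breaks this
linearity instead. `synscale` implements that entire analysis — detection,
rank-order fitting, threshold-aware down-scaling, distribution testing —
together with the companion analyses used in the same preparations:
intrinsic excitability from current-clamp step families, and fictive
respiratory burst analysis in two-channel integrated nerve recordings
across drug epochs. A ground-truth synthetic-data generator makes every
stage testable without any recordings.

## Event detection

`detect_events()` is a threshold-crossing detector on the
baseline-subtracted, low-pass-smoothed current:

1. **Smoothing.** The trace is low-pass filtered at 1 kHz (default) with an
   exactly zero-phase filter: the squared magnitude response of a 4th-order
   Butterworth — what a forward–backward pass applies — multiplied onto the
   spectrum. This keeps onset and peak times unshifted and costs
   O(n log n) at any sampling rate.
2. **Baseline.** A running median over 200 ms tracks the holding current.
   The median is computed on a decimated grid (about 100 points per window)
   and linearly interpolated back; the baseline varies far more slowly than
   the window, so this is exact for practical purposes and keeps the cost
   flat in the sampling rate.
3. **Candidates.** Inward excursions of the baseline-minus-smoothed signal
   that reach the rejection threshold (7.5 pA by default — roughly twice
   the background noise of the target recordings, below which detection is
   unreliable) become events; excursions closer than 5 ms are merged, and
   the onset is backtracked to the last baseline crossing.
4. **Measurement.** Amplitude is the *raw* (unsmoothed) deviation averaged
   over ±0.4 ms at the peak: averaging the raw signal avoids the systematic
   attenuation a filtered peak would carry, while suppressing
   single-sample noise; on noiseless events the measured amplitude is
   within ~0.5% of truth. Rise time is onset to peak — deliberately *not*
   10–90% — because the quantity reported downstream is defined that way;
   users comparing against 10–90% conventions should convert. Charge is the
   integral of the raw deviation from onset until the smoothed signal
   returns within 2.5% of the event amplitude of baseline (capped at
   100 ms). The *relative* return criterion — equal to the typical 0.5 pA
   at a 20 pA event — makes charge exactly scale-equivariant: doubling
   every deviation doubles every charge, a property the test suite asserts
   exactly.

Events riding on the decaying tail of a predecessor (onset within 100 ms of
the previous peak) are measured from the local elevated baseline and
flagged `overlapped`; the small resulting amplitude bias is accepted and
visible in the flag.

## The rank-order scaling procedure

Per neuron, the first 50 detected events from the analysis minute are
pooled (`first_n_amplitudes()`), giving 800 points per group for the
default 16-neuron cohorts. `rank_order()` sorts both pooled samples
ascending and pairs by rank; `fit_rank_linear()` is OLS of treated on
control, so a slope above 1 means up-scaling, and the intercept is fitted
freely (and reported) rather than forced through the origin — under pure
scaling it should be near 0, and that is worth checking rather than
assuming. `fit_rank_exponential()` fits `y = a·exp(b·x)` by nonlinear least
squares (log-linear initialization; r² on the original scale) as the
LTP-signature alternative; two parameters mirror the two-parameter line.

`downscale()` divides treated amplitudes by the fitted slope and removes
scaled values below the detection threshold: such values cannot appear in
the control distribution (they were undetectable), so keeping them would
bias the distribution comparison. Only the down-scaled distribution is
truncated; the control sample is left intact, which is the procedure the
analysis models. An alternative — symmetric truncation of the control
distribution at the same effective threshold — is a defensible variant we
considered; it is not the default because the asymmetric rule is the
documented procedure, and the truncation bias it leaves in the slope is
small under amplitude laws with little sub-threshold mass (see
*Estimator behavior* below).

`ks_compare()` wraps the two-sample Kolmogorov–Smirnov test; p-values are
exact (via the Smirnov distribution) when `n_a·n_b ≤ 10⁴` and asymptotic
otherwise, and the mode used is always recorded. The pipeline verdict
(`multiplicative`) requires all three: linear r² above exponential r², a
significant raw KS difference, and a non-significant KS difference after
down-scaling (α = 0.05 by default).

### Estimator behavior

Two properties of this estimator are worth knowing, and both are computed
by the test suite rather than assumed:

* **Truncation bias.** Detecting both cohorts at the same absolute
  threshold truncates the control law more than the treated law (whose
  scaled equivalent threshold is lower). With the default amplitude law
  this inflates the fitted slope by roughly +0.01–0.02 at a true factor of
  1.51 — well inside the acceptance band, but not zero.
* **Top-rank variance.** With a right-skewed (lognormal) amplitude law the
  uppermost rank pairs are extreme order statistics, and they dominate the
  r² of the linear fit. At 800 points and σ = 0.45 the fit r² is typically
  ≈ 0.99 but falls below 0.99 in roughly a third of replicates; a
  requirement that r² ≥ 0.99 in ≥95% of replicates is not attainable under
  this amplitude law even with perfect detection. The acceptance suite
  states that check at its face value and reports the measured fraction
  honestly.

## The synthetic-data generator

`generate_mepsc_trace()` draws a Poisson number of events, assigns
lognormal amplitudes, and sums unit-peak biexponential kernels
(`exp(-t/τ_d) − exp(-t/τ_r)`, normalized on the discrete grid so an
injected amplitude is hit exactly at the sampled peak) onto baseline plus
Gaussian noise; events are inward, as for AMPA-mediated currents at
−80 mV. Defaults and why:

| parameter | default | rationale |
|---|---|---|
| amplitude law | lognormal, median 18 pA, σ = 0.45 | right-skewed, as quantal amplitudes are; <2% of mass below the 7.5 pA threshold so truncation barely perturbs recovery studies |
| kernel | τ_rise 1 ms, τ_decay 8 ms | typical fast AMPA kinetics; only rise time is reported downstream |
| noise | 2 pA SD | threshold ≈ 2× noise, matching the stated rationale for 7.5 pA |
| event rate | 1.5 /s | makes ≥50 events per one-minute record essentially certain, which the first-50 design requires |
| sampling rate | 100 kHz | voltage-clamp acquisition rate of the target recordings |

`generate_scaled_cohorts()` runs the identical generative process for both
cohorts and multiplies every treated amplitude by the factor before trace
synthesis; event times are independent. Per-neuron seeds derive from the
master seed by fixed prime offsets, so one integer reproduces both cohorts
bit for bit.

`generate_fi_sweeps()` simulates the 24-step current-clamp protocol
(−150 pA to +1000 pA in 50 pA steps, 0.5 s each) with a leaky
integrate-and-fire neuron — the simplest spiking model with a closed-form
firing-rate curve, which gives the excitability analyses an analytic
oracle: `f = 1/(t_ref + τ_m·ln(ΔV∞/(ΔV∞ − ΔV_th)))`. The per-sample update
uses the exact exponential propagator, so the only discretization error is
the one-sample rounding of threshold crossings.

`generate_neurogram()` emulates *integrated* two-channel nerve recordings:
positive half-sine burst envelopes (~1 s, the fictive lung-breath
signature) at shared times over a noisy baseline, the companion channel
offset by a configurable lag. Burst times follow a renewal process
(exponential gap plus a dead time of one burst duration + 1 s) whose mean
interval is exactly the reciprocal of the requested rate, so recovered
epoch frequencies are unbiased — a naive thinned Poisson process would
under-deliver at high rates. Three 10-minute epochs
(baseline → drug → washout) apply multiplicative amplitude and frequency
effects; the defaults (amplitude ×0.6, frequency ×0.2 in drug; partial
recovery in washout) emulate a low-dose AMPA-receptor antagonist that
silences most of the rhythm while reducing motor-pool output by ~40%.

What the generator deliberately does *not* model: dendritic filtering and
space-clamp error, series-resistance artifacts, correlated or 1/f noise,
mEPSC kinetic variability, burst-shape variability beyond amplitude, and
buccal (short, fast) bursts. Tests passing on this generator therefore
certify the *analysis* under its stated assumptions; they do not certify
robustness to those recording pathologies.

## Intrinsic excitability

`input_resistance()` regresses the steady-state voltage deflection (mean
of the last 100 ms of the step — at least five membrane time constants for
plausible cells) on injected current over the non-positive steps;
`resting_potential()` averages the pre-step baseline and applies the
−12 mV liquid-junction correction exactly once (traces flagged as already
corrected are refused). `fi_gain()` counts spikes (upward 0 mV crossings,
2 ms refractory — robust for >50 mV spikes from rest near −60 mV) and fits
rate against current over all non-negative steps, matching the definition
of gain as the slope of the mean-rate/current relation; a
suprathreshold-only option exists because conventions differ.
`compare_fi_slopes()` implements the group comparison as a
homogeneity-of-slopes ANCOVA (`rate ~ current × group`), reading "the
slopes differ" from the interaction term, plus an unpaired t test on
per-neuron gains.

The type-I calibration of the ANCOVA runs on its own statistical null —
a common linear rate–current relation with iid Gaussian noise per
neuron-step — rather than on duplicated deterministic LIF simulations,
which would have zero residual variance and a degenerate F statistic.
(Per-neuron *slope heterogeneity* under the null would instead inflate the
fixed-effects test; that caveat applies to the real analysis too and is
the reason the per-neuron gain t test is reported alongside.)

## Burst analysis

`condition_neurogram()` reproduces the standard conditioning chain for raw
nerve signals — 100–1000 Hz band-pass, full-wave rectification, leaky
integration with a 60 ms time constant — and applies only when raw input
is supplied; the analysis otherwise consumes already-integrated traces.
`detect_bursts()` thresholds the baseline-subtracted integrated trace at
baseline + 4×MAD (robust to burst contamination of the baseline estimate)
with hysteresis exit at 2×MAD, keeps excursions lasting 0.3–3 s
(operationalizing "~1 s" bursts), and classifies a vagal burst as
respiratory only when the hypoglossal channel has an onset within ±0.5 s
(operationalizing "near-synchronous"). On noise-free traces the MAD is
zero and the threshold falls back to a small fraction of the peak
deviation. Amplitude is peak minus the mean of the 1 s preceding onset,
with the peak taken on a 100 ms moving average — the averaging suppresses
the upward bias a noisy maximum carries, and its slight multiplicative
attenuation cancels in the percent-of-baseline quantities that are the
only cross-preparation comparisons the API offers (absolute integrated
amplitudes are not comparable between preparations). Area is the
baseline-subtracted integral clipped at zero.

## Statistics

`unpaired_t()` (Student or Welch — chosen explicitly per call; an `auto`
variance-test mode exists but is never the default, to keep analyses
reproducible), `mann_whitney()` (exact for ≤8 per group without ties,
normal approximation with tie/continuity correction otherwise, mode always
recorded), `paired_t()`, and `ancova_slopes()` all return one-row tidy
`TestResult` tibbles. No multiple-testing correction is applied anywhere —
comparisons are reported per test, and `run_study()`'s stats table lists
every test run so the reader can count them. Exact small-sample KS and
Mann–Whitney p-values are verified in the test suite against brute-force
enumeration over all rank arrangements — an oracle that shares no code
with the implementations.

## The study pipeline

`validate_config()` normalizes a YAML or list configuration (defaults:
7.5 pA threshold, 50 events/neuron, 16 neurons/group, α = 0.05, 10-minute
epochs — the out-of-the-box run reproduces the modeled study design) and
rejects unknown keys with their key path. `run_study()` composes the whole
desk-scale study deterministically from one seed, in simulate or ingest
mode, and writes the CSV report set plus a human-readable summary when an
output directory is set. In simulate mode the excitability arm draws
per-neuron input resistance from a population distribution and adds
membrane noise, so the group comparison has genuine biological and
measurement variability under the null.

## Problem sizes used in the simulation studies

The test suite and the acceptance script run the rank-order recovery at
16 neurons × 2 cohorts × 100 replicates with 40 s of recording per neuron
at 5 kHz and 2.25 events/s. These sizes are the package's declared
simulation scale for this design: they preserve every element that matters
to the estimator (16 neurons, ≥50 detectable events each, the 7.5 pA
threshold, the lognormal law, factor 1.51) while keeping a full
100-replicate study tractable on a single CPU. Detector fidelity is
measured at 10 kHz on 20 s traces (200 replicates); burst recovery uses
full 3×10-minute neurograms at 200 Hz (150 replicates); the type-I
calibrations use 500 replicates per test.

## Known limitations

* One event per supra-threshold excursion: two events closer than the
  merge refractory are counted once. At the default rates this loses ~1%
  of events and does not bias amplitudes.
* The detector is certified on the generator's assumptions (white noise,
  stationary baseline, stereotyped kinetics); real recordings with drifting
  series resistance or correlated noise need the QC filters and visual
  checks, as in any mEPSC analysis.
* The exponential rank-order alternative is a two-parameter summary, not a
  mechanistic LTP model; synapse-specific potentiation produces a kink
  that neither the line nor the exponential fits well, which is exactly
  why the verdict also requires the KS collapse after down-scaling.
* Percent-of-baseline burst statistics require a baseline epoch with
  bursts; silent baselines are flagged, not imputed.
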