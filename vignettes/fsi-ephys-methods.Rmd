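---
title: "Measuring and simulating fast-spiking interneuron electrophysiology with fsiephys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and simulating fast-spiking interneuron electrophysiology with fsiephys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`fsiephys` implements a complete intracellular-electrophysiology analysis for
cortical fast-spiking interneurons (FSIs), together with a conductance-based
simulator that generates matched "vehicle" and "mk801" phenotype cohorts so
that every analysis runs end-to-end without external recordings.  The
measured quantities are the standard whole-cell battery:

* passive properties — resting potential, input resistance from the
  steady-state voltage deflection at the end of 600 ms hyperpolarizing
  steps, membrane time constant from a single-exponential fit to the
  relaxation under a −300 pA step, and sag (end-of-step voltage minus the
  maximal hyperpolarization);
* spike timing — rheobase as the smallest amplitude giving exactly one
  spike on three consecutive trials (1–5 pA increments), first-spike
  latency from stimulus onset to the threshold crossing, and the two-regime
  latency–current analysis on log–log axes;
* spike shape — threshold at the first sample where dV/dt reaches
  10 mV/ms (validated against a ≥20-fold elevation over the mean baseline
  |dV/dt|), half-width at the half-amplitude level between threshold and
  peak, afterhyperpolarization from threshold to trough, phase plots
  (dV/dt against Vm by central differences on the raw trace);
* trains — maximum spike frequency, the ISI accommodation ratio (first ISI
  over the mean of the last three), and the first/second spike amplitude
  ratio;
* synaptic currents — spontaneous event detection (derivative trigger plus
  amplitude criterion), evoked-EPSC averaging under minimal stimulation
  with success/failure classification, bi-exponential decay fits with the
  amplitude-weighted time constant
  $\tau_W = (A_1\tau_1 + A_2\tau_2)/(A_1 + A_2)$, charge integrals, and
  percent peak / charge / $\tau_W$ changes under a selective GluN2B
  antagonist (ifenprodil);
* group statistics — per-feature mean ± SEM with n, two-tailed
  equal-variance t-tests and one-way ANOVA (identical for two groups,
  $F = t^2$), and percent differences.  No multiple-testing correction is
  applied, and this is recorded in the table metadata.

# The simulated cell

The simulator is a single-compartment Hodgkin–Huxley-type model with a
transient Na⁺ current (instantaneous activation $m_\infty^3$, inactivation
$h$), a Kv3-like fast delayed rectifier ($n^2$) that supports the narrow
spikes and fast AHP of FSIs, an ohmic leak, a Kv1-like D-type K⁺ current,
and (in the mk801 preset) a slow spike-activated adaptation K⁺ current.
Gates follow logistic steady-state curves
$x_\infty(V) = 1/(1+\exp(-(V-\theta_x)/\sigma_x))$ with fixed constants
returned by `fsi_kinetics()`.  Units are mV, ms, pA, nS and pF throughout.

The D-current is the mechanistic core.  Its activation gate is
low-threshold and partially open at rest, so it contributes several nS of
resting conductance (lowering input resistance), and its inactivation gate
is slow ($\tau_b$ = 100 ms) with a floor (`b_min` = 0.4) so that the
current never inactivates completely at subthreshold potentials.  Near
rheobase the D-current brakes depolarization and the first spike is
released only after partial inactivation — the delayed first spike.  At
high stimulus intensities the fast activation gate (τ = 2 ms) arrests the
approach to threshold for a few milliseconds regardless of intensity, which
produces the stimulus-insensitive latency component.  With the D-current
removed the model becomes an abrupt-onset, short-latency cell whose latency
keeps falling with intensity: the qualitative contrast the package's
latency-regime classifier is built to detect.

Integration is classic RK4 at a fixed step of 0.025 ms; emitted sweeps are
sampled at 20 kHz.  Additive Gaussian current noise (default SD 2 pA in
current clamp, 3 pA in voltage clamp) is drawn once per integration step
and held across the RK4 stages, so the noiseless path is exact RK4.
`integration_accuracy()` compares a trajectory at dt and dt/2; subthreshold
trajectories agree to better than 0.1 mV.  For spiking sweeps a pointwise
voltage comparison is ill-conditioned — a microsecond shift of the upstroke
produces mV-scale pointwise differences — so spiking accuracy should be
judged on spike times, not sample-wise voltages.

## Phenotype presets and calibration

The `"vehicle"` preset is calibrated so that the package's own extraction
returns values typical of healthy layer-IV FSIs: input resistance near
100 MΩ, spike half-width near 0.38 ms, a delayed first spike of tens to
hundreds of ms near rheobase.  The `"mk801"` preset models the
NMDA-hypofunction phenotype by:

* `g_Kd` reduced to 25% of vehicle (the Kv1.1 loss) — this alone raises
  input resistance by ~80% and abolishes the high-intensity latency floor's
  precondition (the near-rheobase delay shrinks markedly);
* `g_Kv3` reduced to 60% — broader spikes (immature waveform);
* an adaptation conductance (`g_adapt` = 50 nS, gated by a slow
  spike-activated variable) — lengthens late ISIs so the ISI accommodation
  ratio falls below vehicle;
* a GluN2B-enriched synapse: `frac_GluN2B` 0.9 vs 0.35, with the
  GluN2B-like decay slowed (185 vs 108 ms) so the weighted decay constant
  of the composite NMDA EPSC is ≈180 ms vs ≈60 ms.  No single shared pair
  of component time constants can reproduce both composite values at those
  fractions, because the amplitude-weighted τ of the mixture is bounded
  below by `frac_GluN2B × tau_B`; the per-preset decay is therefore a
  deliberate calibration choice (biologically, a shift toward
  GluN2B-dominated receptor complements with slower deactivation).

The leak reversal `E_L` is solved per cell so that the full model rests at
the preset resting potential (−65.5 / −66.9 mV).  This matters because
removing a K⁺-carried resting conductance would otherwise depolarize the
cell by ~15 mV, which the data the presets emulate do not show; the
recalibrated leak stands in for the many unmodeled conductances that keep
the resting potential stable.  All of this is calibration against summary
statistics, not ground truth, and is versioned in `R/model-params.R`.

Cohorts (`generate_cohort()`) draw per-cell multiplicative log-normal
jitter (sdlog 0.15) on all maximal conductances and ±1.5 mV on the resting
target, then re-solve `E_L`; a single seed makes the whole cohort, its
manifest and every downstream sweep reproducible.

## The synapse

Under voltage clamp the membrane current is a sum of conductance
transients times driving force.  Each component is a difference of
exponentials rendered by two one-pole recursive filters (exact for the
discretized kernel, O(n)).  NMDA components are additionally scaled by the
standard Mg²⁺ block factor
$1/(1 + ([\mathrm{Mg}]/3.57\,\mathrm{mM})\,e^{-V/16.13\,\mathrm{mV}})$,
which is 1 at 0 mM and increases with depolarization.  Spontaneous
excitatory events arrive as a Poisson train (22 Hz vehicle, 32 Hz mk801);
a fraction of events (0.25 / 0.35) is NMDA-only and therefore essentially
invisible at −40 mV under 2 mM Mg²⁺ but detectable at 0 mM — this is how
the simulator realizes the Mg²⁺-sensitive excess of spontaneous EPSCs in
the mk801 phenotype.  Evoked responses fail independently with probability
0.5 (minimal stimulation); ifenprodil is modeled as a fractional block of
the GluN2B-like conductance only, so with full block the charge loss
equals the GluN2B charge fraction exactly on noiseless traces (a linearity
identity the tests exploit).  Event times, classes and amplitudes are drawn
before any rendering, so traces differing only in Mg²⁺ or drug share
identical event sequences at the same seed.

# Analysis choices worth knowing

* dV/dt threshold: 10 mV/ms is taken as the field convention for the
  unit-less "10" criterion; the derivative is by central differences on the
  raw 20 kHz trace, no smoothing.
* Crossings are spikes only if followed by a ≥20 mV threshold-to-peak
  upstroke; this rejects criterion crossings produced by the passive
  charging ramp of strong steps (at ~660 pA into 66 pF the stimulus alone
  reaches 10 mV/ms).  Protocols keep amplitudes below that range.
* Crossings whose dV/dt does not exceed the mean baseline |dV/dt| 20-fold
  are flagged (`valid = FALSE`) but never silently dropped.
* Rheobase scans default to 1 pA increments: the exactly-one-spike window
  of the simulated cells is only a few pA wide, and coarser grids (up to
  the allowed 5 pA) can only overshoot by less than one increment.  Cells
  that jump from silence straight to multi-spike firing are reported as
  excluded, mirroring the recording protocol; the Kv1-null model is such a
  cell, so its latency analysis uses the `any_spike` threshold criterion
  instead.
* The latency floor is declared when the >2×I_th latencies have CV < 0.20
  and the high-regime log–log slope magnitude is less than half the
  low-regime slope magnitude.  Both conditions matter: a narrow amplitude
  range makes a CV criterion alone too permissive.
* Half-width uses linear interpolation at the half-amplitude level with
  amplitude defined threshold-to-peak; AHP amplitude is threshold minus
  trough (positive); the AHP-peak time is measured from the spike peak.
* Single-spike waveform features are taken from the first spike of the
  smallest-amplitude sweep that elicits a continuous train (≥5 spikes);
  train measures (max rate, accommodation, amplitude ratio) from the
  largest tested amplitude (rheobase + 300 pA).
* The event detector is a derivative trigger (3 robust SDs of a 1 ms
  boxcar-smoothed derivative, sub-ms gaps bridged) followed by an amplitude
  criterion (3 × baseline noise SD) with a 2 ms refractory; the peak search
  is capped at the next trigger so overlapping events are not merged.  At
  26 Hz this recovers rates within ~5% (coincidence losses in the
  refractory window), well inside Poisson counting error at the durations
  used.
* Success/failure classification of evoked epochs compares the smoothed
  (1 ms) peak in a post-pulse window against 3 × the smoothed baseline SD;
  the window is 1–10 ms for AMPA and widened to 1–100 ms for the
  slow-rising NMDA responses.  Failures are excluded from the average
  (5–10-response averages are supported via `max_n`).
* Charge integrates the baseline-subtracted current trapezoidally over
  500 ms (NMDA) or 50 ms (AMPA) after the pulse.
* Bi-exponential fits run Levenberg–Marquardt from deterministic starts
  (log-linear fits to the early/late thirds of the decay, plus fixed
  perturbations), with time constants bounded by ten times the fitted
  window.  Collapsed fits (τ₁ ≈ τ₂, or a vanishing component, or a
  singular Jacobian at every start — the signature of a truly
  mono-exponential decay) fall back to a flagged single-exponential fit.
* Percent differences are reported to one decimal; the block sign
  convention is positive = reduction (so a positive % change in τ_W means
  the decay got faster after the drug).

# Problem sizes

Defaults are chosen to match the study design the simulator emulates: 9
vehicle vs 13 mk801 cells, 600 ms steps, three trials per rheobase
amplitude, eight latency amplitudes per cell (1.1–3 × I_th), 60 s
spontaneous epochs per condition, 20 minimal-stimulation pulses per evoked
condition with up to 10 successes averaged.  The full pipeline
(`run_all()`) completes in a few minutes on one CPU; the test suite uses
smaller cohorts and shorter epochs where the property under test allows
it, and the repeated-cohort phenotype checks use a lightened extraction
(passive family, coarse any-spike threshold scan, two train sweeps).

# What passing tests do and do not show

The simulator reproduces the qualitative physiology the analyses are
designed to measure — the delayed first spike and its two stimulus
regimes, the direction of every significant group difference (input
resistance up, half-width up, accommodation ratio down in mk801), the
Mg²⁺-sensitive spontaneous excess, the slow GluN2B-weighted NMDA decay and
its ifenprodil sensitivity.  It does not reproduce, and the tests make no
claim about: absolute AHP depth (the two-K⁺-current waveform overshoots
the trough of real FSIs), sag amplitude (no HCN current is modeled; the
small sag that appears comes from D-current deinactivation), the positive
threshold–current slope reported for the mk801 phenotype (in the model the
measured threshold drifts slightly downward with intensity in both
presets), temperature and series-resistance artifacts, or dendritic
filtering.  Latency at the strict single-spike rheobase is close to the
step duration by construction (the single-spike window sits where the
delayed spike barely fits inside the step), so between-group latency
contrasts are most meaningful at matched absolute amplitudes or matched
multiples of I_th.  Real recordings bring detector settings, access
resistance and cell-health exclusions that no synthetic benchmark can
stand in for.

# File formats

Sweeps are written as plain delimited text (a `# key<TAB>value` header
with `sampling_rate_khz`, `mode`, `units` and metadata, then
`time_ms/signal/stimulus` columns) that round-trips at full double
precision; feature tables as TSV keyed by (cell, feature); cohort
manifests as JSON; run configurations as YAML with an MD5 checksum written
next to the outputs.  Reading NWB or ABF is not supported in this build
and raises an explicit unsupported-format error.
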