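# fsiephys

Intracellular electrophysiology analysis for cortical fast-spiking
interneurons (FSIs), with a built-in conductance-based simulator.

Parvalbumin-positive FSIs fire narrow, precisely timed spikes, and their
dysfunction is central to the NMDA-receptor-hypofunction account of
schizophrenia-like pathophysiology.  Characterizing that dysfunction from
whole-cell patch-clamp data requires a battery of quantitative procedures:
spike threshold read from phase plots at dV/dt = 10 mV/ms, rheobase (I_th)
as the smallest current giving exactly one spike on three consecutive
trials, first-spike latency and its two stimulus regimes (latency ∝ 1/I
below 2 × I_th; a stimulus-insensitive floor above it in healthy cells),
passive properties from 600 ms hyperpolarizing steps, spontaneous EPSC/IPSC
frequencies under 2 mM and 0 mM Mg²⁺, and evoked EPSC kinetics fit with a
double exponential

    f(t) = A1 exp(-t/tau1) + A2 exp(-t/tau2),
    tau_W = (A1 tau1 + A2 tau2) / (A1 + A2)

with GluN2B pharmacology quantified as % peak reduction, % charge
reduction and % change in tau_W after ifenprodil.  `fsiephys` implements
every one of these procedures, plus the group-level statistics
(mean ± SEM, n, two-tailed Student's t-test / one-way ANOVA, percent
differences), for anyone analyzing FSI recordings or building synthetic
benchmarks for such analyses.

Because no public recordings accompany the study design this package
targets, it ships a single-compartment Hodgkin–Huxley-type FSI model
(transient Na⁺, Kv3-like delayed rectifier, leak, and a Kv1-like
slowly-inactivating D-current) with AMPA/GluN2A/GluN2B synapses under
voltage-dependent Mg²⁺ block.  Two presets generate matched cohorts: a
`"vehicle"` phenotype (delayed first spikes with a latency floor, input
resistance ≈ 100 MΩ) and an `"mk801"` phenotype (D-current reduced to 25%,
higher input resistance, broader spikes, more accommodation, GluN2B
fraction ≈ 0.9 with slow NMDA decay).  The methods vignette
(`vignettes/fsi-ephys-methods.Rmd`) documents the model, every analysis
convention, and what the synthetic benchmark does and does not show.

## Worked example

```r
library(fsiephys)

p  <- fsi_params("vehicle")                       # healthy-phenotype cell
rb <- find_rheobase(make_cell_provider(p, seed = 1),
                    start_pA = 100, increment = 1)
rb$I_th                                           # 121 (pA)
first_spike_latency(rb$latency_sweep)             # 542.3 (ms)

sw <- simulate_current_clamp(p, step_protocol(rb$I_th + 300), seed = 1)[[1]]
sp <- detect_spikes(sw)       # 48 spikes; threshold -46.9 mV, half-width 0.48 ms

pv <- measure_passive(simulate_current_clamp(
  p, step_protocol(c(-300, -150, -100, -50)), seed = 1))
# V_rest -65.5 mV | R_in 103.2 MOhm | tau_m 8.4 ms
```

The rheobase of this cell is 121 pA and its first spike at rheobase is
released only after ~540 ms — the delayed-firing signature of the
D-current.  At rheobase + 300 pA the same cell fires a 48-spike train of
0.48 ms-wide spikes, and its input resistance lands at 103 MΩ.  The
NMDA-side analysis works the same way:

```r
iso <- isolate_nmda(synaptic_params("mk801"))     # DNQX/gabazine/glycine tags
ss  <- simulate_voltage_clamp(p, iso$syn,
         vc_protocol(60, 20200, n_pulses = 20, pulse_period = 1000),
         seed = 2, tags = iso$tags, label = "NMDA")
fit <- evoked_fit(average_evoked(ss, window_ms = 800,
                                 success_window_ms = c(1, 100), max_n = 10),
                  integration_window_ms = 500)
# peak 105.3 pA, failures 40%, tau1 64.7 ms, tau2 182.9 ms, tau_W 180.4 ms
```

The slow weighted decay (tau_W ≈ 180 ms) reflects the GluN2B-dominated
synapse of the mk801 preset; the vehicle preset yields tau_W ≈ 60 ms.

`run_all(default_config(seed = 1), "out")` runs the whole pipeline —
simulate a 9-vs-13-cell cohort, extract every intrinsic and synaptic
feature, and write the two-group comparison table — in a few minutes on
one CPU.  The numbered drivers under `analysis/` run the same stages
step-by-step and print per-cell summaries.

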