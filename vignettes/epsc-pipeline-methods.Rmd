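---
title: "Quantifying sustained EPSC responses: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sustained EPSC responses: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epsctools)
```

## The experimental setting

In brainstem slices of the oculomotor neural integrators — the prepositus
hypoglossi nucleus (PHN, horizontal gaze) and the interstitial nucleus of
Cajal (INC, vertical gaze) — a brief high-frequency electrical burst
(20 pulses at 100 Hz, 0.2 s) delivered near a neuron held in voltage clamp
at −75 mV triggers an elevation of the spontaneous EPSC frequency that
persists for several seconds. The size and pharmacology of that sustained
response are quantified from whole-cell current traces: how long the EPSC
frequency stays above its pre-stimulus baseline, how many events occur in
the first second after the burst, and how those numbers change under
antagonists of Ca²⁺-permeable AMPA receptors (NAS), NMDA receptors (APV)
and Ca²⁺-activated nonselective cation channels (FFA). A separate set of
agonist-puff recordings characterizes the receptors themselves: the
rectification index of kainate responses, the NMDA/AMPA ratio, and the
capacitance-normalized NMDA charge transfer.

`epsctools` implements that entire quantification chain, plus a synthetic
trace generator with known ground truth, so every stage can be validated
end to end.

## The synthetic trace model

A trace is the sum of three components:

1. **Gaussian baseline noise**, SD `noise_sd` (default 2 pA), white at the
   5 kHz sampling rate.
2. **EPSCs**: an inhomogeneous Poisson process with rate
   $\lambda(t) = r_0 + A\,e^{-(t-t_b)/\tau}\,\mathbf{1}[t \ge t_b]$, where
   $t_b$ is the end of the burst. Each event is a biexponential kernel
   $e^{-t/\tau_d} - e^{-t/\tau_r}$ (defaults $\tau_r$ = 0.5 ms, $\tau_d$ =
   5 ms, typical AMPA-receptor kinetics), normalized so the kernel minimum
   equals the event amplitude. Amplitude magnitudes are log-normal (mean
   20 pA, SD 8 pA) truncated below at 1.5 × `noise_sd`, so a small
   fraction of true events deliberately falls below the 3-SD detection
   threshold and exercises detector misses.
3. **Stimulus artifacts**: 20 biphasic two-sample deflections of
   ±`artifact_amplitude` at the 100 Hz pulse times.

The exponential rate elevation is the simplest two-parameter model that
produces responses "lasting several seconds" with a measurable return to
baseline; nothing richer is identifiable from frequency histograms alone.

### Default calibration

The spontaneous baseline rate before stimulation is not a reported
quantity, so it is an explicit, config-exposed choice: 5 events/s, a value
typical of slice recordings with inhibition blocked. Around it, the
defaults $A$ = 49 events/s and $\tau$ = 0.88 s are *measured-scale*
calibrations: because the detector misses a few percent of events and the
duration rule has a noise-crossing floor, parameters were chosen so that
the quantities the pipeline actually reports on control cohorts — not the
generative expectations — land on the reference summary scale (duration
≈ 2.6 s, 1-s post-burst frequency ≈ 30 events/s). Per-neuron log-normal
random effects (sdlog 0.2 on $A$, 0.25 on $\tau$, shared between a
neuron's control and drug conditions) reproduce the reference
between-neuron SDs (≈ 0.6–0.9 s for duration, ≈ 5–7 events/s for the 1-s
frequency).

Drug conditions multiply $A$ by `rate_scale` and $\tau$ by `tau_scale`.
`calibrate_effect()` converts target percent reductions into these
multipliers by jointly solving the closed-form models of the two measured
statistics (duration ≈ $\tau'\ln(A'/\varepsilon)$ with $\varepsilon$ the
Poisson fluctuation scale of a triplet mean; 1-s frequency
$r_0 + A'\tau'(1-e^{-1/\tau'})$), with attenuation factors for the
mean-of-ratios bias of per-neuron percent reductions. The six default
conditions (NAS, APV, FFA × PHN, INC) carried by
`antagonist_effect_table()` were additionally refined by direct
simulation through the full pipeline, so that measured cohort reductions
reproduce the reference values; the refined multipliers are the package's
frozen study conditions, not tunables.

### What the generator does not emulate

Real recordings contain baseline drift, series-resistance changes over
time, seal instability, overlapping multiquantal events, amplitude–kinetics
correlations, and non-Gaussian noise (line pickup, access artifacts).
Passing tests on synthetic cohorts therefore demonstrate the correctness
and calibration of the *quantification*, not robustness to every
real-world pathology; the robust (MAD-based) noise estimator and the
local-baseline conventions below are the pipeline's main concessions to
non-ideal data.

## Detection conventions

The criterion is the classic one: an EPSC is a peak of inward current
larger than three times the SD of the baseline noise before burst
stimulation. Turning that sentence into an algorithm required several
concrete choices:

* **Filtering.** A 4th-order zero-phase low-pass at 1 kHz mirrors the
  acquisition filter. It is applied as the squared-magnitude Butterworth
  response in the frequency domain, which is the response of a
  forward–backward filter pass and shifts no peak times.
* **Local baseline.** Peak depth is measured against the median of a
  10 ms window ending 2 ms before the peak — not against absolute zero —
  so detection is invariant to holding-current offsets and slow drift.
  Because a preceding event inside that window drags the median down and
  masks the next event, the baseline is the *less negative* of two
  adjacent lagged windows.
* **Amplitude read-out.** The peak is located on the filtered trace but
  its amplitude is read from the unfiltered samples at that index: the
  1 kHz filter attenuates a 0.5 ms-rise EPSC peak by roughly 20%, which
  would otherwise bias amplitudes and drop near-threshold events.
* **Prominence.** A candidate peak must also drop 3 SD below the maximum
  of the preceding 1.5 ms (the scale of the EPSC rise). This rejects
  noise ripples riding on the decay of a previous event, which satisfy
  the baseline-depth criterion but are not events.
* **Artifact blanking.** Peaks within [−1.5 ms, +2 ms] of each stimulus
  pulse are discarded. The pre-pulse extent covers the acausal ringing
  that any zero-phase filter spreads ahead of the biphasic artifact.
* **Merging.** Peaks closer than 2 ms merge to the deeper one. Below
  ≈ 1.5 ms separation the filtered trace cannot resolve two kernels
  anyway; a larger value measurably discards resolvable close pairs at
  post-burst rates of tens of events per second.
* The 3×SD comparison is strict (`>`), and events inside the 0.2 s burst
  window are excluded from all downstream metrics.

Validation: on cohorts whose true amplitudes are all ≥ 5×SD and whose
peak rate is 40 events/s, recall and precision at 2 ms tolerance both
exceed 0.95 (pooled over 50 traces); detection counts are monotone in the
threshold factor; and the detector output is invariant to constant
offsets.

## Sustained-response metrics

Frequency histograms use 100 ms bins anchored at the end of burst
stimulation and are averaged across a neuron's three traces. The
**duration of increased EPSC frequency** runs from burst end to the first
window of three adjacent bins (300 ms) whose mean rate is equal to or
smaller than the pre-burst baseline frequency. Two conventions are
deliberate and config-selectable:

* the triplet window *slides* one bin at a time (0.1 s resolution), with
  `mode = "disjoint"` as the alternative that quantizes at 0.3 s;
* the duration endpoint is the *start* of the qualifying triplet
  (`endpoint = "end"` adds the 0.3 s window length).

If no triplet qualifies before the trace ends, the duration is capped at
the post-burst extent and flagged. The **1-s post-burst frequency** is
the event count in [burst end, burst end + 1 s] divided by the number of
traces. **Percent reductions** are computed per neuron and then averaged
(mean of ratios): for pairs (2, 1) and (4, 1) the convention yields
(50 + 75)/2 = 62.5%, not the 66.7% a ratio of means would give. Neurons
with a non-positive control value are excluded and flagged.

The duration statistic is verified *exactly* against a brute-force scan of
every triplet on random histograms.

## Receptor pharmacology

* **Rectification index**: RI = (|I₊₄₀|/40)/(|I₋₆₀|/60), conductance at
  +40 mV over conductance at −60 mV relative to the reversal potential,
  computed from magnitudes so an ohmic cell gives exactly 1. RI < 1
  classifies the kainate response as inwardly rectifying — the
  Ca²⁺-permeable AMPA receptor phenotype. Peak (not steady-state)
  currents are used, measured from the pre-puff baseline within 2 s of
  puff onset.
* **Reversal potential**: linear interpolation of peak vs holding to the
  zero crossing; responses must bracket zero.
* **NMDA/AMPA ratio**: |peak NMDA at +40 mV| / |peak kainate at −70 mV|,
  holding potentials validated from metadata.
* **Charge transfer**: trapezoidal integral of the baseline-subtracted
  current over the 10 s after the puff, reported as a magnitude in pC and
  divided by the input capacitance (pC/pF).
* **Input capacitance**: the time integral of the step-onset transient
  above the steady-state current divided by the membrane voltage change
  (Q = C·ΔV), with the voltage change corrected for the series-resistance
  drop (ΔV·(1 − I_ss/I_peak)). Integrating the transient is robust to
  multi-exponential decays where a single-exponential fit is not.
  Recovery error is < 2% across C ∈ {20…200} pF, Rs ∈ {5, 20} MΩ.
* **Series-resistance QC**: Rs = ΔV/I_peak per −10 mV/100 ms test pulse;
  a recording passes while the largest change from the first sweep stays
  ≤ 20% (strictly above 20% discards, so exactly 20% passes).

## The statistical battery

`choose_test()` gates on Shapiro–Wilk normality at α = 0.05: normal data
get Student's t tests (paired, or unpaired with pooled variance — not
Welch, which is available behind `"welch_t"`), non-normal data get the
Wilcoxon signed-rank or Mann–Whitney test. For paired designs the gate is
applied to the paired differences (per-group gating is available via
`gate_on = "groups"`). Distribution comparisons use Kolmogorov–Smirnov.
Rank tests are exact for n ≤ 12 and use the continuity-corrected normal
approximation beyond. Post hoc power comes from the noncentral t
distribution at the observed effect size (two-tailed α = 0.05); rows
gated to a rank test are reported with the same parametric approximation,
the usual post hoc convention. **No multiple-testing correction is
applied** — each report row is tested at face value, mirroring standard
practice for this kind of summary table; treat the p-values accordingly.

Numerical notes established by the validation suite:

* exact rank-test p-values match full enumeration of sign assignments and
  rank splits for n ≤ 8 (e.g. all-positive differences at n = 8 give
  exactly 2/256 = 0.0078125);
* under the null, empirical rejection rates of the four location tests at
  n = 8 over 2000 replicates lie within [0.03, 0.07]. The exact
  two-sample KS test at n = 8 is conservative *by discreteness* — its
  achievable levels near 0.05 are 0.019 and 0.087 — so its null rejection
  rate is ≈ 0.02; this is a property of the exact KS distribution, not of
  the implementation;
* noncentral-t power matches Monte-Carlo rejection rates of the pooled t
  test within 0.02 across d ∈ {0.5…2}, n ∈ {8, 10, 45}.

## End-to-end validation and problem sizes

`run_drug_experiment()` chains everything: paired cohorts (8 neurons per
nucleus, 3 traces per neuron and condition, 10 s at 5 kHz) for both
nuclei, detection on every trace, per-neuron metrics and reductions, and
the report. Across 100 replicate experiments per drug, the pipeline
reproduces the qualitative pharmacology in ≥ 90% of replicates per check:
significant duration and frequency reductions where the effects are
strong (NAS and FFA in the PHN, APV in the INC), and the characteristic
ordering of mean percent reductions (NAS and FFA larger in PHN, APV
larger in INC).

The *weak-side* significances (NAS and FFA in the INC, with duration
reductions of only 16–22%) do not replicate at that rate and are not
asserted: at n = 8, with Poisson counting noise on a 100 ms-binned
histogram from three traces, the attainable paired power for a 16%
duration reduction is ≈ 0.55–0.75 regardless of how the generator's
baseline rate and time constant are set within the summary constraints.
This is a genuine small-sample property of the assay, worth keeping in
mind when interpreting such rows in real data too.

Simulation sizes used by the test suite (100 duration-oracle histograms,
50 detector traces, 60 RI cohorts, 2000 null replicates, 40,000
Monte-Carlo power replicates, 100 end-to-end experiments) were chosen so
each check's Monte-Carlo error is several times smaller than the margin
it verifies.

## Known limitations

* The detector is a threshold detector; template matching or
  deconvolution would be needed for heavily overlapping events, and
  per-event kinetics are deliberately out of scope.
* Whether peak amplitude should be referenced to a local baseline or the
  absolute holding level is ambiguous in the field; local baseline is
  used here and documented everywhere it matters.
* The duration statistic depends on the baseline-rate estimate; with very
  low baseline rates (≪ 1 event/s) the triplet criterion can only
  terminate on empty triplets, making the statistic coarse.
* Liquid-junction-potential correction is assumed applied upstream;
  potentials in metadata are taken at face value.
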