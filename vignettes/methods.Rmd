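---
title: "Models and methods behind ictalmea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ictalmea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ictalmea)
```

`ictalmea` analyses induced ictal-like network activity in multichannel
microelectrode array (MEA) recordings from acute brain slices, and the
single-neuron chloride electrophysiology that accompanies such experiments.
This vignette explains the models, the tunable parameters, the synthetic-data
generator that validates the pipeline, and the numerical and design choices a
maintainer would want stated.

## The analysis problem

Proictal media (low Mg2+, elevated K+) induce two kinds of epileptiform
activity in neocortical slices on a 59-electrode grid: ictal-like events
(ILEs) — tens of seconds of sustained discharging confined to a spatially
coherent group of electrodes — and brief interictal-like discharges (IILDs).
The scientific outcome measures are, per source and 20-minute window: the
number of ILEs, their mean duration, the discharge frequency within them,
and the number of electrodes they span, plus the frequency and extent of
IILDs that occur independently of ILEs. Paired baseline/drug comparisons of
these outcomes across slices nested in patients are the inference target.

Analysing raw single electrodes conflates sources and depends on an
analyst's electrode choice. The pipeline instead works on *sources*:

1. **Preprocessing** (`preprocess()`): per-channel mean removal, optional
   1 Hz high-pass and mains notch (zero-phase Butterworth), exclusion of
   grossly aberrant channels, anti-aliased downsampling (default 1 kHz).
2. **Source separation** (`decompose()`): PCA followed by fixed-point ICA
   with a log-cosh contrast. Each independent component (IC) carries a
   per-electrode weight vector ("the share of the raw signal attributed to
   the source") and one time course used for all event analysis.
3. **Event detection** (`detect_discharges()`, `group_maxed_interval()`,
   `classify_events()`): discharges are threshold crossings of the IC trace;
   the maxed-interval method groups them into events; long events are ILEs,
   everything else becomes IILD clusters with independence rules.
4. **Metrics** (`summarize_epoch()`): the outcome measures per source and
   epoch.
5. **Inference** (`fit_paired_mixed()`): Bayesian random-intercept models
   for the paired outcomes, reported as posterior mean differences with 95%
   credible intervals; no p-values.

## Source separation

PCA retains the smallest number of components explaining at least
`variance_target` (default 0.95) of the variance; equal-eigenvalue ties at
the cut are all kept. ICA is fixed-point iteration with symmetric
decorrelation, tolerance 1e-5, at most 1000 iterations, deterministic
seeded initialisation.

One choice deserves emphasis. On noise-dominated recordings the variance
rule retains the entire noise bulk (50+ components whose eigenvalues sit in
a tight band). A Gaussian subspace is rotation-invariant under the ICA
model — no rotation of it is more independent than any other — and dragging
dozens of such components through the fixed-point iteration destabilises
the estimate of the genuinely non-Gaussian directions (we observed planted
sources splitting across components). `decompose()` therefore applies the
ICA rotation only to eigencomponents whose eigenvalue exceeds
`signal_eig_factor` (default 2) times the median eigenvalue — for
spatially uncorrelated noise the eigenvalue bulk concentrates within a few
percent of its median at these sample sizes, so a factor of 2 is a
conservative noise edge — and passes the remaining retained components
through unrotated. Reconstruction from all ICs still explains exactly the
retained PCA variance, so the `variance_target` contract is unchanged.

The unmixing matrix is estimated on an evenly spaced subsample (default
100k samples) and applied to the full recording; with a handful of signal
components this is statistically generous and keeps a 20-minute decomposition
in seconds.

Weights are scaled to max |weight| = 1 per IC (traces rescaled inversely, so
the product is untouched), and each IC is oriented so its largest deflection
is negative, the LFP convention. A source's *spatial extent* is the number
of electrodes with |weight| >= `theta` x max |weight|; `theta` defaults to
0.2 and is reported in all output metadata.

Bad-channel exclusion deliberately targets only gross outliers: a channel is
removed when its log-variance deviates from the channel median by more than
`bad_channel_z` (default 6) robust SDs *and* at least a factor of 20 in
variance. Electrodes over an active source have elevated variance for
physiological reasons; an exclusion rule sharp enough to catch them would
bias the spatial extent (we saw exactly this with a plain robust-z rule).

## Event detection

Discharges are crossings of |trace| above `k_mad` x 1.4826 x MAD (robust
SD). The default `k_mad = 6` is a noise-floor choice: a 20-minute, ~56-IC
decomposition contains ~7e7 noise samples, and at 6 robust SDs the expected
number of false crossings over the whole recording stays below one, while
planted discharges sit at ~10 robust SDs on the source's peak electrode.
Crossings within a 50 ms refractory window collapse to the largest peak.

The maxed-interval grouping is the classic burst-detection scheme: an event
opens at the first inter-spike interval (ISI) <= `max_begin_isi_s`, extends
while ISIs <= `max_end_isi_s`, events closer than `min_ibi_s` merge, and
events shorter than `min_event_duration_s` or with fewer than
`min_discharges` members are discarded. Defaults (2 s, 2 s, 5 s, 5 s, 5)
place ILEs of ~20 s with ~3 Hz internal discharges comfortably inside the
detectable region; all are exposed in configuration and logged. Events of at
least `ile_min_duration_s` (default 10 s) are ILEs; remaining discharges
form IILD clusters. IILDs are excluded from the IILD outcome metrics when
they follow an ILE of the same source within `postictal_exclusion_s`
(default 60 s — postictal suppression has no published number, so the window
is configurable) or, under the default source-exclusivity rule, whenever
their source shows any ILE.

Within-ILE discharge frequency is n/duration per ILE (not (n-1)/duration),
averaged over ILEs. Counts are normalised to a 20-minute window. Epochs
without ILEs report zeros, with a `had_activity` flag separating true zeros
from absent sources.

Onset classification inspects the first 2 s of an ILE: low amplitude
(< 0.5x event RMS) with a *prominent* dominant frequency >= 10 Hz is
low-voltage-fast (LVF) — prominence means the peak spectral bin carries at
least 20x the median spectral power, which a genuine oscillation exceeds by
orders of magnitude while the maximum bin of a flat/noise window (whose
location is arbitrary) does not; initial discharges exceeding 1.5x the
median event discharge amplitude are hypersynchronous; anything else is
unclassified. Detection
anchors an event at its first suprathreshold discharge, so an LVF
oscillation that stays subthreshold lies *before* the detected onset and
end-to-end LVF recall is limited — a known limitation; the classifier is
validated on traces with known onsets.

## Bayesian paired mixed models

For outcome y of unit j (slice or cell) in patient i:

y_ij = alpha + beta * post_ij + gamma' x_ij + b_i + eps_ij,
b_i ~ N(0, sigma_b^2), eps_ij ~ N(0, sigma_e^2)

`beta` — the treatment-minus-baseline difference — is reported as its
posterior mean with the 2.5/97.5% quantiles. Baseline adjustment enters as
post x (baseline - mean baseline) ("continuous", so beta is the effect at
the average baseline) or as post x 1[baseline > 0] ("binary", so beta is
the effect in units without baseline activity). An additional centred fixed
effect (e.g. preoperative seizure frequency) can be added by name.

Priors are weakly informative and scale with the data: Normal(0,
(2.5 sd(y))^2) on fixed effects, half-Normal(sd(y)) on both variance-
component scales; a Gaussian likelihood is assumed. The model is sampled
with JAGS using a *non-centred* random-intercept parameterisation
(b_i = sigma_b z_i, z_i ~ N(0,1)): with ~12 patients the centred form mixes
poorly in sigma_b (split R-hat ~1.04 at 4 chains x 2000 draws) while the
non-centred form reaches R-hat < 1.005. Convergence gates are split
R-hat <= 1.01 and bulk ESS >= 400 over 4 chains x 2000 kept draws (defaults);
failures are flagged on the returned object, never dropped. Identical seeds
give identical summaries.

The adjusted intraclass correlation is the posterior mean of
sigma_b^2 / (sigma_b^2 + sigma_e^2), the share of outcome variance
attributable to patient identity conditional on the fixed effects. Pair
designs with one unit per patient identify it weakly; calibration checks
use two units per patient.

`rmcorr()` implements the common-slope ANCOVA formulation of the
repeated-measures correlation: y ~ subject + x, r = sign(slope) sqrt(SS_x /
(SS_x + SS_err)), df = n_obs - n_subjects - 1, Fisher-z interval with
SE = 1/sqrt(df - 1). With 44 observations from 11 subjects, df = 32, and
r = .82 yields the 95% CI (.67, .91).

## Chloride electrophysiology

All constants are computed, never hard-coded: RT/F = 26.30 mV at the bath
temperature of 305.15 K (32 C).

* `hh_bicarbonate(ph_i, ph_o, hco3_o)` = hco3_o x 10^(ph_i - ph_o)
  (constant-pCO2 Henderson–Hasselbalch). At (7.2, 7.4, 26) the exact value
  is 16.41 mM; a commonly quoted 16.38 mM corresponds to rounding the
  power-of-ten factor. The function returns the exact value.
* `ghk_reversal()` is the GHK voltage equation for the Cl-/HCO3--permeable
  GABA-A channel in the anion convention,
  E = (RT/F) ln[(Cl_i + r HCO3_i)/(Cl_o + r HCO3_o)], r = P_HCO3/P_Cl
  (default 0.3); r = 0 reduces to the Cl- Nernst potential.
  `invert_ghk_cl()` is its exact algebraic inverse in Cl_i and errors, with
  the offending bound, when a reversal is too negative to be attainable.
  Somatodendritic E_GABA(A) gradients are converted to chloride
  concentration differences by per-cell inversion; medians are taken across
  cells.
* `estimate_reversal_from_iv()` uses an ordinary least-squares line through
  the (V, I) points and reports E = -intercept/slope — a linear fit is
  robust to current noise and matches how such I-V protocols are read out —
  plus the slope conductance and driving force. Zero slope is an error;
  negative slope is flagged, not hidden.
* `ljp_henderson()` implements the generalized Henderson equation over all
  species with a bundled table of limiting molar conductivities (standard
  electrochemical references; gluconate, HEPES and methanesulfonate from
  Ng & Barry 1995). The sign convention is the potential of the bath
  relative to the pipette — the value subtracted from command potentials in
  offline correction; identical solutions give exactly 0 and swapping
  arguments negates the value. Divalent mobilities are electrophoretic
  (lambda/|z| relative to K+); tables expressed per unit charge list half
  these values.
* `rc_from_transient()` reads the passive properties off the capacitive
  transient of a voltage step: Rs = dV/I_peak, C = (integral I dt)/dV
  (trapezoidal). At 10 kHz sampling the discretisation error is ~0.04% for
  typical tau.
* `qc_series_resistance()` passes a recording iff Rs never changed by more
  than 20% of its initial value ("exceeded" read strictly, so exactly 20%
  passes).
* `tonic_from_histogram()` estimates each holding current as the mode of the
  all-point current histogram (1 pA bins, parabolic interpolation through
  the three bins around the maximum — sub-bin precision without a kernel
  bandwidth choice) and reports the mode difference as the tonic current.
  The mode, unlike the mean, ignores the skewed tail of phasic synaptic
  events, which is the point of the histogram method. Bin grids are anchored
  at the data minimum, making the estimate exactly equivariant under
  constant shifts. Two near-equal histogram peaks trigger an ambiguity
  warning.

## The synthetic-data generator

No raw patient recordings accompany this package, so `generate_recording()`
defines the study conditions under which everything is validated. Defaults
are the reported baseline scale of induced activity: when present, ILEs at
8.9 per 20 min, mean duration 22.6 s, within-ILE discharge rate 3.1 per
second, spanning ~21 electrodes; 56% LVF / 44% hypersynchronous onsets
(assigned in exact proportion); sparse large-amplitude preictal discharges
before each ILE; isolated IILDs at 0.08 per second on an ILE-free source
(~8 electrodes, the reported IILD scale). Signals are (spatial map) x
(source trace) sums; maps grow as contiguous grid patches with a smooth
fall-off from 1 to ~0.3 at the rim; discharges are 20 ms biphasic
transients of 100 uV peak (10x the noise SD, satisfying the >= 8x design
floor) with preictal discharges twice as large; noise is half 1/f, half
white at 10 uV per channel. Discharge trains are Poisson with an 80 ms
dead time, reflecting the waveform width plus network refractoriness (and
keeping the planted rate identifiable under the 50 ms detection
refractory). Treatment epochs can multiply any planted rate, emulating
KCC2-block or -enhancement pharmacology as planted effect sizes.

What the generator does *not* emulate: propagation delays within a source
(maps are rank-1), waveform nonstationarity across an ILE, electrode drift
and artifacts, and the postictal suppression of IILDs. Passing tests
therefore show the pipeline recovers its own generative model at realistic
SNR — they do not certify performance on every pathology of real
recordings.

Synthetic recordings in the tests and the acceptance script are generated
at 1 kHz rather than the instrument's 10 kHz: the analysis band is below
~100 Hz, the pipeline's first step downsamples to 1 kHz anyway, and a
20-minute, 59-channel double-precision matrix at 10 kHz would be 5.7 GB.
Rates, amplitudes, durations and noise are unchanged by this choice.
`generate_hierarchical_dataset()` mirrors the patient/slice/period
structure with known effect, variance components and ICC. Calibration runs
use 200 null replicates at 12 patients x 2 units, and ICC recovery uses 50
patients x 2 units.

## Pipeline orchestration

`run_pipeline()` executes simulate - separate - detect - summarize - model
from one seeded `run_config()` and writes a self-contained run directory
(recording container, ground truth, weights, event/metrics tables, recovery
report, posterior summaries, log); outputs embed a config fingerprint and
are bit-identical under identical configs. The study-level inference stage
draws its outcome tables from the hierarchical generator with the planted
effects rather than simulating dozens of full MEA recordings: the signal
path is validated once per run against its own ground truth, and the
inference layer is validated against planted effects at the study's actual
hierarchical structure — coupling the two through ~50 full decompositions
per run would add hours of computation without adding validation power.
The recording container is a documented open directory format (JSON/CSV
metadata plus a float64 raw-sample file) rather than a proprietary vendor
format; conversion from vendor files can be added behind the same
`mea_recording` contract.

## Known limitations

* ILE onset-time refinement is not attempted; detected starts anchor at the
  first suprathreshold discharge, biasing LVF durations slightly short
  (~2 s of a ~20 s event under the generator's conditions).
* The IILD independence rules are configurable stand-ins; published
  criteria for postictal exclusion windows are not available.
* Outcomes are modelled as Gaussian even where they are counts or bounded;
  this matches the reporting style the models mirror but is not ideal for
  very sparse activity.
* The Henderson LJP is a junction model, not a measurement; for exotic ions
  the bundled mobility table must be extended by the user.
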