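---
title: "Methods: age-dependent propofol EEG band power and burst suppression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: age-dependent propofol EEG band power and burst suppression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anestheeg)
```

## The problem

During propofol-induced unconsciousness the frontal EEG shows two hallmark
rhythms: a slow oscillation (0.1–1 Hz) and an alpha oscillation (8–13 Hz).
Their power changes strongly with age across childhood and adolescence, and
there is clinical interest in whether children with autism spectrum
disorder (ASD) follow a different trajectory than neurotypical (NT)
children — both in oscillation power and in susceptibility to burst
suppression, the deeply suppressed EEG state marked by near-isoelectric
epochs. This package implements that comparison as a reproducible
pipeline: epoch selection from anesthesia records, multitaper band-power
estimation, age-varying cohort spectrograms, Bayesian regression of band
power on age and group, burst-suppression detection and grading, and a
Beta-posterior comparison of cohort incidences.

Because clinical recordings of this kind are not publicly deposited, the
package ships a first-class synthetic cohort generator whose defaults
encode the published cohort structure, so that every stage of the pipeline
is exercised end-to-end on data with known ground truth.

## Epoch selection

Each case contributes one 120-second analysis epoch chosen from the
anesthesia log: the propofol infusion rate must be constant over the epoch
and over the 300 s preceding it, no other anesthetic drug (propofol bolus,
midazolam, fentanyl) may occur in the 300 s before or during the epoch,
and the epoch must start at least 300 s after discontinuation of any
inhaled agent. Times use a half-open `[start, start + duration)`
convention in seconds from record start. Two points are deliberate
decisions rather than published rules:

* **Stability** is the strictest reading — zero rate-change events in the
  window and its washout. A rate-tolerance variant would be a relaxation;
  the strict rule is deterministic and conservative.
* **Tie-breaking** among multiple qualifying epochs takes the earliest
  start, making selection reproducible.

The published screening for artifacts was visual; here it is automated
conservatively: samples must stay below 500 µV in absolute value, no 1-s
window's variance may exceed 10 times the epoch's median 1-s variance, and
the suppression detector must find no events in the epoch. All thresholds
are arguments.

## Multitaper spectral estimation

Spectra are estimated with DPSS (Slepian) multitapers. The tapers are the
leading eigenvectors of the Slepian tridiagonal commuting matrix, computed
by Sturm-sequence bisection plus inverse iteration in compiled code. This
route is exact (it matches a dense eigendecomposition to near machine
precision at small sizes, which the tests assert) and remains cheap at the
120-s epoch length (30,000 samples), where a dense solve would be
infeasible.

Defaults, chosen for resolvability rather than taken from any published
setting (none is stated for this analysis):

* Epoch spectra: the full 120-s window with time-halfbandwidth `nw = 6`
  and `k = 11` tapers. The half-bandwidth is then 0.05 Hz, so the slow
  band (0.1–1 Hz) is genuinely resolved.
* Spectrograms: 2-s windows, 0.1-s step, `nw = 3`, `k = 5`. Such windows
  cannot resolve the slow band — the spectrogram is for visualization and
  nonstationarity checks, and the function can warn when a requested band
  is unresolvable at the chosen window.

Conventions, fixed package-wide: power spectral density in µV²/Hz;
dB values are `10*log10(density)` with a floor of 1e-12 µV²/Hz before the
logarithm; each window is detrended (constant + linear) before tapering,
making band powers invariant to offsets; channels (Fp1, Fp2, F7, F8) are
averaged in the linear-power domain and then converted to dB (dB-domain
averaging is available as an option); band power is the mean linear
density over the frequency bins in the half-open band `[lo, hi)`,
expressed in dB; a band whose lower edge falls below the frequency
resolution of the estimate is an error rather than a silent extrapolation.

## The age-varying cohort spectrogram

The population view is the per-frequency median spectrum over subjects in
a sliding age window: at each grid age from 2 to 23 years in 0.5-year
steps, the median over all subjects within ±2 years. The median is taken
in dB; since the median commutes with monotone transforms, the linear- and
dB-domain medians coincide. Empty windows are flagged missing rather than
interpolated. Each subject contributes one epoch spectrum, matching the
one-epoch-per-case design. The source description mentions both "0.5 year
age bins" and a ±2-year sliding window; this implementation takes the
±2-year window evaluated at 0.5-year steps as the single construction.

## Bayesian band-power regression

For each band, per-subject band power (dB) is regressed on: a group
indicator (ASD = 1), centered age and its square and cube, group-by-age
interactions of all three orders, and the covariates sex, propofol
infusion rate (mcg/kg/min), propofol bolus (mg/kg), midazolam (mg/kg),
fentanyl (mcg/kg), and epilepsy comorbidity. Age is centered at the cohort
mean before expansion, so the group main effect is the group contrast at
mean age. Covariates are fit on their raw clinical scales. Fentanyl is
carried in mcg/kg — the unit its summary table uses — rather than the
mg/kg that appears once in running text, because only the former is
clinically plausible.

"No prior probabilities" is operationalized as the Jeffreys noninformative
prior p(β, σ²) ∝ 1/σ². The sampler is a conjugate Gibbs scheme
(β | σ² is multivariate normal around the least-squares solution;
σ² | β is inverse-gamma), run by default for 10,000 kept iterations after
1000 burn-in with thin 1. Tests require the posterior mean to agree with
the closed-form conjugate posterior within Monte Carlo error, and the
sampler to recover noise-free coefficients.

Intervals are 80% highest-posterior-density intervals computed as the
shortest contiguous interval over sorted draws (the published wording
mixes "two-sided posterior density interval" and "HPD"; the equal-tailed
interval is available as an option). Group contrasts at a chosen age
combine the group main effect with the interaction terms at centered age;
the reported *certainty* is defined here as Pr(ASD power < NT power). The
published certainty percentages are not internally consistent enough to
reverse-engineer their convention, so no attempt is made to match them
numerically; the package's definition is stated and tested instead.

The cubic representation of age is itself checked by model comparison:
polynomial orders 1–3 are compared through the BIC approximation to the
Bayes factor, since exact Bayes factors do not exist under the improper
prior. Simulation tests require the selection to recover the generating
order.

The published coefficient tables themselves cannot be reproduced without
the clinical recordings. What the package substantiates instead, by
simulation at the published cohort size (n = 152 = 42 + 110): the 80% HPD
for the group coefficient covers a known generating offset (−1.926 dB, the
published slow-power group coefficient used as ground truth) at a rate
consistent with its nominal mass over 100 replicate cohorts.

## Burst-suppression detection and grading

Suppression events are detected as maximal intervals where the
cross-channel mean envelope — the analytic-signal magnitude after a
0.5–30 Hz zero-phase Butterworth band-pass, smoothed with a 0.25-s moving
average — stays below 5 µV for at least 0.5 s, with events separated by
less than 0.1 s merged. The 5 µV criterion is a conventional clinical
suppression amplitude; the original scoring was visual, so every parameter
is an argument.

Grading follows the published grammar: a case is graded 1 if it shows at
least three suppression-event onsets within any 60-s window (boundary
inclusive — onsets at {0, 25, 59} s qualify, {0, 25, 61} s do not), or a
single event lasting at least 10 s (inclusive), at any time during the
case. The tests pin this to a brute-force window-scanning oracle on 1000
random event sets. The dual human-rater agreement step of the original
protocol is replaced by this single deterministic detector.

Cohort incidences are compared through Beta posteriors. The default is
the coherent uniform-prior posterior Beta(k+1, n−k+1); the published
formula literally reads β = n + 1, and that variant is selectable as
`paper_literal` rather than silently corrected. The comparison draws
10,000 Monte Carlo sample pairs and reports the fraction with the ASD rate
above the NT rate, alongside a deterministic quadrature evaluation of the
same probability as a cross-check. Incidence counts are explicit inputs
throughout because the published ASD incidence (23.0%) and its Table
counts (14 of 56, i.e. 25.0%) cannot both be exact; the discrepancy is
documented, not resolved.

## The synthetic cohort generator

The generator is calibrated to the published cohort structure and is the
ground truth for every end-to-end test.

* **Metadata.** Ages are truncated normals on [2, 23] with the group
  means/SDs of the published baseline table (ASD 10.88 ± 5.25, NT
  13.29 ± 5.27); male sex Bernoulli(0.857 / 0.555); epilepsy
  Bernoulli(0.095 / 0); infusion rate Normal(239.88, 32.69) /
  Normal(256.11, 37.15) truncated at 0 (mcg/kg/min); boluses and fentanyl
  likewise from the table's moments. Midazolam is zero-inflated (a 0.05
  mg/kg premedication given with probability 0.20 / 0.04), reproducing the
  published near-zero group means. Burst-suppression episodes are
  Bernoulli at the published incidences, 0.230 (ASD) and 0.122 (NT).
  Weight is a simple linear-in-age model with noise; it carries no role in
  the analysis beyond realism of per-kg dosing.
* **Band-power trajectories.** For each band and group the target power is
  a cubic polynomial in centered age interpolating the published
  posterior-mean powers at their stated ages, plus one early-childhood
  anchor per curve chosen so that the cubic peaks in childhood and
  declines monotonically afterwards through 23 years (the published curves
  are shown but not tabulated, so the interpolant is a modeling choice).
  For slow power in NT children, the published value at 10.8 years is the
  largest of the stated values, so that curve peaks near 10 years rather
  than 6–8; the monotone-decline property after the peak holds for every
  curve. Extrapolation outside [2, 23] is clamped.
* **Waveforms.** Each record is broadband background noise (flat
  2.5 µV²/Hz across 1.5–35 Hz with roll-offs outside) plus narrowband
  slow (centered 0.55 Hz) and alpha (centered 10 Hz, ~2 Hz bandwidth)
  components realized as spectrally shaped noise — not pure sinusoids —
  so cohort spectrograms see plausible spectral shapes. Components are
  scaled empirically, using the package's own multitaper estimate of the
  clean analysis epoch, to hit the trajectory target within a fraction of
  a dB; the round-trip tolerance asserted in tests is ±1 dB. Channels
  share the oscillations and differ by small independent noise. The
  background level is chosen so the awake-state envelope sits well above
  the 5 µV suppression threshold at every age (so false suppression events
  do not arise), while staying below every band's trajectory target (so
  component scaling is always feasible).
* **Logs.** Each log has midazolam (when given) and fentanyl at induction,
  one propofol bolus, an initial rate setting and one rate change at 60 s —
  so every epoch-selection rule is exercised — leaving the earliest
  qualifying epoch at 360 s.
* **Suppression patterns.** Positive cases receive either a cluster of
  3–5 short events inside a 60-s span or a single prolonged event of
  12–18 s, placed before the analysis epoch. Durations sit comfortably
  away from the 0.5-s detection and 10-s grading boundaries so that the
  pattern's grade is invariant to the detector's ~0.15-s edge bias;
  boundary behavior itself is tested directly on explicit event lists.

What the generator does **not** emulate: movement and electrode artifacts
(beyond the transients tests inject deliberately), eye blinks, EKG/EMG
contamination, drug pharmacokinetics (band power depends on age and group
only, not on the sampled doses), spindle-like waxing and waning of the
alpha rhythm, and any within-subject nonstationarity during the stable
epoch. Consequently, passing tests demonstrate that the pipeline measures
what it claims on signals with the assumed structure — not that the
detector or artifact screen would match expert scoring on real recordings.

## Problem sizes and numerical choices

Simulation-based tests use sizes chosen to balance statistical
resolution against runtime: the HPD-coverage study uses 100 replicate
cohorts of n = 152 at the full 10,000 + 1000 sampler settings;
Bayes-factor order selection uses 50 replicates per generating order;
calibration round-trips use 10 records across ages, groups and bands, and
the group-separation check uses 50 records at age 22.5; the suppression
grammar is compared with its oracle on 1000 random event sets; the
end-to-end run uses the published cohort sizes 42/110 with a
1000-case-per-group incidence scale-up through the Bernoulli flags and
event grammar (waveform synthesis at that scale adds nothing to the
calibration question and is exercised at 42/110).

Other numerical choices: the spectral floor (1e-12 µV²/Hz) guards the
logarithm for silent segments; EDF output quantizes to 16 bits with
per-channel physical ranges, so round-trips are exact to one quantization
step; all randomness flows through explicit integer seeds, and rerunning
any stage with the same seed reproduces results bit-for-bit.

## Limitations

* The trajectory interpolants are constrained only at the published ages;
  between anchors they are a smooth guess, and recovery tests can only
  validate what the generator encodes.
* The artifact screen and suppression detector are deterministic automations
  of procedures that were originally visual and adjudicated by two raters;
  their thresholds are defensible defaults, not fitted to human scoring.
* The Beta-posterior comparison takes counts as given; it cannot resolve
  the published count/denominator ambiguity, only expose both
  parameterizations.
* The regression assumes homoscedastic Gaussian residuals in dB and no
  within-subject repeated measures, mirroring the one-epoch-per-case
  design.
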