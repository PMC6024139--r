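# anestheeg

Analysis of the propofol-induced frontal EEG in pediatric cohorts —
autism spectrum disorder (ASD) versus neurotypical (NT) — for
anesthesiologists and clinical neurophysiology researchers studying how
anesthetic brain dynamics change with age and neurodevelopmental status.

During propofol anesthesia the frontal EEG carries two hallmark rhythms,
a slow oscillation (0.1–1 Hz) and an alpha oscillation (8–13 Hz), whose
power rises through early childhood and declines through adolescence. The
package implements the full comparison pipeline between cohorts:

* **Epoch selection** — one 120-s epoch per case with a stable propofol
  infusion and a 5-minute washout of every other anesthetic drug, screened
  for artifacts and EEG suppression.
* **Multitaper spectral estimation** — DPSS (Slepian) tapers computed from
  the tridiagonal commuting matrix; band power in dB as
  `10·log10` of mean power density (µV²/Hz) over the band, channels
  averaged in linear power across Fp1, Fp2, F7, F8.
* **Age-varying cohort spectrogram** — per-frequency median spectra over a
  ±2-year sliding window evaluated every 0.5 years from 2 to 23 years.
* **Bayesian regression** — band power on group, centered age + age² +
  age³, group×age interactions, and anesthetic covariates, under the
  noninformative prior p(β, σ²) ∝ 1/σ² via conjugate Gibbs sampling
  (10,000 kept draws after 1000 burn-in); posterior medians with 80%
  highest-posterior-density intervals; group contrasts at chosen ages with
  certainty defined as Pr(power_ASD < power_NT).
* **Burst suppression** — events as intervals where the band-passed
  cross-channel mean envelope stays below 5 µV for ≥ 0.5 s; a case is
  graded positive given ≥ 3 event onsets within any 60-s window or one
  event lasting ≥ 10 s. Cohort incidences are compared through Beta
  posteriors: with k graded cases of n the uniform-prior posterior is
  Beta(k+1, n−k+1), and Pr(P_ASD > P_NT) is estimated from 10,000 Monte
  Carlo sample pairs with a quadrature cross-check,
  Pr(A > B) = ∫ f_A(x) F_B(x) dx.
* **Cohort tables** — standardized mean differences,
  SMD = |m₁ − m₂| / √((s₁² + s₂²)/2) for continuous variables and the
  Bernoulli analogue for proportions, flagged notable above 0.2.
* **Synthetic cohorts** — a calibrated generator (metadata, anesthesia
  logs, 4-channel 250-Hz EEG in EDF) whose band powers follow cubic age
  trajectories anchored at published group means, with Bernoulli
  burst-suppression episodes at rates 0.230 (ASD) and 0.122 (NT), so the
  whole pipeline runs end-to-end without clinical data.

## Worked example

```r
library(anestheeg)

# target trajectories at 22.5 years: the ASD alpha deficit
power_trajectory(22.5, "ASD", "alpha")
#> [1] 6.37
power_trajectory(22.5, "NT", "alpha")
#> [1] 11.89

# synthesize one ASD subject, select the analysis epoch, measure band power
syn <- synthesize_eeg(
  data.frame(subject_id = "demo", group = "ASD", age = 22.5, sex = "male",
             epilepsy = FALSE, infusion = 240, bolus = 1.3, midazolam = 0,
             fentanyl = 0.7),
  seed = 42)
sel <- select_epoch(syn$record, syn$log)
sel$start
#> [1] 360
sp <- epoch_spectrum(syn$record, sel$start)
round(band_power(sp, "alpha"), 2)
#> [1] 6.19
round(band_power(sp, "slow"), 2)
#> [1] 11.48
```

The epoch selector lands on 360 s — the earliest start whose 120-s window
has a constant infusion, full drug washout, and clean EEG — and the
measured multitaper band powers sit within a fraction of a dB of the
generator's trajectory targets (6.37 and 11.56 dB).

```r
# burst-suppression incidence: 14/56 ASD vs 15/123 NT cases
compare_incidence(14, 56, 15, 123, seed = 1)
#> <incidence_comparison> A: 14/56, B: 15/123 (standard)
#>   Pr(P_A > P_B) = 0.9847 (MC, 10000 draws); 0.9834 (quadrature)

# baseline-table comparison: male sex 36/42 vs 61/110
smd_binary(36, 42, 61, 110)
#> <smd_result> binary: SMD = 0.704 (notable)
```

A full cohort run — generation, epoch selection, spectra, both band
regressions, suppression grading, incidence comparison and the baseline
table — is one call:

```r
res <- run_pipeline(pipeline_config(n_asd = 42, n_nt = 110, seed = 11,
                                    outdir = "results/run1"))
```

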