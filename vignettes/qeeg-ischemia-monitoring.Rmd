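---
title: "Quantitative EEG monitoring of cerebral ischemia and reperfusion: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative EEG monitoring of cerebral ischemia and reperfusion: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qeegstroke)
```

## The monitoring problem

Continuous electrocorticography (ECoG) during middle cerebral artery
occlusion (MCAO) and reperfusion in the rat shows a characteristic spectral
signature: during occlusion the trace becomes strongly delta-dominant
(1--4 Hz), immediately after reperfusion faster activity (theta, alpha,
beta) rebounds, and over the following week all canonical bands remain
suppressed relative to healthy controls while slowly recovering. Quantifying
that signature gives bedside-style numeric markers of ischemic state.

This package implements the full analysis as a tested pipeline. A recording
sampled at 1 kHz is high-pass filtered at 0.3 Hz (replicating the
acquisition hardware), cut into 30-s epochs, screened for amplitude
artifacts, and decomposed with a Welch power spectral density estimate.
Analyses run up to a 40 Hz ceiling, split into delta (1--4 Hz), theta
(4--8 Hz), alpha (8--12 Hz) and beta (12--28 Hz) bands. Relative band power
is each band's share of the 1--40 Hz reference power; power between 28 and
40 Hz is tracked as a *residual* band so the five disjoint bands tile the
reference exactly and the fractions sum to one. Three ratio indices
summarize the balance between slow and fast activity:

$$
\mathrm{DTR} = \frac{P_\delta}{P_\theta}, \qquad
\mathrm{DAR} = \frac{P_\delta}{P_\alpha}, \qquad
\mathrm{DTABR} = \frac{P_\delta + P_\theta}{P_\alpha + P_\beta}.
$$

Because they are ratios of powers from one spectrum, the indices are
invariant to overall signal amplitude and identical whether computed from
absolute or relative powers. Classification applies the published
exceedance thresholds — DAR above 3.7 and DTABR above 3.5 — as strict
inequalities (a value exactly at the threshold is not flagged), and the
pipeline reports crossings without interpreting them: notably, the
anesthetized control regime's own DAR (6.45) sits above the 3.7 threshold,
so supra-threshold flags in control sessions are expected and meaningful
only in comparison across phases.

## Spectral estimation choices

The PSD is a Welch average of Hann-windowed 2-s segments with 50% overlap,
pooled over all kept epochs (segments never straddle an epoch boundary).
A 2-s segment gives 0.5 Hz resolution — the coarsest grid that still
resolves the 1 Hz delta edge — and anything coarser is rejected as a
parameter error. The one-sided density is normalized so that
`sum(psd) * resolution` equals the signal variance (Parseval; the test suite
enforces agreement within 5% on white noise, and exact additivity of the
five disjoint band powers to the reference power). Band edges are half-open
`[lo, hi)` so each 0.5 Hz bin is counted exactly once.

Two conventions were genuinely open:

* **Reference band.** Whether relative power is normalized by the 1--40 Hz
  or the 1--28 Hz total is not determined by the source description. We use
  1--40 Hz, matching the stated analysis ceiling; the choice rescales all
  relative powers by a common factor and leaves every index untouched,
  because the reference cancels in the ratios.
* **Unit of analysis.** One PSD (hence one set of band powers and indices)
  per animal per session, then summaries across the six animals of a group —
  the convention that matches per-group figures with n = 6. The alternative
  (average band powers across animals, then form indices — a ratio of means
  rather than a mean of ratios) is exposed as `index_unit = "pooled"` in
  [pipeline_config()].

## The synthetic cohort generator

No animal recordings are distributed, so the package generates
phase-labeled cohorts whose band-power composition is *calibrated* to the
published acute-phase index rows. Each phase has a `spectral_profile`:
target band fractions, a total power, and an inter-animal jitter. A
recording is a sum of five independent Gaussian noise components, one per
band, each band-passed with a zero-phase 4th-order Butterworth filter.
The acute profiles (anesthetized control, ischemic stroke phase ISP,
immediate reperfusion IRP) are exact algebraic inversions of the published
(DTR, DAR, DTABR) rows: fixing alpha as the unit, delta = DAR,
theta = DAR/DTR, beta = (delta + theta)/DTABR − 1, renormalized to
1 − residual with the residual fraction fixed at 0.05 (the source reports
no 28--40 Hz content; a small non-zero value keeps the reference band
honest). The inversion is feasible exactly when the implied beta power is
positive, and the forward identity is tested to 1e-12.

Three numerical points matter for faithful recovery:

* **Filter realization.** Direct transfer-function Butterworth designs are
  numerically unstable for a 1--4 Hz band at 1 kHz (poles at radius
  0.998 and polynomial coefficient cancellation); filters are therefore
  designed in zero-pole-gain form and applied as cascaded second-order
  sections, forward and backward for zero phase.
* **Stationarity.** Each band component is generated with a burn-in of six
  filter time constants on both ends and trimmed, so the retained trace is
  stationary band noise with no startup transients (transient residue
  otherwise produces spurious multi-sigma excursions at the trace edges and
  biases low-frequency power).
* **Leakage calibration.** The band filters are not brick-wall and the
  Welch/Hann window smears power across band edges, so mixing components
  with variances equal to the target fractions under-recovers high-contrast
  profiles by 10--25%. The generator instead solves $M w = f$ for the
  component variances $w$, where $f$ are the target fractions and
  $M_{ij}$ is the deterministic leakage matrix: the share of a
  unit-variance band-$j$ component's power that the analysis pipeline
  measures in band $i$, computed from the filters' $|H|^4$ zero-phase power
  responses convolved with the Welch spectral window. With this calibration
  the full pipeline recovers the ISP and IRP index rows within a few
  percent on 5-min sessions; the acceptance checks require 10%.

Inter-animal variability multiplies each fraction by a log-normal factor
(sigma 0.1 by default) and renormalizes — producing between-animal spreads
of the same order as the published SDs without claiming to match them.
Cohorts derive one sub-seed per animal/phase cell from the master seed via
a deterministic multiplicative hash, so generation is reproducible and
independent of evaluation order; the whole pipeline run is byte-identical
across reruns of one seed.

The subacute presets (days D1--D7) are *qualitative*: they encode the
described trajectory (all four canonical bands below the awake-control
trajectory with the residual band absorbing the deficit; theta elevated on
D3--D4; alpha elevated on D4, D6, D7; DTABR trough on D1--D2 with a peak on
D3; DTR and DAR peaks on D5) but no published numbers exist for them, so
they are excluded from numeric acceptance checks. Sham animals draw from
the matching control preset in every phase — awake control for awake
sessions, anesthetized control during the anesthesia/occlusion/reperfusion
window. Total powers (2000 uV^2 anesthetized, 4000 in immediate reperfusion
where absolute power rises sharply, 1500 awake, 1200 on the suppressed
subacute days) are placeholders: no index or relative power depends on
them.

What passing tests on these cohorts shows — and what it does not: the
pipeline provably inverts second-order band-power structure, which is all
the qEEG indices see. Real ECoG has features the generator deliberately
omits (1/f spectral slope within bands, non-Gaussian amplitude
distributions, anesthesia depth dynamics, movement artifacts beyond simple
amplitude spikes, electrode drift), so recovery here validates the
analysis chain, not the biology.

## Statistics

The battery mirrors the study's: Kolmogorov--Smirnov normality, Student's
pooled-variance t (the stated test; not Welch's), one- and two-way
fixed-effects ANOVA, and Tukey HSD with compact letter display. Model
fitting is delegated to base R (`aov`, `TukeyHSD`, `t.test`,
`stats::ptukey`); the package adds the contracts and tidy surfaces.

Because the KS test is applied with mean and SD estimated from the sample,
plain KS p-values would be conservative; `ks_normality()` calibrates the
p-value against a Monte-Carlo Lilliefors null (default 10 000 replicates,
fixed seed, each null sample standardized by its own estimates). The
empirical type-I error of the one-way ANOVA at p < 0.05 is verified to sit
in 0.05 ± 0.01 over 5 000 null replicates, and the Tukey family-wise error
under the same null at or below 0.06.

Compact letters come from a greedy clique cover of the non-significance
graph in group-label order: each group joins every existing letter it is
compatible with, otherwise opens a new letter and absorbs compatible
predecessors; redundant letters are pruned. Groups sharing no letter differ
at the chosen level.

Two-way ANOVA accepts balanced designs only — with unequal cell counts the
sums-of-squares decomposition is ambiguous, and the published design is
balanced, so unbalanced input is an explicit error rather than a silent
Type-I/II/III choice. The subacute comparison (control vs D1--D7) is run
as a one-way ANOVA over eight groups with Tukey letters; the control group
value per sham animal is its across-day mean.

## Infarct quantification

`percent_infarct_area()` is the closing measurement: 100 x lesion pixels /
ipsilateral-hemisphere pixels, on binary masks. Pixel size cancels and is
ignored; segmentation of stained sections is upstream and out of scope.
The synthetic mask generator grows a lesion from a random interior seed by
uniform 4-neighborhood dilation, trimming the final ring
(nearest-to-origin pixels first) to hit the target percentage exactly up to
1 px rounding.

## Degenerate inputs and tie-breaks

* Zero power in a denominator band (theta, alpha, alpha+beta) is an error
  naming the band, as is an empty 1--40 Hz reference band.
* Index values exactly at a classification threshold are *not* flagged.
* A two-sample t with zero pooled variance returns t = 0, p = 1 when the
  means agree and is an error otherwise.
* Artifact rejection never alters sample values, only the keep mask, and
  rejecting every epoch is an error.
* EDF encoding uses a symmetric digital range (-32767..32767) so a zero
  trace round-trips exactly; the physical range is the observed amplitude
  range, giving quantization error at most range/2^16.

## Problem sizes

The shipped test suite and the acceptance script run everything at the
scale the package's own claims need: 5-min 1 kHz sessions, cohorts of six
sessions per acute phase for index recovery, 200 jittered ischemic sessions
for the DTABR sensitivity rate, 5 000 replicates for the statistical
calibration, and a reduced two-animal, four-phase study for the
byte-identity check of the full simulate-analyze-report loop. The default
`pipeline_config()` reproduces the full study shape: 2 groups x 6 animals
x 11 phases = 132 recordings.

## Known limitations

* The generator matches second-order structure only; see above.
* Single-channel analysis: the emulated setup implants two electrodes but
  reports one analysis stream, and the package does not model montages.
* Subacute presets are descriptive, not calibrated to printed values.
* EDF support is deliberately minimal: single signal, 1-s records, no
  annotations.
* The in-vivo F statistics of the original cohort depend on unreleased
  animal data and are reproduced only qualitatively on synthetic cohorts.
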