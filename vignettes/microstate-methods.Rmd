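---
title: "Microstate analysis of resting-state EEG: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate analysis of resting-state EEG: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegmicrostates)
```

## The model

Spontaneous scalp EEG does not wander continuously through topography space:
for stretches of roughly 50–100 ms the spatial distribution of potentials
stays quasi-stable, then switches abruptly to another configuration. These
stretches are *microstates*, and resting recordings are classically described
by four canonical classes: A (left–right diagonal orientation), B (the
mirrored right–left diagonal), C (a rostral–caudal axis), and D (a
fronto-central maximum). The package models a recording as a sequence of
draws from $K$ fixed average-referenced template maps,

$$ x_t = a_t \, s_t \, m_{L_t} + \varepsilon_t, $$

where $m_k$ is a unit-norm zero-mean template, $L_t$ the active class,
$a_t > 0$ an amplitude envelope, $s_t \in \{\pm 1\}$ an irrelevant polarity,
and $\varepsilon_t$ spatially uncorrelated noise. Everything downstream
respects two symmetries of this model: polarity invariance (similarity is
*squared* spatial correlation, so $\pm m_k$ are the same state) and
reference invariance (all maps and samples are average-referenced before
comparison).

## Segmentation

**GFP and peak picking.** Global field power is the spatial population
standard deviation of a sample across channels. Topographies at GFP peaks
have the highest signal-to-noise, so clustering operates on peak maps only
(`detect_gfp_peaks()`, local maxima thinned to a 10 ms minimum separation,
keeping the larger of close pairs). The source text this pipeline models is
silent on whether every sample or only peaks entered clustering; peaks-only
is the established practice and is what `aggregate_group_prototypes()`
implements, capped at `peaks_per_subject = 1000` highest-GFP peaks per
recording so that no subject dominates the pooled set.

**Modified K-means.** `modified_kmeans()` alternates (i) assigning each map
to the prototype with the largest squared spatial correlation and (ii)
re-estimating each prototype as the first principal direction of its
assigned maps — the sign-invariant analogue of the cluster mean — until the
relative improvement of global explained variance (GEV) falls below `tol =
1e-6`. Restarts (default 20) alternate between two initialization families,
K observed maps and the principal directions of a random partition; the two
families reach different basins of attraction, and on every exhaustively
checkable instance we test (up to 8 maps, K ≤ 3) the best-of-restarts fit
attains the global optimum found by enumerating all set partitions. An
emptied cluster is re-seeded from the worst-fitted map of any cluster that
can spare one.

**One template set per study.** Prototypes are fitted once on the pooled
peaks of *all* recordings (both sessions, both groups) and then back-fitted
everywhere. Pre/post parameter differences can therefore never be artifacts
of session-specific template sets. Fitted maps are labeled by exhaustive
best matching (total absolute correlation over all $K!$ permutations)
against idealized canonical A–D maps built from schematic 10–20 electrode
positions — or against user-supplied reference maps.

**Back-fitting and smoothing.** `backfit()` labels every sample with its
best prototype; ties resolve to the previous sample's label (then the lowest
class index), and zero-GFP samples inherit the previous label with fit 0.
`smooth_segmentation()` absorbs segments shorter than `min_duration_ms`
into the adjacent segment with the higher boundary fit, iterating to a fixed
point; segments touching an epoch boundary are exempt because their true
extent is censored. The pipeline default of 30 ms reflects the
~70–95 ms durations typical of clinical resting EEG. For *recovery*
analyses against the generator's ground truth we instead use a 10 ms floor:
the generator's minimum dwell is two samples at 200 Hz, so any
single-sample segment is necessarily a misassignment, while 30 ms would
also swallow genuine short dwells of the geometric law and bias mean
durations upward by ~30%.

## Temporal parameters and syntax

From a segmentation, `temporal_parameters()` reports per class the mean
segment duration (ms), the occurrence rate (segments per second of labeled
time — rejected epochs do not dilute rates), and coverage (fraction of
samples). Boundary-touching segments are *included* in duration averaging,
which keeps the identity $\text{coverage} = \text{occurrence} \times
\text{duration}$ exact; the test suite asserts it on random sequences.
`transition_syntax()` counts every within-epoch change of label as one
directed transition and normalizes by the grand total of between-class
transitions (one normalization over the whole off-diagonal, not per row).
GEV is computed as $\sum_t (\mathrm{GFP}_t r_t)^2 / \sum_t \mathrm{GFP}_t^2$
with $r_t$ the spatial correlation to the assigned prototype, recomputed
from the recording so smoothing cannot stale it; per-class terms sum to the
total, and GEV is non-decreasing in $K$ (checked across $K = 4,5,6$).

## Preprocessing

The chain mirrors clinical practice for 19-channel 10–20 recordings at
200 Hz: a zero-phase second-order IIR notch at 50 Hz (Q = 30), a zero-phase
4th-order Butterworth band-pass at 0.1–40 Hz, segmentation into 2 s epochs
rejected whenever any channel exceeds ±150 µV, then average referencing of
the kept epochs, in that order. The epoch length is not dictated by the
modeled protocol; 2 s is common microstate practice and is configurable.
ICA-based artifact removal is deliberately not re-implemented — component
selection is operator-dependent — and recordings are expected to be
artifact-reduced upstream; the amplitude rejection still guards against
gross artifacts. EDF input/output uses a minimal 16-bit EDF implementation
(round-trips are exact to within one quantization step); CSV values are
taken as microvolts as-is.

## The synthetic generator

`synthesize_eeg()` plants a semi-Markov label sequence: per-class dwell
times are truncated-geometric in samples (memoryless, minimum 2 samples)
with configurable means, and successors are drawn from a zero-diagonal
row-stochastic embedded chain. Defaults are the study conditions the
package models: 19 channels, 200 Hz, 6-minute recordings, $K = 4$ with
dwell means 85/85/75/95 ms for A–D — chosen to land in the printed
~73–95 ms range with occurrences near 3/s — and a uniform embedded chain.
The amplitude envelope is a rectified 10 Hz sinusoid (alpha-like GFP
waxing/waning, a GFP peak roughly every 50 ms) riding on a small positive
floor (10% of peak) so that no sample is exactly zero; without the floor
the envelope's zero crossings would make labels at those instants
undefined. Polarity flips on a random schedule with ~1 s mean interval are
on by default so the tests prove the pipeline ignores them. Noise is
spatially uncorrelated Gaussian scaled so that mean signal GFP over mean
noise GFP equals `snr` (default 5). The generator does *not* emulate 1/f
spectra, volume-conduction correlations in the noise, channel artifacts, or
head-model physics — passing recovery tests therefore demonstrates
correctness of the estimation machinery under the model's assumptions, not
robustness to everything real clinical data can do.

The dwell law, SNR and envelope are calibration choices: the clinical study
this package re-implements reports no dwell statistics or SNR for its
recordings, so these defaults were fixed once from the printed parameter
ranges and never tuned against test outcomes.

## Group statistics

The statistical layer pins the conventions needed to reproduce the printed
cohort results from the bundled 21-patient table: pooled-variance two-sample
t (sign follows the caller's group order; the cohort report passes
non-responsive minus responsive), paired t on before − after, Mann–Whitney
U with tie-corrected normal z, Pearson chi-square without continuity
correction, and a two-level repeated-measures ANOVA whose F equals the
squared paired t (asserted to 1e-9). Benjamini–Hochberg FDR is applied per
family; families are each (group × parameter) set of K class comparisons,
and each group's K(K−1) directed transition comparisons. The source text
does not define its correction families, so this grouping is this package's
documented choice rather than an attempt to reverse-engineer the original.
Under a 10⁴-replicate null at the study's group sizes (12 vs 9) the pooled
t rejects at 0.046 ± 0.005 at α = 0.05.

Two printed statistics are deliberately *not* reproduction targets: the sex
comparison (z = −0.408 does emerge from a Mann–Whitney on an M/F coding)
and the etiology chi-square, whose category collapse to one degree of
freedom is not stated in the source.

## Validation design and problem sizes

The acceptance layer (`scripts/acceptance.R`, `tests/testthat/`) recomputes:

* the cohort statistics from the bundled table (exact to printed rounding);
* clustering optimality against exhaustive partition search on instances of
  4–8 maps, K = 2–3;
* ground-truth recovery on a 10-subject synthetic cohort of 120 s
  recordings at snr = 5 (template correlation ≥ 0.95, durations within 15%,
  coverages within 0.03, transition probabilities within 0.05, label
  accuracy ≥ 90%);
* GEV monotonicity across K = 4, 5, 6;
* the end-to-end study at the modeled cohort's size (12 responsive + 9
  non-responsive subjects, pre and post sessions of 120 s): a planted
  responder-only increase of class-C dwell (75 → 90 ms) must surface as
  significant FDR-adjusted class-C duration and coverage changes in the
  responsive group and nothing in the non-responsive group, and a matched
  null run must stay silent everywhere.

The 120 s session length (rather than the full 6 minutes) is the package's
chosen validation size; it keeps per-subject parameter estimates precise
enough that the planted effect is unambiguous. Because all synthetic
subjects share one template set and differ only by seed, between-subject
variance is purely sampling noise — real cohorts add genuine
between-subject topography and dynamics variability that these tests do not
emulate.

## Known limitations

* Clustering is a heuristic; optimality is only *verified* on exhaustively
  enumerable instances.
* The canonical A–D reference maps are idealized geometric gradients, good
  enough to order and name fitted classes, not empirical grand averages.
* Only first-order transition statistics are computed; no entropy or
  higher-order syntax.
* The two-level RM-ANOVA covers the pre/post design; there is no mixed
  group × time model.
* EDF support covers continuous single-rate recordings (the interchange
  case), not multi-rate or annotation-bearing files.

## A minimal session

```{r example, eval = FALSE}
library(eegmicrostates)

# cohort demographics and outcome
report_cohort(cohort_fixture())

# a small synthetic study with the default planted responder effect
cfg <- study_config(n_re = 4, n_nre = 3, duration_s = 60, seed = 1)
report <- run_study(cfg)
print(report)
write_report(report, "study_out")
```
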