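# eegmicrostates

Resting-state EEG microstate analysis for pre/post intervention cohorts,
built for the disorders-of-consciousness (DOC) setting: bedside 19-channel
10–20 recordings, a group of patients measured before and after a course of
high-definition transcranial direct current stimulation (HD-tDCS), and the
question of whether the temporal structure of brain activity changed in the
patients who responded behaviorally.

The package is aimed at researchers who want the complete chain —
preprocessing, group-level microstate segmentation, temporal parameters,
transition syntax, and the pre/post group statistics — as tested, scriptable
R functions, plus a synthetic EEG generator with known ground truth to
validate every stage.

## The method

Spontaneous EEG passes through brief (~50–100 ms) epochs of quasi-stable
topography, the *microstates*, classically clustered into four classes A–D.
The pipeline:

1. **Preprocess** each recording: 50 Hz notch, 0.1–40 Hz zero-phase
   band-pass, 2 s epochs rejected beyond ±150 µV, average reference.
2. **Segment**: compute global field power
   `GFP_t = sqrt(mean_c (x_tc − mean_c x_tc)^2)`, pool the highest-GFP peak
   topographies of *all* recordings, and cluster them with a modified
   K-means in which similarity is the squared spatial correlation (polarity
   is ignored) and each prototype update is the first principal direction of
   its assigned maps. The objective is the global explained variance
   `GEV = Σ_t (GFP_t·r_t)² / Σ_t GFP_t²`, with `r_t` the spatial correlation
   between sample `t` and its prototype.
3. **Back-fit** the K prototype maps to every sample of every recording and
   smooth out segments shorter than 30 ms.
4. **Parameters** per class: mean duration (ms), occurrence (1/s), coverage
   (fraction of time), GEV share — and the transition *syntax*, the directed
   between-class transition counts normalized over all between-class
   transitions.
5. **Statistics**: post vs pre per group via two-level repeated-measures
   ANOVA (per class, Benjamini–Hochberg FDR within each parameter family)
   and paired t per directed transition pair; cohort demographics via
   pooled t / Mann–Whitney / chi-square.

A bundled table of 21 DOC patients (12 responsive, 9 non-responsive, with
CRS-R scores at baseline, after one session, and after the full course)
drives the demographic statistics, and the synthetic generator plants a
semi-Markov microstate process with known templates, dwell times and
transition matrix to validate recovery.

## Worked example

```r
library(eegmicrostates)

# demographic and outcome statistics of the bundled cohort
report_cohort(cohort_fixture())
#> Cohort: 21 patients (12 RE, 9 N-RE)
#>   age (y):    RE 59.00 +- 9.95, N-RE 50.33 +- 15.80
#>   course (d): RE 85.25 +- 83.53, N-RE 81.89 +- 57.60
#>   age:    t = -1.542, p = 0.140
#>   course: t = -0.103, p = 0.919
#>   sex:    z = -0.408, p = 0.683
#>   CRS-R T0 vs T2 (paired): t = -3.451, p = 0.003
```

No demographic variable separates the groups, but the paired t on CRS-R
totals (before vs after the stimulation course, all 21 patients) is clearly
significant — the cohort as a whole improved, driven by the 12 responders.

```r
# synthetic study: 8 responsive + 6 non-responsive subjects, 120 s sessions,
# with the default planted effect (responders' class-C dwell 75 -> 90 ms post)
cfg <- study_config(n_re = 8, n_nre = 6, duration_s = 120, seed = 1)
report <- run_study(cfg)
print(report)
#> Microstate study report (K = 4, 28 recordings, seed 1)
#>   pooled-peak clustering GEV: 0.986; mean per-recording GEV: 0.916
#>   significant pre/post parameter changes (FDR):
#>     RE class C duration_ms: 97.03 -> 110.97 (F = 22.43, p_adj = 0.0085)
#>     RE class C coverage: 0.22 -> 0.26 (F = 23.64, p_adj = 0.0073)
#>   no significant transition changes after FDR
```

The pipeline flags exactly the planted change — class-C duration and
coverage rise in the responsive group — and stays silent for the
non-responsive group. `write_report(report, "out/")` emits the per-recording
parameter table, the Table-2-shaped pre/post summary, the transition
summary, and the prototype maps as plain CSV/JSON.

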