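Package: eegmicrostates
Title: Resting-State EEG Microstate Analysis for Disorders-of-Consciousness Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation of multichannel resting-state EEG into microstates by
    polarity-invariant (modified) K-means clustering of global-field-power peak
    topographies, back-fitting of group-level prototype maps to individual
    recordings, and extraction of the classical temporal parameters (global
    explained variance, mean duration, occurrence rate, time coverage) and the
    between-class transition syntax. Includes the preprocessing chain typical of
    clinical 19-channel 10-20 recordings (notch and band-pass filtering,
    amplitude-based epoch rejection, average referencing), a synthetic EEG
    generator with a planted semi-Markov microstate structure and known ground
    truth for validation, a bundled cohort table of 21 patients with prolonged
    disorders of consciousness assessed with the Coma Recovery Scale-Revised
    before and after high-definition transcranial direct current stimulation,
    and the pre/post group-statistics layer (pooled and paired t, Mann-Whitney,
    chi-square, two-level repeated-measures ANOVA, Benjamini-Hochberg FDR).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
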