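Package: emolang
Title: Emotion Markers in Mobile-Sensed Language
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An experience-sampling (ESM) analysis pipeline linking momentary
    emotion self-reports to language captured on smartphones. Provides a
    synthetic-study generator with planted effect sizes (beep schedules,
    AR(1) emotion trajectories, transcripts, voiced waveforms, keystroke
    logs), dictionary-based word-category counting, a simplified acoustic
    feature extractor (F0, jitter, shimmer, HNR, voicing statistics),
    keystroke-dynamics summaries, timestamp linkage with within-person
    standardization and trait aggregation, multilevel and Spearman
    emotion-feature association tables with Holm step-down correction, and
    a cross-validated predictive-R2 procedure with resampled train/test
    splits for single and combined feature sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    lmerTest,
    optparse,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
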