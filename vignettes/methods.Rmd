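---
title: "Methods: emotion markers in mobile-sensed language"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: emotion markers in mobile-sensed language}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emolang)
```

## The problem

Experience-sampling (ESM) studies prompt participants several times a day
to rate their current emotions -- here seven dimensions (valence, arousal,
anger, anxiety, sadness, stress, happiness) on 0-100 visual analogue
scales, ten times a day for two weeks. Alongside the self-reports, a
smartphone can passively capture language: what is said after each survey
(a short voice note), how it is said (voice acoustics), what is typed
(keyboard messages), and how it is typed (keystroke dynamics). emolang
implements the full analysis chain that links these four language streams
to the emotion ratings:

1. **Feature extraction** -- dictionary word-category percentages,
   thirteen acoustic voice parameters, and six typing-dynamics variables;
2. **Assembly** -- timestamp linkage, inclusion filtering, within-person
   standardization (momentary level) and per-participant aggregation with
   a DASS depression score (trait level);
3. **Association** -- multilevel slopes / Spearman correlations with Holm
   step-down control per displayed table;
4. **Prediction** -- cross-validated predictor selection and resampled
   out-of-sample R².

Because raw mobile-sensing data of this kind cannot be shared, the package
ships a first-class synthetic-study generator with *planted* effect sizes.
Every downstream stage is validated against what the generator planted.

## Momentary versus trait level

The momentary dataset standardizes each variable within participant over
the linked observations only, so a slope between two standardized
variables acts as a pooled within-person correlation: it asks whether
moments with more positive-emotion words than *that person's own average*
are also moments of higher valence than their average. The trait dataset
collapses each participant to one row of means (plus the DASS depression
subscale, the mean of 7 items scored 0-3), and uses Spearman correlations
across participants.

The momentary pairwise model is `emotion ~ feature + (1 | participant)`,
fitted by REML with lme4. With both sides within-person standardized the
random-intercept variance is essentially zero; the fixed slope is the
quantity of interest. P-values use the large-sample normal approximation
by default (a Satterthwaite option via lmerTest exists); at the sample
sizes involved (hundreds to thousands of observations) the two are
indistinguishable, and the normal approximation keeps the Monte-Carlo
validation suites fast.

Holm's step-down procedure is applied per displayed table (level x
feature family), flagging `p_(k)` only while every sorted `p_(j)` clears
`alpha / (m - j + 1)`. Holm controls the family-wise error rate; the
package's null-calibration suite verifies the realized rate on simulated
null studies.

## The predictive procedure

For one emotion and feature set: candidates are the Holm-flagged features
(or the 3 largest absolute correlations when nothing is flagged, ties
broken by the fixed feature order); a seeded 10-fold cross-validation on
the 80% training set keeps candidates whose coefficient p-value averages
below .05 over folds, falling back to the 2 smallest mean p; the final
momentary model adds per-participant random slopes for every retained
predictor, and test rows are predicted with the participant's own
estimated effects when the participant appeared in training. The score is

> predictive R² = 1 − MSE(test) / Var(test outcomes),

with the population (n) variance convention; it is negative whenever the
model predicts worse than the test mean, and negative values are
preserved through the 50-split resampling. The resampled splits are
observation-level stratified by participant at the momentary level
(every participant keeps a training observation whenever possible) and
participant-level at the trait level, so trait models are always scored
on unseen people.

Three deliberate choices here, where the procedure's description leaves
room:

* **Selection model.** The fold-level models used for coefficient
  p-values carry a random intercept only; the varying slopes enter at the
  final fit. This keeps selection stable on small folds and an order of
  magnitude faster.
* **Singular fits are accepted.** Within-person standardized outcomes
  force the random-intercept variance to the boundary, so virtually every
  final fit is "singular" in lme4's sense; treating that as failure would
  degenerate every model. Random slopes are dropped (in fixed,
  last-to-first order) only when the optimizer actually errors.
* **Global candidates.** The candidate list comes from the association
  stage on the full dataset, not from within each split. This mirrors a
  procedure in which selection references "the significant correlations
  of the previous analyses", and it means per-split R² values are not
  fully independent of the test rows at the candidate-selection stage --
  a known, documented property of that design.

## The synthetic study

The generator's defaults are the study conditions: 60 participants, 14
days x 10 beeps (the first beep uniform in [10:00, 11:00), nine more in
equal blocks of [11:00, 22:00)); per-beep answer probability 0.89 at day
one for the average participant, a person-level log-odds SD of 1 and a
log-odds decrement of 0.08 per day, which yields a mean compliance near
0.78 (SD ~0.15) with per-participant compliance spanning roughly
0.26-0.99 and activity that declines over the study; voice notes follow
19% and keyboard activity 60% of answered surveys, reproducing the
observed stream sizes (about a thousand voice observations and four
thousand keyboard bins).

Emotion dynamics: each emotion's standardized state is
`z_e = f_e F + sqrt(1 - f_e^2) U_e`, where `F` and the `U_e` are
independent stationary AR(1) processes (coefficient 0.4). The shared
factor `F` (loadings +0.8 valence/happiness, +0.2 arousal, −0.5 to −0.6
for the negative emotions) produces the characteristic positive-affect
versus negative-affect correlation structure with one parameter per
emotion. Ratings are `trait mean + within-person SD x z`, clipped to
[0, 100]; clipping (rather than truncated sampling) slightly compresses
variance for emotions whose trait mean sits near a scale end (anger,
anxiety, sadness), a documented mild bias accepted for simplicity.
Between-person trait means use the observed cohort means and SDs; the
within-person SD defaults to 12 VAS units, a typical ESM magnitude.
DASS items are drawn from a right-skewed severity distribution
(Beta(1.2, 6) scaled to 0-3, binomial items), concentrating subscale
scores below 0.75 with occasional higher values.

Planted effects: each feature's standardized value is
`z_f = sum_e lambda_(f,e) (z_e + zbar_e) + s eps`, with `s` absorbing the
residual variance, `zbar_e` the participant's standardized trait
deviation (so planted couplings act at both levels), and the defaults
taking `lambda = ±0.15` from the literature direction priors. Two
consequences worth knowing:

* When several correlated emotions load on one feature, the *marginal*
  feature-emotion correlation compounds beyond the per-emotion loading
  (first-person-singular words reach |r| ≈ 0.4 under the default prior
  set). A single planted loading with all others zero produces exactly
  the specified within-person r, which is how the parameter-recovery
  suite is configured.
* Floors (percentages at 0, counts at 0) attenuate planted correlations
  slightly for rare categories; the recovery suite uses a mid-frequency
  category where the attenuation is a few percent.

Rendering: transcripts are multinomial word draws whose category
probabilities equal the planted category percentages (filler words come
from a non-lexicon list, so recognized fraction is also controllable);
waveforms are Hann-pulse trains with the planted F0 (semitone scale
anchored at 27.5 Hz), period jitter and amplitude shimmer calibrated so
the extractor's mean-absolute-difference definitions recover the planted
values (`sigma = target x sqrt(pi)/2` for both), additive noise setting
the harmonics-to-noise ratio, and unvoiced gaps setting the segmentation
features; keystroke logs place entries inside the ±30-minute bin with
inter-key intervals from the planted typing speed. Rendering inverts the
extractor exactly for F0 level, jitter, shimmer, HNR and segmentation;
contour-shape parameters (slopes, ranges) and loudness are approximated
by triangular contours, which is why the heavy statistical suites run on
the returned ground-truth features while rendering fidelity is tested on
dedicated analytic fixtures. The generator makes no attempt at
linguistically realistic Dutch or phonetically realistic speech; what
passing tests establish is that the *pipeline arithmetic* is right, not
that real speech behaves like the synthesizer.

## Acoustic extraction choices

Frames are 40 ms with a 10 ms hop (two full periods at the 55 Hz search
floor). Voicing requires a normalized autocorrelation peak of at least
0.45 *and* frame RMS within 60 dB of the clip peak (ties unvoiced). The
autocorrelation is taper-corrected (unbiased), so a perfectly periodic
frame peaks at 1 regardless of lag, and an octave-error guard prefers
the shortest-lag local maximum within 90% of the global peak. Peak lags
are refined by parabolic interpolation, which holds the pure-tone F0
error under 0.05 semitones at 16 kHz.

F0 statistics are computed on the semitone scale: the normalized SD
(SD/mean, the variant consistent with the observed magnitudes around
0.22 against means near 30), the range as the 80th minus 20th percentile
(the percentile convention matches observed ranges near 7 semitones;
max-min would not), and rising/falling slopes as least-squares slopes
over maximal monotone runs of the median-smoothed voiced contour
(falling slopes reported as magnitudes). Jitter and shimmer are measured
on period-level pulse peaks (sub-sample interpolated): mean absolute
consecutive-period difference over mean period, and mean absolute dB
ratio of consecutive peak amplitudes. HNR is `10 log10(r / (1 - r))` of
the voiced-frame autocorrelation peak. Loudness is a framewise RMS
intensity proxy, *not* an auditory-model loudness; since all analyses
standardize within person, any monotone rescaling of loudness is
analysis-invariant. Clips with no voiced frame return NA for the
F0/jitter/shimmer/HNR fields while the segmentation statistics are still
computed.

## Degenerate inputs and numerical conventions

Empty transcripts yield a degenerate flagged feature vector with zero
percentages; zero-variance variables within a participant become missing
for that participant (logged); an entry exactly on the keyboard-bin
boundary follows the closed-left/open-right convention
`[esm − 30 min, esm + 30 min)`; voice linkage is greedy nearest-first
within 5 minutes with exact matches taking precedence, injective in both
directions; sample (n−1) SDs are used for standardization; Spearman uses
mid-ranks and the t-approximation; split proportions land within one row
of 80/20.

## Problem sizes used in validation

The validation suites run at reduced but statistically meaningful sizes
chosen once: parameter recovery at 60 participants x ~80 linked
observations over 20 seeds (planted r = 0.25, recovered mean within
±0.05); null calibration at 20 x 40 over 200 replicate studies
(family-wise flag rate at most 0.075); power checks at 20 x 40 with a
planted r = 0.4. The acceptance script reruns the default-protocol
cohort at full scale (60 x 140) on the ground-truth feature path.

## Known limitations

* The demo lexicon (~150 entries) exercises the counting machinery; it
  is not a validated sentiment dictionary, and recognized fractions on
  synthetic text reflect the generator's filler rate, not real-world
  lexical coverage.
* The acoustic extractor is a deliberate simplification of a full
  parameter set: no formants, no auditory loudness, no noise-robust
  pitch tracking. Absolute values of slope- and loudness-family
  parameters are tool-specific; only within-person standardized values
  are comparable across extractors.
* Trait-level analyses with ~50-60 participants are intrinsically
  noisy; the resampled trait R² has large spread, and the pipeline
  preserves (rather than floors) its negative values.
* The AR(1) emotion model treats the beep sequence as equally spaced and
  ignores overnight gaps.
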