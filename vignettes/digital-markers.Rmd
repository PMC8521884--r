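---
title: "Digital markers of depression treatment response: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital markers of depression treatment response: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbmarkers)
```

`dbmarkers` measures remote digital markers of depression — facial emotion
activity, amount of speech, and head movement — and tests their change over
a 4-week antidepressant course with repeated-measures statistics. This
vignette is the package's account of its models, its tunable constants and
the design decisions behind them, and of what its validation on synthetic
cohorts does and does not establish.

## 1. The marker model

### Facial markers

The input is per-frame face-tracker output in the OpenFace CSV dialect:
binary presence `AUxx_c` and 0–5 intensity `AUxx_r` for each facial action
unit (AU), plus head pose and per-frame tracking quality. Frames are first
quality-gated (`success == 1` and `confidence >= 0.70`; the 0.70 default is
a conventional tracking-confidence floor). When no frame survives, markers
are reported missing, never zero.

Six basic emotions are scored against declarative AU prototype sets
(`default_emotion_map()`), the conventional EMFACS/Ekman prototypes:
happiness {6, 12}, sadness {1, 4, 15}, surprise {1, 2, 5, 26}, fear
{1, 2, 4, 5, 7, 20, 26}, anger {4, 5, 7, 23}, disgust {9, 15}. The map is a
parameter: any alternative mapping can be passed to every facial-marker
function.

Per frame and emotion, the *match* is the fraction of constituent AUs
flagged present and the *intensity* is the mean of their intensities. The
frame's single label — the "most probable" emotion — is the argmax of match,
subject to a 0.5 match floor (below it the frame is unlabelled). Ties on
match are resolved by, in order: the number of active constituent AUs, the
per-frame intensity, and a fixed emotion order (`emotion_tie_order()`).
The active-AU-count step is a deliberate design choice: the fear prototype
strictly contains the surprise prototype, so a frame showing the full fear
set matches both at 1.0; preferring the prototype that explains more of the
observed activation resolves this deterministically in favour of the more
specific hypothesis, where an intensity-only tie-break would flip on noise.

From the frame labels and scores come the 13 facial markers per response:

* **emotion count** — labelled-frame fraction; the six counts plus the
  unlabelled fraction always sum to 1;
* **emotion intensity** — mean constituent-AU intensity over *all* valid
  frames (0–5 scale), not only labelled ones (mean rather than max or sum,
  so the marker stays on the AU scale);
* **overall expressivity** — the per-frame sum of the six emotion
  intensities, averaged over frames (0–30). By linearity it equals the sum
  of the six intensity markers. An alternative composite that averages the
  raw AU columns directly is available via `overall_expressivity(from =
  "aus")`; the emotion-sum variant is the default because the composite is
  defined as a sum across emotions.

Markers are computed within each stimulus response and then averaged within
subject, assessment and stimulus valence class — matching a per-condition
results layout — rather than pooled across the whole assessment first.

### Voice marker

Rather than binding to an external phonetics toolkit, speech is segmented
by a self-contained energy detector with Praat-convention defaults, all in
config: 10 ms non-overlapping windows; a window is *sounding* if its
log-energy is within 25 dB of the loudest window (a relative threshold, so
the rule is gain-invariant); interior silent gaps shorter than 0.3 s are
bridged; sounding runs shorter than 0.1 s are discarded. **Voice
percentage** is total speech time over total response time, read as
speech/total (bounded in [0, 1]) rather than a speech/silence odds ratio.
Digital silence yields zero segments; a signal shorter than one window is
an error.

### Movement markers

From the pose columns: framewise displacement is the Euclidean norm of the
translation difference between consecutive frames, in raw tracker units per
frame (all videos share one frame rate, so no per-second normalisation is
applied). **Head movement mean** and **SD** are the arithmetic mean and
sample SD (n−1) of these displacements; **head pose change mean** is the
analogous mean norm of the Euler-angle differences, in radians per frame —
component-wise differences are adequate in the small-angle regime of a
seated, camera-facing subject (a quaternion geodesic would be the
alternative for large rotations). Quality-gated frames break the chain: no
displacement is computed across a gap.

## 2. The stimulus protocol

Normative image valence scores are z-scored with the population-SD
convention (immaterial at pool sizes near 900, but fixed for
reproducibility). Classes: neutral `|z| <= 0.5` (closed band), positive
`z >= 1.5`, negative `z <= -1.5`, everything else an excluded buffer that
keeps the classes well separated. The negative threshold is read as the
mirror image of the positive one, and both outer thresholds are inclusive;
these are named configuration defaults, not hard-coded facts.

Each assessment presents 13 images in the fixed pattern
N P N X N P N X N P N X N (X = negative): 7 neutral, 3 positive, 3
negative, starting and ending neutral, with positive and negative never
adjacent. Images are drawn uniformly at random within class, excluding the
subject's full presentation history, so no image repeats across a study;
when a class runs out the sequencer raises an exhaustion error naming it.
A response is valid when the participant spoke at least 10 s.

## 3. The longitudinal procedure

Assessments are binned baseline = days 0–6, week 2 = days 7–21, week 4 =
days 22–35; later days are excluded. (Only "week 0" is inherent to the
design; the 0–6 baseline window is a documented constant.) Cells are
subject-by-bin means; subjects missing any bin are dropped (complete-case),
and each result row records its own `n` — degrees of freedom always derive
from that `n`, never from an assumed sample size.

The omnibus test is the one-way within-subject ANOVA: `SS_time` (df `k-1`),
`SS_error = SS_total - SS_subjects - SS_time` (df `(n-1)(k-1)`),
`F = MS_time/MS_error`. Degenerate inputs are defined, not accidental:
identical columns give F = 0, p = 1; a perfectly additive matrix (zero
error variance) gives F = Inf, p = 0 with a warning.

Sphericity is tested with Mauchly's W on an orthonormal contrast projection
of the sample covariance, using Box's two-term chi-square approximation
(`k(k-1)/2 - 1` df); at k = 2 the test is skipped (W = 1 trivially), and
with n <= k the contrast covariance is singular, so the test is recorded as
not estimable and the uncorrected F is reported. The reporting rule is
deliberately literal to the convention this pipeline reproduces: when
sphericity is violated, the table's statistic columns carry W and the
sphericity p-value. Because using a sphericity test as the effect test is
unconventional, the Greenhouse–Geisser epsilon and the corrected F p-value
are always computed and stored alongside (`gg_epsilon`, `p_gg`) as a
robustness check; readers can re-derive the table either way.

Multiplicity: the omnibus p-values are Benjamini–Hochberg adjusted, with
the family defined as the 17 markers within one stimulus condition
(matching a per-condition table layout); a whole-table family is available
via `fdr_family = "table"`. Pairwise contrasts between the three visits use
Tukey HSD on the common within-subject error term — Tukey's procedure
already controls the familywise error across the three contrasts, so no
further BH is stacked on top. The direction flag is the sign of the
week-4 minus baseline mean, claimed only when the FDR-adjusted p is below
alpha (0.05 throughout; the sphericity alpha is likewise 0.05).

Min–max normalisation to [0, 1] exists for trajectory plots only; by
contract it never precedes a test.

MADRS rules: eligibility at a total of 20 or more; responders at a 30%
or greater baseline-to-week-4 reduction; severity bands severe (>34),
moderate (20–34), mild (7–19), asymptomatic (<7).

## 4. The synthetic cohort generator

The generator exists so every stage is testable without clinical
recordings; its defaults *are* the study conditions the pipeline targets:

* 18 subjects, weekly remote assessments on days 0, 7, 14, 21, 28, clinic
  MADRS on days 0, 14, 28;
* baseline MADRS from a truncated normal, mean 34.1, SD 4.9, on [25, 45],
  rounded to integers;
* a latent severity that declines linearly from baseline to
  `baseline * (1 - response)` at day 28, with per-subject response
  fractions truncated-normal around 0.60 (SD 0.08) and floored at the 0.30
  responder criterion — a cohort of confirmed responders moving from the
  moderate/severe range toward the non-clinical range;
* observed MADRS = latent + N(0, 2 points), rounded and clipped to [0, 60]
  (the rounding is skipped in the exact deterministic limit `noise_sd = 0`
  so parameter recovery is exact);
* assessment-level missing-completely-at-random dropouts at rate 0.18,
  which leaves about 12 of 18 subjects complete-case — the attrition
  regime the analysis is meant to survive.

Severity drives everything through transparent linear links in
`u = severity/60`, clipped to valid ranges (`latent_state()`): mean active-AU
intensity `3.5(1 - u)`, voice fraction `0.88 - 0.55u`, translational step
rate `0.85 - 0.60u`, angular rate `0.05 - 0.035u`, and per-emotion episode
rates in which fear and anger rise with severity while happiness falls,
modulated by stimulus class (more happiness episodes to positive images,
more sadness/fear/anger/disgust to negative ones). Lower severity therefore
means more expressivity, speech and movement — the motor-recovery signature
the markers are designed to detect. `effect_sizes` rescales any link slope;
`noise_sd` scales or overrides the per-marker observation noise. Inter-
assessment variability is not constrained by any published value; the
defaults (e.g. 0.02 SD on counts, 0.06 on intensities, 0.04 on voice) were
chosen once as plausible within-subject measurement noise and are free
parameters.

The generator works at two levels that share the same links. The
marker-level path draws the 17 marker values directly, with emotion
intensities including the AU-prototype *overlap* term (an episode of
emotion *e* raises marker *m*'s mean constituent intensity by the fraction
of *m*'s AUs inside *e*'s prototype, plus an idle-baseline term of about
`0.04 E`), because that is what frame-level rendering actually produces.
The rendered path builds every response down to frames and audio: AU
episodes as contiguous blocks with known schedules, presence = intensity
above 1.0 (the documented activation constant), head pose as a random walk
with log-normal step lengths (CV 0.5, so the realized displacement SD is
half the mean), and audio as 2.5 s speech/silence cycles whose scheduled
speech fraction is exact over the default 10 s response. The two levels
agree to within a few percent on rendered cohorts, and that agreement is
itself under test.

Everything is driven by one integer seed and is bit-identical under it.
A config without a seed is refused.

### What the synthetic validation does not show

The generator emulates the *structure* of real assessments, not their
content: Gaussian marker noise with MCAR dropouts (no mood-dependent
missingness), linear severity links (no floor/ceiling nonlinearity beyond
clipping), white-noise "speech" (no prosody, no inter-word pauses shorter
than the detector's bridging window), block emotion episodes (no natural
micro-expressions), and no rater error structure on MADRS items (totals
only). Passing tests therefore demonstrate that the pipeline's arithmetic,
filtering rules and statistical calibration are correct, and that effects
of the modelled size are recoverable through the full chain — not that the
published effect sizes would replicate in new clinical data.

## 5. Numerical and validation choices

* `rm_anova`, Mauchly's W, Tukey p-values and BH adjustment are each tested
  against independent oracles on 100+ random instances: explicit-loop sums
  of squares, the multivariate-linear-model sphericity machinery, direct
  double numerical integration of the studentized-range distribution, and a
  hand-written step-up loop (tolerance 1e-8; 1e-6 for distribution tails).
* Calibration: under a spherical null with n = 18, k = 3, the omnibus
  rejection rate over 1000 replicates is required to sit in [0.03, 0.07]
  at alpha = 0.05; under generator defaults, the full pipeline must flag
  overall expressivity, voice percentage and head movement mean as
  significant increases in at least 90% of 200 seeded cohort replicates.
  The simulation sizes (1000 null draws, 200 cohorts, a single fully
  rendered default study for the extraction check) are the package's
  validation problem sizes, chosen to estimate those rates with adequate
  precision.
* Tie-breaks, thresholds and bin edges are all named constants surfaced in
  function signatures or the run config; none is buried in code.

## 6. Known limitations

* The AU-to-emotion prototype map is conventional but not canonical;
  substantive conclusions about individual emotion counts depend on it.
  It is swappable by design.
* Reporting Mauchly's W as the row statistic under non-sphericity follows
  the reproduced convention but conflates a test of an assumption with a
  test of an effect; use the stored Greenhouse–Geisser fields for a
  conventional reading.
* The voice detector measures sounding time, not speech: music, coughs or
  steady background tones count as voice. Its bridging rule means duty
  cycles above ~0.88 (gaps under 0.3 s) are read as continuous speech.
* Euler-angle differences understate large head rotations.
* The complete-case rule discards subjects informatively if missingness
  correlates with severity; no imputation or mixed-effects alternative is
  provided here by scope.
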