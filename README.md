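# coupleEEG

Trial-level brain–behavior coupling analysis for EEG, in R.

## The scientific problem

In paradigms where a participant watches a stimulus and produces a graded
behavioral response on every trial — for example observing another
person's pain and deciding how much money to donate to reduce it — the
question is whether the single-trial amplitude of activity in a cortical
region of interest (ROI) explains trial-to-trial variation in behavior.
`coupleEEG` implements a two-level ("summary statistics") analysis of
that question for EEG source data, together with the behavioral
statistics used by the accompanying stimulation (TMS / HD-tDCS)
experiments, and a synthetic-data module that makes the whole chain
testable against known ground truth.

The analysis core:

1. **Sensor conditioning.** Zero-phase 4th-order Butterworth filtering
   (60 Hz low-pass, 49.5–50.5 Hz line-noise band-stop), common-average
   re-referencing, 7-s epoch segmentation, baseline correction 400–200 ms
   before the fixation cross, and peak-to-peak trial rejection.
2. **LCMV beamforming.** For each ROI, the spatial filter
   `W = (L'C⁻¹L)⁻¹ L'C⁻¹` with `C = Σ + λ·(tr Σ/n_ch)·I`, where `L` is the
   channels × 3 forward block and `Σ` the covariance of the evoked
   response over the entire epoch, computed per condition.  `W` has unit
   gain at the target (`WL = I₃`) and minimal variance elsewhere; each
   trial is multiplied by `W`, giving three-dipole ROI time courses.
3. **First level.** For every subject, dipole and time point, a robust
   regression (IRLS, Tukey bisquare, tuning 4.685) of the within-subject
   Z-scored response on source amplitude; the slope time courses are the
   subject-level summary statistic.
4. **Second level.** At each time point the one-sample Hotelling
   `T² = n·x̄'S⁻¹x̄` over the subjects' dipole slope 3-vectors, converted
   to `F = T²(n−p)/(p(n−1))` with df `(p, n−p)`.  Runs of adjacent time
   points with `F` above the `p_unc = 0.01` critical value (4.675 for
   n = 28, p = 3) form clusters whose mass is the summed statistic;
   family-wise control over time uses a sign-flip max-cluster permutation
   test (each permutation flips whole subjects' slope time courses), and
   Bonferroni correction handles the ROI × condition family.

Behavioral batteries: within-group Z-transforms, per-cell robust
intensity→response slopes, one-sample/paired t, fully within-subject
two-way ANOVA with partial η², Newman–Keuls post-hoc tests, JZS
default-prior Bayes factors (Cauchy scale 0.707, one- or two-sided),
Fisher-z rating-accuracy correlations, and stimulus-set statistics from
intensity count tables.

## Worked example

A compact synthetic study: 12 subjects, one condition, a lead field with
two ROIs, and a ground-truth coupling confined to 0.60–0.70 s after movie
onset (400–500 ms after the noxious event at +0.2 s) in ROI1 only.

```r
library(coupleEEG)

truth <- groundTruth(window = c(0.60, 0.70), targetRoi = "ROI1")
study <- simulateEEGStudy(
  nSubjects = 12,
  intensityCounts = list(Hand = c(`2` = 16, `4` = 16, `6` = 16)),
  nChannels = 10, nRois = 2, truth = truth, fs = 50,
  tPre = 0.5, tPost = 1.0,
  events = c(fixation = -0.4, movie_onset = 0, noxious_event = 0.2),
  seed = 101)

cfg <- analysisConfig(filter = FALSE, baselineWindow = c(-0.1, 0),
                      baselineRef = "fixation", rejectThreshold = Inf,
                      nPerm = 99, bonferroniM = 4, seed = 101)
report <- runEEGPipeline(study$provider, study$table, study$leadfield, cfg)
report$clusters
```

```
   roi condition startIdx endIdx startMs endMs       mass pseudoP significant
1 ROI1      Hand       56     61     400   500 118.278068    0.01        TRUE
2 ROI2      Hand        7      7    -580  -580   8.243926    0.41        FALSE
```

The pipeline recovers the planted coupling: a Bonferroni-significant
cluster in the coupled ROI spanning 400–500 ms after the noxious event
(`startMs`/`endMs` are reported relative to that event), with the
permutation pseudo-p at its floor of 1/(nPerm+1); the stray single-sample
cluster in the uncoupled ROI stays far from significance.  Stimulus-set
arithmetic from the shipped intensity count presets:

```r
cnt <- intensityCountsPreset("table2_eeg")
stimulusSetStats(cnt$Hand, cnt$Face, labels = c("Hand", "Face"))$display
#> "Hand: 4.0 +/- 1.4 (n=43); Face: 3.7 +/- 1.7 (n=52); t(93) = 0.88, F(51,42) = 1.49"
```

## Scope notes

The package deliberately excludes realistic head modelling (BEM/FEM),
electrode co-registration, ICA ocular correction and MRI-based ROI
definition: lead fields are user-supplied (or generated parametrically),
and artifact rejection is an amplitude-threshold surrogate for visual
screening.  See the methods vignette (`vignettes/coupling-methods.Rmd`)
for the model, parameter choices, and limitations.
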