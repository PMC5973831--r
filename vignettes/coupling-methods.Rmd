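---
title: "Methods: trial-level brain-behavior coupling with coupleEEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-level brain-behavior coupling with coupleEEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coupleEEG)
```

## The model

`coupleEEG` asks whether the single-trial amplitude of EEG source
activity in a region of interest (ROI) explains trial-to-trial variation
in a graded behavioral response (a donation of 0–6 euro, or a 0–10
rating).  The analysis is a two-level summary-statistics scheme, the
random-effects construction routinely used in neuroimaging:

**First level (within subject).**  After sensor conditioning and LCMV
beamforming, each trial yields a three-dipole ROI time course
`s(t) ∈ R³`.  For every subject, dipole and time sample we fit a robust
simple regression with the source amplitude as predictor and the
within-subject, within-condition Z-scored response as outcome, keeping
the slope.  The direction of the regression (activity predicting
behavior) follows the summary-statistic convention; with a single
predictor the slope is zero exactly when the correlation is, so the test
of "no coupling" is unaffected by the direction choice.  Robust
regression (iteratively reweighted least squares with Tukey's bisquare)
is used because single-trial EEG amplitudes are heavy-tailed: occasional
residual artifacts would otherwise dominate ordinary least squares.

**Second level (across subjects).**  If the ROI carries no information
about behavior, subjects' slope vectors are distributed around zero.  At
each time point we test that with the one-sample Hotelling statistic
over the subjects' dipole 3-vectors,

\[ T^2(t) = n\,\bar{x}(t)^\top S(t)^{-1} \bar{x}(t), \qquad
   F(t) = T^2 \frac{n-p}{p(n-1)} \sim F_{p,\,n-p} \text{ under } H_0, \]

with \(p = 3\) dipoles.  Working multivariately over the three dipole
axes avoids committing to a source orientation: \(T^2\) is invariant
under any common invertible linear transform of the dipole frame (a
property the test suite asserts to 1e-8), so the arbitrary axes of a
forward model cannot change the inference.

**Cluster-level correction over time.**  Adjacent time points with
\(F\) above the critical value at \(p_{unc} = 0.01\) (4.675 for
\(n = 28, p = 3\)) are merged into clusters scored by their summed
statistic.  The null distribution of the maximum cluster mass is built
by sign-flip permutation: each permutation multiplies every subject's
entire slope time course (all dipoles and times) by an independent fair
coin, valid because under the null the slopes are symmetric about zero.
A cluster's pseudo-p is `(1 + #(null ≥ mass)) / (nPerm + 1)` — the
add-one convention keeps pseudo-p strictly positive and makes the floor
`1/(nPerm+1)` explicit.  Bonferroni correction then handles the
ROI × condition family (default m = 8: four ROIs — two plus their
mirrored counterparts — times two conditions; `m` is configurable
because the family size is a design choice of the study at hand).

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `lowpassHz` | 60 | Hz | retains evoked bands, removes EMG-range noise |
| `bandstop` | 49.5–50.5 | Hz | European line noise; 4th-order zero-phase Butterworth notch |
| `baselineWindow` | −0.4 to −0.2 | s before fixation | pre-stimulus quiet period |
| `rejectThreshold` | 150 | µV peak-to-peak | automated surrogate for visual artifact screening |
| `lambdaReg` | 0.05 | fraction of mean sensor power | common-average-referenced covariances are rank-deficient; 5% is the conventional loading |
| `clusterAlpha` | 0.01 | — | cluster-forming level on the F scale |
| `nPerm` | 1000 | — | pseudo-p floor ≈ 0.001, enough for Bonferroni at m = 8 |
| `bonferroniM` | 8 | — | ROI × condition family size |
| IRLS tuning | 4.685 | — | bisquare constant giving 95% Gaussian efficiency |

Filter design is 4th-order Butterworth applied forward–backward
(zero phase) — the field's default where only cutoffs are prescribed.
The covariance entering the beamformer is computed from the evoked
response (trial average) over the entire epoch, per condition, with
filters built separately per condition so that slow changes in noise
structure between sessions cannot leak across; `covarianceMode =
"trials"` pools single-trial covariances instead, as a sensitivity
analysis.  When the pipeline re-references the data to the common
average it applies the same transform to the lead-field rows: unit gain
must hold in the reference frame of the data, and skipping this step
measurably attenuates reconstructed coupling.

## The synthetic-data generator

The generator emulates the structure of a costly-helping experiment:

* **Behavior.**  Validated stimulus intensities 2–7 are drawn with the
  shipped count presets (`table2_eeg`: 43 Hand + 52 Face = 95 trials;
  `table2_tms`: 30 + 30 per session).  Donations follow
  `round(clip(intercept + b_s·intensity + ε, 0, 6))` with subject slopes
  `b_s ~ N(0.6, 0.15²)` euro per intensity unit, intercept −0.2 euro and
  trial noise SD 0.8 euro.  Those defaults were chosen once so that the
  synthetic group mean donation (≈2.1 euro), its spread, and the
  Z-slope magnitudes (≈0.5) sit in the range a donation paradigm
  produces; rounding is half-away-from-zero because the donation bar
  moves in 1-euro steps.  Ratings use the same scheme on a 0–10 scale.
* **Brain.**  Sensors are laid out parametrically on a unit disc
  (sunflower layout, a stand-in for an electrode cap); each ROI
  contributes two tangential (Gaussian-derivative) and one radial
  (Gaussian) topography, unit-normed, full rank by construction.  The
  coupled ROI's source is `(γ0 + γ1·z + η)·w(t)` along a fixed dipole
  orientation, where `w` is a Gaussian bump (σ = 50 ms) restricted to
  the coupling window — restriction makes "coupling confined to the
  window" literally true, at the cost of a slightly truncated bump.
  Defaults γ0 = 5, γ1 = 1, amplitude noise 0.5, white background source
  noise SD 1 on every dipole and white sensor noise SD 1 give a
  per-trial amplitude–behavior correlation around 0.6 at the waveform
  peak: a deliberately clear testbed effect, stronger than typical real
  single-trial EEG couplings.
* **Seeding.**  One master seed derives named sub-streams (table, lead
  field, per-subject epochs), so components can be regenerated
  independently and every run is exactly reproducible.

What the generator does **not** emulate: volume-conduction geometry of a
real head, correlated (1/f, alpha) background spectra, ocular artifacts,
non-stationary noise, or behavioral drift.  Passing tests therefore
demonstrate the correctness and calibration of the *procedure* — not
that real data would yield any particular effect size.

## Validation experiments and problem sizes

Two simulation studies validate the inference engine end to end; both
run the identical pipeline code at reduced problem sizes chosen as a
package design decision so the experiments remain routine to re-run:

* **Null calibration** (`fwerSimulation`): 200 studies of 12 subjects,
  12 channels, one ROI, 40 trials, 1.5 s at 100 Hz, with γ1 = 0, 200
  permutations each.  The fraction of studies with any cluster pseudo-p
  ≤ 0.05 estimates the family-wise error rate and should fall in the
  binomial 99% band [0.02, 0.09] around the nominal 0.05.
* **Window recovery** (`clusterRecoverySimulation`): 20 studies of 24
  subjects, 16 channels, two ROIs, the full 95-trial stimulus set, 4-s
  epochs at 125 Hz, coupling confined to 420–480 ms after the noxious
  event; slopes are fit over the post-event second and 399 permutations
  are used (pseudo-p floor 0.0025, well under the Bonferroni cutoff
  0.05/8).  A study counts as a success when a Bonferroni-significant
  cluster in the target ROI overlaps the true window.

The default recording conditions (64 channels, 500 Hz, 7-s epochs,
Table-preset trial counts) remain the generator defaults; the validation
studies scale the *problem size*, not the procedure.

## Numerical choices and degenerate inputs

* IRLS: OLS start; scale re-estimated each iteration as
  `MAD(residuals)/0.6745`; convergence when coefficients move < 1e-8;
  at most 50 iterations, non-convergence flagged rather than raised.
  When the MAD collapses to zero (a majority of points fit exactly) the
  coefficients are frozen instead of rescaled — the classic breakdown
  guard; this is what keeps a 20-point line with one gross outlier at
  slope 1 rather than snapping back to OLS.  Constant predictor columns
  inside the mass-univariate sweep (e.g. identically-zero source
  segments) get slope 0; the scalar `robustFit()` rejects constant x
  outright.
* Slope t values use the final weighted-least-squares covariance with
  `n − 2` degrees of freedom — adequate for flagging per-subject fits;
  group inference never uses them.
* Hotelling: 3×3 systems are inverted by closed-form cofactors,
  vectorized across time; a time point is flagged singular (and excluded
  from clusters) when `|det|` falls below a relative tolerance, rather
  than patched by regularization.
* Sign flips are i.i.d. fair coins per subject; the identity assignment
  is an admissible draw.  Permutation streams derive from the config
  seed per ROI × condition cell, so adding a cell never perturbs
  another's p-values.
* `zscoreWithin` refuses constant groups by name; perfect correlations
  in rating accuracy are clipped at `|r| = 1 − 1e-12` with a warning
  before the Fisher transform.
* The two-way repeated-measures ANOVA is delegated to `stats::aov` with
  the `Error(subject/(A*B))` stratification; effects with vanishing sum
  of squares are reported as F = 0, p = 1 (additive data thus give an
  exact zero interaction), and effects with vanishing error term as
  F = ∞, p = 0.
* Newman–Keuls p-values are adjusted to be monotone over nesting (an
  enclosed pair inherits the largest p among pairs enclosing it), which
  reproduces the classic blocking rule via `p ≤ α` and gives the exact
  studentized-range/t identity in the two-group case.
* The JZS Bayes factor integrates the non-central-t likelihood against
  the Cauchy(0, 0.707) prior with adaptive quadrature; one-sided tests
  truncate the prior to the stated direction.  The test suite checks the
  result against an independent 20001-point trapezoid oracle to 1%.

## Design decisions where the design was open

* **Statistic scale for cluster mass.**  Masses sum the F-transformed
  statistic; the printed critical value 4.675 at `p_unc = 0.01` with 28
  subjects and 3 dipoles is exactly the F(3, 25) quantile, which pins
  the F scale down as the working scale.  Raw-T² massing is available
  via `statScale = "T2"`.
* **Bonferroni family size** defaults to 8 (4 ROIs × 2 conditions) and
  is configurable, since reasonable family definitions differ.
* **Epoch time base.**  Epoch time is stored relative to movie onset
  with named event latencies (fixation −1 s, noxious event +1 s by
  default); cluster boundaries are reported in ms relative to the
  noxious event, the scale on which such effects are discussed.
* **Serialization.**  Epoch containers are stored as RDS with a JSON
  sidecar of dimensions, sampling rate, events and generation
  parameters, so provenance is inspectable without loading data; trial
  tables and lead fields travel as CSV.
* **Degrees of freedom** are always derived from the data actually
  analyzed, never hard-coded.
* **Interface.**  The package surface is the function API plus this
  vignette; a thin CLI wrapper (`inst/scripts/coupling-cli.R`) exposes
  `simulate`, `eeg-run`, `tms-run`, `tdcs-run` and `stimstats` verbs for
  shell use.

## Known limitations

* No realistic forward modelling: the parametric disc lead field shares
  only the algebraic structure (full-rank 3-column blocks) with a
  BEM-derived one; absolute source units are arbitrary.
* Temporal clustering only — no spatial/spatio-temporal adjacency, no
  TFCE.
* Amplitude-threshold artifact rejection cannot emulate an expert's
  visual screening, and ICA ocular correction is out of scope; datasets
  with heavy blink contamination need external cleaning first.
* The robust-slope first level assumes the response is meaningfully
  Z-scorable within subject and condition; near-constant behavior
  (e.g. a subject donating the same amount on almost every trial) makes
  the Z-transform, and hence the coupling question, ill-posed for that
  subject.
* The BrainVision reader covers the multiplexed IEEE-float and INT16
  dialects only.
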