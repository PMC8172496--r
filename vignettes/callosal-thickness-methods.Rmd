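---
title: "Pointwise callosal thickness morphometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pointwise callosal thickness morphometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccmorph)
```

## The measurement model

The corpus callosum (CC) appears in the midsagittal plane as an arch running
from the rostrum (anterior) through the genu, body and isthmus to the
splenium (posterior). `ccmorph` quantifies its local thickness without any
subregional parcellation: parcellation schemes impose arbitrary boundaries
on a structure with no macroscopic landmarks, and the package instead
measures thickness at many corresponding positions along the whole
structure.

Given a subject's traced upper and lower callosal boundary polylines
(coordinates in mm; the package convention is x increasing
anterior→posterior, y increasing inferior→superior), the pipeline is:

1. **Orientation.** Each boundary is oriented anterior-first by comparing
   endpoint x coordinates, so Position 1 is always the rostral tip and
   Position `n_points` the bottom of the splenium.
2. **Equidistant resampling.** Each boundary is resampled to `n_points`
   (default 100) points at equal arc-length spacing along the traced
   polyline, by linear interpolation within segments. Manual traces are
   polylines; spline interpolation would invent curvature the rater never
   drew, so it is deliberately avoided.
3. **Midline.** The callosal midline is the spatial average of the two
   resampled boundaries. The default (`pointwise_average`) averages
   coordinate-wise at matched indices. An alternative
   (`resampled_average`) re-resamples that average curve to equidistant
   points along its own arc length; it is provided for sensitivity
   analyses because published descriptions of the midline construction
   leave this step ambiguous.
4. **Callosal distance values (CDVs).** The CDV at position i is the
   distance from the upper surface point i to midline point i. Under the
   default midline this equals the distance from the lower point to the
   midline and half the upper–lower inter-point distance, so a single CDV
   per position summarizes both surfaces; local thickness is 2 CDV. This
   is why the analysis treats 100 dependent variables rather than 200:
   upper-to-midline and lower-to-midline distances are identical by
   construction, and result maps are simply mirrored onto both outlines
   for display.

Correspondence between the two boundaries is index-wise after independent
resampling — the simplest reading of "corresponding surface points". No
closest-point matching is performed.

### Numerical behaviour worth knowing

* Resampled points sit at their prescribed arc-length fractions of the
  *source* polyline essentially to machine precision (the test suite
  verifies 1e-9 relative).
* Resampling an already-resampled boundary again is exact only for
  straight polylines. On curved input the chord length of the resampled
  chain differs from the source arc length by O((κ·Δs)²), so repetition
  reproduces the points only to that discretization bound (sub-micron to a
  few microns at anatomical curvatures and n = 100; the suite asserts a
  1e-3 mm bound on a circular-arc fixture). A tolerance of 1e-9 would be
  achievable only on straight segments.
* Thickness changes alter boundary arc length, so two shapes differing
  only inside a window acquire slightly different index-to-arc mappings:
  window edges effectively shift by up to about one position. This is an
  inherent property of index-wise correspondence, not an implementation
  artifact; the parameter-recovery tests therefore classify positions by
  the generator's noise-free ground truth rather than by nominal window
  indices.
* Degenerate inputs: boundaries must have ≥ 2 vertices, finite
  coordinates and no zero-length segments (hard errors); upper/lower
  endpoint mismatch beyond a tolerance (default 2 mm) is a warning only,
  since real tracings meet at the tips only approximately and synthetic
  test shapes need not meet at all. An exact tie in the orientation test
  (equal endpoint x) returns the polyline unchanged.

## The statistical model

At each position independently the CDV is modelled by ordinary least
squares:

> cdv_i = intercept + diagnosis contrasts + covariates + error

with diagnosis reference-coded (HC as reference when present) and the
omnibus hypothesis tested by an extra-sum-of-squares F on the joint
nullity of the group contrasts: df1 = k − 1, df2 = n − p, where p counts
all model columns. Post-hoc contrasts restrict the model to two groups and
report F with df1 = 1 (the square of the corresponding t). Inference is
two-sided throughout.

**Covariates.** Age, education, TIV, illness duration and
chlorpromazine-equivalent dose, in that order, all configurable. Education
is retained by default because diagnostic groups typically differ on it.
Sex is never entered: the design is exactly sex-matched and sex is
strongly correlated with TIV, which is already in the model.

**Clinical covariate centering.** Illness duration and medication dose
are undefined for controls. Entering raw values would conflate the
patient–control contrast with medication exposure, so in any model that
includes HC these covariates are centered to the patient's own group mean,
with controls (and the group mean itself) at 0. Centered covariates are
mean-orthogonal to the group indicators, so they absorb within-group
dose/duration variability without moving the group contrasts. In
patient-versus-patient contrasts the raw values are used, preserving
between-group differences in exposure. A patient with a missing clinical
value is imputed at the own-group mean (centered 0) rather than dropped,
preserving the matched design.

**Multiple testing.** Each comparison's positions form one FDR family
(the omnibus map is one family, each pairwise map its own), corrected by
the Benjamini–Hochberg step-up procedure at q = 0.05 by default. The
Benjamini–Yekutieli variant is available for users worried about the
strong spatial correlation of adjacent positions; BH is the default
because the neighbouring-position dependence is positive, the regime in
which BH retains control.

**Post-hoc gating.** `run_study()` fits pairwise contrasts only when the
omnibus family contains at least one FDR-significant position (the
protocol's "in case of significant ANCOVA results"); the gate can be
disabled for methodological work.

**Power.** `anova_power()` uses the noncentral F distribution with
noncentrality λ = f²N (Cohen's f), df1 = k − 1 and df2 = N − k − c for c
covariates. At f = 0 it returns α exactly.

`anova_from_summary()` reconstructs one-way ANOVA F statistics from
published group means, SDs and sizes, which is how the demographic
worked examples (age F ≈ 0.05, education F ≈ 5.5 on df 4;145 for five
groups of 30) are reproduced without raw data.

## The synthetic cohort generator

No imaging data ship with the package; a generator produces cohorts whose
every property is known, so the full pipeline can be validated end to end.

**Geometry.** The centerline is a circular arc with chord 72 mm and apex
height 22 mm — gross CC proportions — with upper and lower boundaries
offset along the local normal by a position-dependent half-thickness.
Constant curvature keeps the index-correspondence stagger between the
offset boundaries and the centerline small, which in turn keeps the
zero-noise pipeline inversion (recovering the template through resampling
and midline construction) within 2% of the template mean. The template
half-thickness is a constant base (2.8 mm) plus Gaussian bulges at the
genu (amplitude 1.6 mm at arc fraction 0.12) and splenium (2.0 mm at
0.88) and a mid-body dip (0.9 mm), giving local thickness of roughly 9 mm
at the bulges and 4 mm in the body. The anatomy is deliberately stylized:
an arch with normal offsets exercises every geometric and statistical
operation; no claim of anatomical realism is made (no rostral hook, no
curvature variation, no bending-angle variability).

**Effects.** Group effect maps are per-position multiplicative thickness
factors. They are applied as piecewise-constant arc-length cells (one
cell per position) rather than interpolated ramps, so that an injected
window occupies exactly its stated positions in the emitted geometry.
Preset maps: `null`; `ocd_global` (thinning everywhere except a mid-body
exemption, positions 40–60); `sz_focal` (thinning only in the rostrum,
positions 1–8, and isthmus, positions 70–80); and `paper_like` combining
both with BD/MDD unaffected. The window boundaries are package choices —
the source protocol defines no numeric ranges — and are configurable.
The default factor 0.8 (20% thinning) is likewise an artifact choice
sized for statistical power in validation runs, not an empirical effect
size.

**Noise model.** Three sources, all defaults chosen once as plausible
rather than fitted to any dataset:

* *Tracing noise* — isotropic Gaussian coordinate jitter per vertex,
  SD 0.25 mm (quarter-voxel at 1 mm isotropic imaging).
* *Head-size scaling* — each subject's thickness is scaled by
  (TIV/1450)^0.5, making part of the inter-subject variability
  explainable by the TIV covariate; this mirrors the head-size dependence
  that motivates entering TIV in the ANCOVA in the first place.
* *Residual subject scale* — a lognormal multiplier with SD 0.03.
  Together with the TIV component this yields roughly 5% global
  inter-subject thickness variability. The residual component is shared
  across all positions of a subject, which makes position-wise tests
  correlated within a cohort — a realistic and consequential property:
  pooled rejection fractions across positions of one cohort have more
  variance than a binomial count. Calibration checks that rely on the
  binomial standard error therefore simulate the *response* under the
  fitted model's assumptions (iid Gaussian errors per position against a
  real covariate design), while cohort-level simulations are judged on
  FDR-level criteria that are robust to this dependence.

**Covariates.** Ages are drawn once per within-group index and shared
across groups (exact one-to-one age matching, the strict version of the
±1-year matching the statistics assume); sex alternates M/F (15/15 at
n = 30); education, illness duration and chlorpromazine equivalents are
drawn from truncated normals with group-specific means and SDs matching
the published demographic summaries; TIV ~ N(1450, 130) ml truncated at
900. HC clinical covariates are absent, never zero.

**Reproducibility.** A single seed drives everything. Per-subject
substream seeds are drawn from one master stream seeded by the global
seed; deriving them arithmetically (seed + f(index)) is avoided because
nearby `set.seed` values leave measurable correlations in the first draws
of their streams, which masquerade as spurious group differences in a
matched design.

**Degenerate noise.** If coordinate noise produces a zero-length segment
or pushes a vertex across the midline, the subject is regenerated with a
warning, up to a bounded number of retries, then errors.

## What passing tests do and do not show

The generator's cohorts are smooth, exactly matched, Gaussian-noised and
free of tracing bias, rater drift, segmentation failures and lesion
artifacts. Tests passing on them demonstrate that the geometry is
faithful, the linear model and FDR machinery are correctly implemented
and calibrated, and that regionally injected thinning of realistic
magnitude is recovered with high sensitivity and controlled false
positives. They do not demonstrate robustness to the failure modes of
real tracings, nor that any particular clinical effect size is
detectable in real populations.

Problem sizes used by the validation suite (package choices balancing
Monte-Carlo error against convenience): cohorts of 5 × 30 subjects at 100
positions; 10 seeds for parameter-recovery runs; 2,000 pooled
position-tests for type-I calibration; 200,000 replicates for the
ANOVA-power Monte-Carlo oracle.

## Known limitations

* Index-wise correspondence repositions effect-window edges by up to
  about one position (see above); narrow focal effects are localized no
  more finely than that.
* The profile's extreme positions approach zero CDV when tracings meet at
  the tips and carry little signal; they are included in the profile, not
  trimmed.
* Published demographic tables of the motivating study contain rows whose
  reported statistics are not reproducible from the printed summaries
  (e.g. a two-sample t with df 57 from two groups of 30, and pairwise
  clinical rows with unexplained missing-data patterns); the package
  reproduces the rows that are internally consistent and makes no attempt
  at the others.
* Mixed-effects, permutation and spatial-cluster inference are out of
  scope, as is any MRI processing upstream of the traced contours.
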