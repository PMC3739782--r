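---
title: "Separating taphonomic deformation from biological shape variation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{taphomorph methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taphomorph)
```

## The problem

Fossil skulls from a single species can look like several species once
burial compaction has flattened some dorsoventrally, squeezed others from
the sides, crushed one side inward, or rotated the braincase against an
undistorted snout. When each deformation style recurs across specimens it
produces a *taphomorphotype* — a cluster in shape space that mimics a taxon.
`taphomorph` provides the quantitative machinery to ask whether the
structure of a landmark-based morphospace is driven by such deformation
rather than by biology, and a simulator to validate that machinery when raw
landmark data cannot be shared.

## Shape analysis model

### Superimposition

Specimens are sets of K named 3D landmarks. `gpa()` removes the nuisance
parameters of position, size and orientation:

* **Position**: each configuration is centered on its landmark centroid.
* **Size**: each is divided by its centroid size (the square root of summed
  squared landmark distances to the centroid), which is retained separately
  for allometry tests. We deliberately use plain unit-size scaling and do not
  apply full-Procrustes scale refinements; sizes stay interpretable in mm.
* **Orientation**: each configuration is rotated by the orthogonal
  Procrustes solution (SVD) *constrained to proper rotations* (determinant
  +1). This matters here more than in most morphometric settings: left/right
  asymmetry is taphonomic signal, and an unconstrained solver could silently
  mirror a specimen.

The consensus is re-estimated as the arithmetic mean of the aligned
configurations and the align/average loop repeats until the unit-size
consensus moves by less than `tol` (root-summed-square, default 1e-10) or
200 iterations, whichever comes first (non-convergence is flagged and the
partial result returned). The first centered-and-scaled specimen seeds the
consensus; the converged result does not depend on that choice, and to make
the output completely pose-independent the ensemble is finally rotated into
a canonical frame: the consensus principal axes, each axis signed so that
the landmark with the largest absolute coordinate on it is positive, with
properness restored on the third axis if needed. Configurations in which all
landmarks are collinear have no defined rotation and are rejected.

### Tangent projection

Unit-size aligned shapes live on a curved manifold; PCA assumes linearity.
`tangent_project()` orthogonally projects each aligned configuration onto
the hyperplane tangent to that manifold at the unit-size consensus
(`x + (1 - x·ĉ)ĉ`). The projection is idempotent and changes coordinates
only at second order in the Procrustes distance to the consensus, so for
compact ensembles it is a small correction. Whether to project is exposed as
a switch (`shape_pca(..., tangent = )`); it defaults to ON, the conservative
standard choice, and the setting is recorded in the pipeline log.

### Principal components

`shape_pca()` eigen-decomposes the covariance (n−1 divisor) of the flattened
3K coordinates. Superimposition removes 7 degrees of freedom in 3D, so
trailing eigenvalues are numerically null; anything below 1e-12 times the
leading eigenvalue is treated as exactly zero and dropped. PC signs are
arbitrary; we fix them by making each loading's largest-magnitude element
positive, and every reported statistic is sign-invariant. Component
retention offers two rules: the broken-stick comparison (strict inequality,
stopping at the first failure — the conventional reading) and a fixed k,
defaulting to k = 4, because in taphonomic applications the leading axes are
retained for interpretability (each axis matching a recognizable deformation
style) rather than by the stick rule alone.

### Confidence bands and outliers

For each axis the band is `mean ± multiplier × SD` with the *sample* (n−1)
standard deviation — material at n ≈ 28 — and multiplier 1.96 (the normal
95% interval). Bands are per-axis by design: their products form the
axis-aligned "ellipses" drawn in morphospace plots. A specimen strictly
outside a band differs significantly from the mean of the whole sample on
that axis — not necessarily from any other group, which is why the workflow
deliberately avoids CVA/DFA-style group tests: with a handful of nominal
specimens per species there are no defensible groupings to discriminate.
A Mahalanobis ellipse would condition on the joint covariance instead; we
keep the per-axis form as the default because it matches how single-axis
deformation interpretations are read off wireframes.

### Error protocol

One specimen digitized R times (default design: 10 replicates) is projected
into the fitted morphospace — centered, unit-scaled, rotated onto the
consensus, tangent-projected if the model was — rather than included in the
PCA, so the morphospace of the main sample is unchanged by the error study.
Euclidean distances of replicates and of all other specimens to the
replicate mean, restricted to PC1–PC4, are compared; overlap (farthest
replicate ≥ nearest other specimen) would mean measurement error is
comparable to real specimen differences. A joint-PCA variant can be had by
simply appending the replicates to the input list.

### Allometry and sensitivity

Centroid sizes of fossil cohorts are rarely normal, so association between
PC scores and size uses Spearman rank correlation with midranks for ties.
Two-sided p-values come from full permutation enumeration for n ≤ 10 and
from the t approximation `t = r√((n−2)/(1−r²))` above that. Sensitivity
analyses (`sensitivity_rerun()`) drop named specimens and re-run the entire
superimposition and PCA — removing specimens moves the consensus, so
projecting old scores would be wrong. Significance is read at α = 0.05
throughout.

## The simulator

`skull_template()` places the 56 landmarks of the bundled psittacosaurid
scheme on an idealized skull, parameterized by length × width × height
(defaults 200 × 140 × 90 mm, an adult-sized skull, wider than tall, with a
10 mm jugal-horn flare). The geometry is invented but anatomically ordered —
rostral landmarks rostral, naris/orbit/temporal rings as loops, jugal horns
at maximal width — and exactly mirror-symmetric about the sagittal plane.
The template is versioned through its parameters: tests pin the exact build.
Coordinates use x increasing rostrum→caudal, +y to the left, +z dorsal;
superimposition removes orientation, so this is purely a bookkeeping choice.

Deformation operators (`deformation_spec()`), idealizing the recurring
deformation styles as linear or piecewise-rigid maps:

| mode | parameter | action |
|---|---|---|
| `dorsoventral_compression` | factor c ∈ (0,1] | z offsets from mid-height × c, uniform or caudally graded |
| `mediolateral_compression` | factor c | y offsets from the sagittal plane × c |
| `unilateral_crush` | factor c + side | one side's y compressed toward the midline, smoothstep-graded over a `falloff` band so the midline stays continuous |
| `caudal_rotation` | angle θ, hinge | landmarks caudal to the hinge rigidly rotated about the mediolateral axis; the rostrum is bit-identical |
| `allometric_juvenile` | scale s ∈ (0,1] | isotropic scale plus a shape offset ∝ (1−s): orbits inflated, rostrum shortened |

Identity magnitudes (c = 1, θ = 0) are exact no-ops, and operators compose
left-to-right.

`simulate_cohort()` draws a cohort from a `cohort_spec()`. The defaults
emulate the structure of a 28-skull single-locality fossil cohort: a mixture
dominated by dorsoventral (weight 0.4, c ~ U(0.6, 0.95)) and mediolateral
(0.3, c ~ U(0.7, 0.95)) compression with some unilateral crushing (0.2) and
occasional caudal rotation (0.1); three juveniles at roughly half size; and
two per-landmark isotropic Gaussian noise layers — individual biological
variation (SD 1.5 mm on a ~200 mm skull) followed by digitizing noise (SD
0.5 mm, digitizing being several times more precise than biology is
variable). These magnitudes are simulation parameters chosen to reproduce
the qualitative morphospace structure of real crushed cohorts; they are not
estimates of any particular specimen's deformation. All randomness flows
from one integer seed through R's standard RNG stream, drawn sequentially
per specimen, and the generating truth (mode, magnitude, side, age class)
travels with the cohort.

Two assignment styles are supported. `"single"` (default) gives each
specimen one deformation mode — discrete taphomorphotypes. `"compose"`
applies every mode to every specimen with independently drawn magnitudes —
continuous co-occurring deformation. The distinction matters for validation:
under `"compose"` the mode magnitudes are independent, the shape covariance
is diagonal in the mode basis, and PCA can recover the generating directions
as individual axes; under `"single"` the cluster means themselves contribute
a cross-covariance that rotates the leading axes away from the pure mode
directions by a fixed angle. Axis-wise recovery additionally requires the
modes' *effective* shape variances (magnitude variance × squared shape-space
displacement per unit magnitude) to be well separated — with near-equal
effective variances, finite-sample correlation between the magnitude draws
mixes the axes within the leading plane, even though the plane itself is
recovered. The recovery test suite therefore pairs a compression mode with
caudal rotation (well-separated effective variances) for axis-wise checks,
and checks plane (subspace) recovery for the near-degenerate
compression/compression pair. `recovery_report()` reports both: the best
single-axis |cosine| per mode and the `span_cosine` against the retained
subspace, with mode directions computed at reference magnitudes
(compression 0.8, crush 0.75, rotation 0.2 rad, juvenile 0.5) in the fitted
model's frame.

## What the simulation does and does not establish

Passing tests on simulated cohorts show that the pipeline's algebra and
inference behave as designed under known truth: filtering counts, GPA
optimality and invariances, spectrum recovery, calibrated null rejection of
the allometry test (5% at α = 0.05), and recovery of planted deformation
axes. Real fossil data differ in ways the generator deliberately omits:
breakage (here only emulated as missing landmarks), plastic flow, spatially
correlated and heteroscedastic digitizing error (no published data to
calibrate it), pose-dependent landmark visibility, and biological covariance
structure beyond isotropic noise. Conclusions about any real cohort must
come from running the pipeline on that cohort, not from the simulator.

## Numerical choices and degenerate inputs

* GPA convergence 1e-10 (consensus RSS change), cap 200 iterations;
  residual descent is monotone and tested.
* Null-eigenvalue cutoff 1e-12 × leading eigenvalue.
* Broken-stick comparison is strict (`>`); ties with the threshold drop the
  component, which only matters in constructed boundary cases.
* Outlier flagging is strict (`<` / `>`): a score exactly on the band edge
  is inside.
* Exact Spearman enumeration is capped at n = 10 (10! permutations,
  vectorized); beyond that the t approximation is standard and the exact
  null is unaffordable.
* Degenerate inputs error early with precise messages: empty retained
  landmark sets, all specimens dropped, collinear configurations, constant
  sizes, fewer than 2 replicates, fewer than 3 specimens for PCA, fewer
  than 4 remaining after a drop list.
* Problem sizes used in the test and acceptance runs — cohorts of 28–30
  specimens, 10,000-replicate null calibration, 20-seed recovery studies —
  were chosen as the smallest designs at which the respective statistical
  statements are stable.

## Known limitations

Missing landmarks are handled only by exclusion (landmark- or
specimen-wise); there is no imputation or sliding-semilandmark support.
Retrodeformation — inverting the crushing — is intentionally out of scope:
without independent knowledge of the original shape it mostly launders
assumptions into results. The per-axis confidence bands ignore score
covariance (by design, see above). And the fixed-k = 4 default encodes an
interpretability judgment, not a statistical criterion; the broken-stick
count is always reported alongside it in the pipeline log.
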