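---
title: "Methods: semi-automatic abdominal adipose tissue volumetry"
author: "adiposeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-automatic abdominal adipose tissue volumetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adiposeg)
```

# Scope and model

`adiposeg` quantifies abdominal visceral (VAT), subcutaneous (SAT) and
total (TAT) adipose tissue from a two-echo Dixon MRI acquisition.  The
method is deliberately training-free: it relies only on intensity
thresholds and positional priors (where subcutaneous fat sits relative
to the body outline), so it needs no annotated data and behaves
identically across cohorts.

The measurement chain is:

1. **Water/fat reconstruction** (when scanner fat-only images are
   absent).  A two-echo Dixon acquisition samples water and fat signals
   in phase (`IP = W + F`) and in opposed phase (`OP = W - F`), so
   `W = (IP + OP)/2` and `F = (IP - OP)/2`.  `reconstructWaterFat()`
   applies these identities; negative intermediates produced by
   magnitude noise are clipped to zero only after the conservation check
   `water + fat = IP`, which the implementation maintains bit-exactly by
   re-deriving fat from the rounded water image.
2. **Region of interest.** The operator marks the slice containing the
   L4/L5 intervertebral disc — the standard anatomical anchor for
   abdominal fat — and `selectRoi()` takes 25 slices (3 mm each) above
   and below, a 51-slice ROI.  Automatic disc detection is explicitly
   out of scope; the anchor is operator input by design.
3. **Body mask.** Per slice: Otsu threshold on the in-phase intensity,
   morphological closing (disc radius 3 voxels), hole filling and
   largest connected component.  This region underlies the abdominal
   volume and bounds every later mask.
4. **Fat mask.** A threshold on the fat-only image inside the body mask,
   followed by an opening of radius 1 voxel.  The default threshold is
   Otsu computed from in-body fat intensities (whole ROI); a fixed
   operator threshold (`thresholdSpec("fixed", value)`) mirrors the
   manual threshold-setting of the original acquisition protocol, and a
   per-slice Otsu variant exists for strongly shaded data.
5. **SAT/VAT separation** (`splitSatVat()`), per slice:
   the *boundary shell* is the body minus its erosion by `shellDepth`
   (2 voxels); SAT is the union of fat components touching that shell;
   the *abdominal cavity* is the largest connected component of
   body minus (SAT and shell), hole-filled; VAT is fat inside the cavity.
   Fat belonging to neither — vertebral marrow, intermuscular fat —
   remains in the total-fat mask only, which is why TAT can exceed
   VAT + SAT, as it does in real abdomens.
6. **Volumetry** (`computeVolumes()`): masks are restricted to the 30
   central ROI slices and voxel counts are converted to mL with the
   voxel volume (4.6875 mm³ at the default 1.25 × 1.25 × 3 mm
   reconstruction).

# Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `halfWidth` | 25 | slices | ROI half-depth around L4/L5 (51 slices total) |
| `centralCount` | 30 | slices | volumetry slab |
| `bodyCloseRadius` | 3 | voxels | bridges skin gaps in the body mask |
| `shellDepth` | 2 | voxels | boundary shell seeding SAT |
| `fatOpenRadius` | 1 | voxels | suppresses thin SAT–VAT leakage channels |
| `connectivity` | 8 | – | 2-D pixel neighbourhood (4 or 8) |
| threshold | Otsu | intensity | fat/non-fat cut inside the body |

Processing is 2-D per transverse slice throughout: with 6 mm acquired
(3 mm reconstructed) slices, through-plane connectivity is unreliable,
so per-slice analysis with 8-connectivity is the default and the
connectivity is configurable.

**Central-slab convention.** "The central 30 of 51 slices" does not by
itself say which 30.  The package uses the half-open window
`[c - ceil(k/2) + 1, c + floor(k/2) + 1)` around the L4/L5 slice `c`,
i.e. 14 slices below and 15 above the anchor at the defaults.  The
convention is asymmetric but fixed, documented, and configurable via
`centralCount`; all truth volumes in the phantom module use the same
window, so comparisons are internally consistent.

**Separation mechanism.** The positional prior is implemented as
boundary-shell seeding plus a largest-interior-component cavity.  Any
other training-free operator with the same contract could be swapped in
behind `SegmentationParams` without API change; this one was chosen
because it is deterministic, needs no anatomy model, and reproduces the
qualitative behaviour of manual reads, including marrow fat counting
toward TAT only.

# The synthetic phantom

No public scans accompany the method, so the package ships a parametric
abdominal phantom (`phantomSpec()`, `generatePhantom()`) with analytic
ground truth:

* an elliptic-cylinder body (default semi-axes 160 × 110 mm, 150 slices
  at 1.25 × 1.25 × 3 mm³) with a subcutaneous fat ring of uniform
  thickness;
* ellipsoidal visceral fat blobs inside the cavity, kept clear of the
  ring by a clearance of twice the shell depth and mutually disjoint
  (both checked numerically at construction, with offenders named);
* optional non-fat organ cylinders (darker than fat, brighter than the
  muscle background);
* an optional vertebral body embedded in the posterior ring containing a
  marrow-fat disc — fat that the separation stage must leave in
  TAT only;
* intensities `fat = 1000`, `water = 300` (arbitrary units) and Rician
  magnitude noise, default SD 50: complex-channel Gaussian noise
  followed by the magnitude for in-phase and fat-only images, additive
  Gaussian for the phase-corrected signed opposed-phase image.

Boundary voxels take area-weighted composite intensities from a 4×
supersampled in-plane grid (3 z-subsamples for blobs), and truth masks
use the ≥ 50% occupancy rule.  Occupancies are snapped to the exact
1/48 grid of the supersampling scheme so that a half-occupied voxel sits
exactly at 0.5 for both the truth rule and the composed intensity.
`analyticVolumes()` gives closed-form slab volumes (ring annulus area ×
height, clipped-ellipsoid integrals, marrow cylinder), exact for
untapered bodies; the difference between voxelised truth and the closed
form is bounded by the partial-volume budget, the number of boundary
voxels times the voxel volume, which `GroundTruth@surfaceVoxels`
records.

`randomPhantomSpec(seed)` draws per-subject variation for cohort
simulations: the subcutaneous target volume (coupled to body size, ring
thickness solved in closed form), 3–6 blobs with randomised flattened
shapes placed by rejection sampling, and a marrow feature when the ring
can host one.  Draws are accepted when the closed-form VAT lies in
700–1400 mL and SAT in 1100–3900 mL over the central slab, which keeps
simulated cohorts in the range reported for overweight adults
(cohort means settle around 800 mL VAT and 2900 mL SAT).  Everything is
deterministic given the seed.

What the phantom does *not* emulate: real organ anatomy, breathing and
motion artefacts, coil shading, bias fields, and stack-stitching seams.
Passing the synthetic validation therefore demonstrates the geometric
and statistical correctness of the pipeline — thresholds recover
partial-volume boundaries, the positional separation respects the
compartments, volumes integrate correctly — but not robustness to
scanner-specific artefacts, which requires real data.

# Validation statistics

* `diceCoefficient()` — overlap `2|A∩B|/(|A|+|B|)`; two empty masks
  score 1 by convention (identical empty regions agree), logged.
* `blandAltman()` — bias (mean of reference − automatic differences),
  SD of differences, 95% limits of agreement (bias ± 1.96 SD) and the
  t-based 95% CI of the bias (n − 1 df).  Published agreement tables are
  sometimes ambiguous about which of the last two their "95% CI" means —
  at n = 10 the two differ by about √10 in width — so the class reports
  both under explicit names.
* `sampleSizeTwoSample()` — smallest per-group n at which a two-sided
  two-sample t test on the stated relative difference reaches the target
  power, using noncentral-t power.  The noncentral-t route matters: for
  a 30% difference on a mean of 3829 (SD 1106) at 80% power it returns
  16 per group, where a normal-approximation formula returns 15.
* `spearmanRank()` — Pearson correlation of mid-ranks (tie-aware);
  two-sided p by exhaustive permutation for n ≤ 9, t approximation
  above.  By exhaustive enumeration over the null support, the t
  approximation tracks the exact p within 0.05 for n ≥ 6 but can
  deviate by up to 0.077 at n = 5; the exact route is therefore the
  small-sample default.

# Numerical choices and degenerate inputs

* Connected components and hole filling use compiled per-slice flood
  fill with a 4/8 connectivity choice; hole filling traverses the
  background with the dual connectivity.  Results are tested against an
  independent brute-force flood fill.
* A `satThickness` of 0 produces no SAT; all interior fat becomes VAT
  (with a logged warning when no fat touches the shell).
* Empty fat masks and empty cavities return empty results with warnings
  rather than errors; an empty body on any slice is an error naming the
  slice, since a valid abdominal ROI always contains body.
* Ratios use the 0/0 → 0 convention.
* The magnitude identity `IP ≥ |OP|` cannot hold voxel-wise under noise;
  `dixonPair()` checks it statistically (tolerance 3× the background
  noise SD estimated from a corner patch; error if more than 5% of
  voxels exceed it).
* Magnitude-only opposed-phase input is accepted behind
  `magnitudeOP = TRUE` under a water-dominant prior (fat fraction
  ≤ 0.5), which mirrors fat-dominant voxels below one half; it is
  approximate and documented as such.  Scanner fat-only images, when
  available, are always preferred.

# Problem sizes

The shipped validation uses a 10-subject ensemble at full acquisition
geometry (150 slices, auto-sized in-plane grid around 270 × 190 voxels)
for the cohort Dice and volume-recovery checks, and a reduced
40-slice, 1.5 mm phantom for unit tests; both sizes exercise identical
code paths.  Monte-Carlo cross-checks use 50 000 replicates.

# Known limitations

* Thin fat channels connecting SAT and VAT can leak labels in either
  direction; the radius-1 opening mitigates but does not remove this.
* Vertebral marrow is excluded from VAT only when the vertebral body is
  outside the cavity component (posterior, ring-embedded); a vertebra
  protruding into the cavity contributes its marrow to VAT.  An operator
  exclusion mask is accepted by the command-line front end.
* The per-volume Otsu threshold assumes a reasonably bimodal in-body fat
  histogram; severe bias fields would call for the per-slice variant or
  a fixed operator threshold.
* Single-echo phase errors, T2* decay and B0 inhomogeneity are not
  modelled (two-point reconstruction only).
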