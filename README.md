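# adiposeg

Semi-automated quantification of abdominal adipose tissue from two-point
Dixon MRI, in R.

Visceral adipose tissue (VAT) is metabolically active and increasingly
implicated in gastrointestinal and metabolic disease, but measuring it
well requires volumetric imaging rather than single-slice surrogates.
`adiposeg` implements a training-free measurement chain for 3-D Dixon
abdominal scans, for imaging scientists and clinical researchers who
need reproducible VAT/SAT/TAT volumes without annotated training data:

* **Two-point Dixon reconstruction** — from in-phase (`IP = W + F`) and
  opposed-phase (`OP = W − F`) echoes, `W = (IP + OP)/2`,
  `F = (IP − OP)/2`, with exact signal conservation
  (`water + fat = IP`, bit-exact).
* **L4/L5-anchored segmentation** — the operator marks the L4/L5
  intervertebral disc; the pipeline takes 25 slices either side
  (51-slice ROI), extracts the body mask (per-slice Otsu, closing, hole
  filling, largest component), thresholds the fat-only image inside it,
  and separates subcutaneous from visceral fat by positional priors: fat
  components touching the body-boundary shell are SAT, fat inside the
  largest interior (cavity) component is VAT, and depot fat such as
  vertebral marrow stays in TAT only. Volumes come from the central 30
  slices, `volume = voxel count × dx·dy·dz`.
* **Synthetic abdominal phantom** — a parametric Dixon abdomen
  (subcutaneous ring, ellipsoidal visceral blobs, organs, vertebral
  marrow, Rician noise) with closed-form ground-truth volumes, so every
  stage is testable without any scan data.
* **Validation statistics** — Dice overlap, Bland–Altman agreement
  (bias, limits of agreement, CI of the bias), Spearman rank correlation
  with exact small-sample p-values, and noncentral-t two-sample
  sample-size calculations.

## Worked example

Generate a synthetic subject, segment it, and validate against the
known truth:

```r
library(adiposeg)

spec <- phantomSpec()                      # 150 slices, 1.25 x 1.25 x 3 mm
ph   <- generatePhantom(spec, seed = 1)    # DixonPair + fat-only + truth

seg <- segmentAbdomen(ph$fatOnly, ph$pair$inPhase,
                      roi = roiSpec(l4l5Index = 75))
seg$volumes
#> FatVolumes: VAT 814.6, SAT 2463.9, TAT 3296.5, abdominal 4980.3 mL; VAT/SAT 0.33, VAT/TAT 0.25

ph$truth@analytic                          # closed-form ground truth
#> FatVolumes: VAT 818.6, SAT 2474.9, TAT 3311.6, abdominal 4976.3 mL; VAT/SAT 0.33, VAT/TAT 0.25

compareSegmentations(seg$result,
                     list(sat = ph$truth@sat, vat = ph$truth@vat,
                          tat = ph$truth@fat, body = ph$truth@body))
#> ValidationReport
#>   Dice: sat 0.9960, vat 0.9964, tat 0.9961, body 0.9979
```

Every estimated volume lands within ~0.5% of the analytic value and the
per-region Dice overlap with ground truth exceeds 0.99. Note that
TAT (3297 mL) exceeds VAT + SAT (3279 mL): the difference is the
vertebral marrow fat, which the positional separation deliberately
leaves in neither compartment.

The power calculation behind a two-group VAT comparison (30% difference
on a reference mean of 3829 mL, SD 1106, 80% power, two-sided α = 0.05):

```r
sampleSizeTwoSample(3829, 1106, 0.30, 0.80, 0.05)
#> [1] 16
```

A thin command-line front end is included:

```sh
Rscript inst/cli/adiposeg.R phantom --seed 1 --out-dir phantom1/
Rscript inst/cli/adiposeg.R segment --fat phantom1/fat.nii.gz \
    --ip phantom1/ip.nii.gz --l4l5 75 --out-dir results/
Rscript inst/cli/adiposeg.R stats power --mean 3829 --sd 1106 --diff 0.30
```

## Package tour

| area | functions |
|---|---|
| I/O | `readVolume`, `writeVolume`, `readMask`, `writeMask`, `writeReport`, `readSegmentationConfig` |
| Dixon | `dixonPair`, `reconstructWaterFat`, `fatFraction` |
| Segmentation | `selectRoi`, `buildBodyMask`, `buildFatMask`, `splitSatVat`, `computeVolumes`, `segmentAbdomen` |
| Phantom | `phantomSpec`, `randomPhantomSpec`, `generatePhantom`, `analyticVolumes` |
| Validation | `diceCoefficient`, `blandAltman`, `compareSegmentations`, `cohortValidation` |
| Statistics | `sampleSizeTwoSample`, `twoSampleTPower`, `spearmanRank` |

The methods vignette (`vignettes/adipose-volumetry-methods.Rmd`)
describes the model, parameter choices, the phantom's scope and
limitations, and the numerical conventions in detail.
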