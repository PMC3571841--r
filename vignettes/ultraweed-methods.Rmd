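---
title: "Methods: ultrasonic and image-based weed infestation detection"
author: "ultraweed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ultrasonic and image-based weed infestation detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ultraweed)
```

## The measurement problem

Site-specific weed management needs to know where in a field the weeds are.
In cereals there is no crop-free inter-row band to inspect, but weed-infested
patches carry more biomass and a denser canopy than clean crop, so they read
*taller* to a downward-pointing distance sensor. `ultraweed` implements the
full analysis behind that idea:

1. **sensor chain** — an ultrasonic sensor's voltage output is converted to a
   distance, and plant height is obtained by subtracting that distance from a
   reference distance measured over weed-free ground;
2. **imaging chain** — nadir photographs of each sampling point, framed by a
   grey circular ring, are reduced to a plant-coverage fraction inside the
   ring via excess-green thresholding;
3. **statistics** — the sensor heights are related to manually assessed weed
   height, density and biomass by correlation and multiple regression, and
   infestation classes are predicted by canonical discriminant analysis.

A synthetic-data module generates plot images, voltage traces and field
tables with known ground truth, so every stage is testable end to end
without access to field data.

## Sensor model

The sensor outputs 0–10 V proportionally to the echo travel time. The default
calibration, established against a tape measure, is the linear map

$$d\,[\mathrm{cm}] = 7.0275\,v + 29.658, \qquad R^2 = 0.99 .$$

Plant height is $h = d_{\mathrm{ref}} - d$, with $d_{\mathrm{ref}}$ the
average of calibrated distances over the first 10 s of a trace taken over
weed-free ground (default mounting height 0.80 m). The sensing window is
350–1000 mm; the device flags echoes outside it by emitting its full-scale
output, which we treat as the error sentinel (10 V). A reading is `valid`
only if its distance, expressed in mm, lies inside the window; sample
summaries average the valid readings and report the invalid count.

Two boundary behaviours deserve note:

* the **sentinel voltage equals full scale**, so a legitimate distance of
  exactly 100.008 cm (10 V) is indistinguishable from an error flag. Field
  distances sit near 72–79 cm (3–8 cm canopies under a 80 cm mount), far from
  the ambiguity; the synthetic trace generator nudges an in-window voltage
  that collides with the sentinel by $10^{-9}$ V.
* the calibration intercept (29.658 cm = 296.58 mm) lies *below* the sensing
  window, so a trace generated for that distance correctly emits the
  sentinel even though the inverse mapping itself returns 0 V. The pure
  inverse is exposed as `distanceToVoltage()`.

## Imaging chain

Processing follows a fixed sequence, with every default equal to the printed
protocol value:

| stage | operation | default |
|---|---|---|
| colour space | `rgbToHsv8` | hue rescaled to 0–255 |
| frame segmentation | `segmentFrame` | H [116, 255], S [0, 128], V [31, 255], AND |
| noise removal | `medianMajority` | 10 × 10 majority window |
| ROI detection | `houghCircle` | accumulator on the image grid |
| frame exclusion | `shrinkRoi` | radius − 10 px |
| vegetation index | `exgImage` | ExG = 2G − R − B, clipped to [0, 255] |
| plant mask | `segmentPlants` | ExG > trunc(255 × 0.08) = 20 |
| coverage | `plantCoverage` | C = p~f~ / (p~f~ + p~b~) inside the ROI |

Conventions that the protocol leaves open, fixed here once:

* **Coordinates** are 0-based with x = column and y = row; circle membership
  uses pixel centres.
* **Binary median with an even window.** The median of a binary window is a
  majority vote; for the even 10 × 10 window the package uses offsets
  −4…+5 in both axes, ties (exactly 50 of 100) resolve to background, and
  pixels beyond the border count as background. Two consequences are worth
  knowing: a band narrower than 6 px is erased entirely, and the filtered
  structure shifts by about half a pixel up-left (an even window has no
  symmetric placement). That shift propagates into ROI centres, which are
  therefore biased by roughly −1 px in each axis; it is a property of any
  faithful even-window implementation, not of the fixtures.
* **Hough membership and ties.** An object pixel supports centre $c$ at
  radius $r$ iff its Euclidean distance to $c$ rounds to $r$
  ($d \in [r-\tfrac12, r+\tfrac12)$), evaluated in exact integer arithmetic
  ($4d^2 \in [(2r-1)^2, (2r+1)^2)$). The maximum is taken jointly over
  centre and radius; ties break to the smallest radius, then row-major pixel
  order. The accepted radius set is a configuration (`radii`), because the
  frame's pixel radius depends on camera height; the protocol effectively
  fixed one radius.
* **ExG truncation and strictness.** The 8 % threshold maps to grey level
  20 by truncation (255 × 0.08 = 20.4), and the comparison is strict
  (ExG > 20), so level-20 pixels are background. Clipping ExG to [0, 255]
  before thresholding is equivalent for any non-negative threshold.

## Statistics

* `pearsonCor` / `simpleRegression` — product-moment correlation and simple
  least squares. "Regression with fixed intercept" is ambiguous between
  through-origin and a pre-set intercept; both are supported
  (`throughOrigin`, `fixedIntercept`) rather than guessing the intent.
  R² for intercept-free fits follows `stats::lm` (uncentred total sum of
  squares).
* `multipleRegression` — OLS with backward elimination: while the least
  significant predictor has p > `alphaDrop` (default 0.10, matching
  retention of effects significant at the 90–95 % level), it is removed and
  the model refitted. Raw and standardized coefficients
  (raw × sd(x)/sd(y)), standard errors, p-values and adjusted R² of the
  final model are reported, along with the excluded set. With
  `alphaDrop = NULL` no predictor is dropped. Ties in elimination remove
  the first of the equally largest p-values — reproducibility over elegance.
* `cdaFit` — canonical discriminant analysis. With pooled within-group
  covariance $W$ and between-group scatter $B$, canonical directions are
  eigenvectors of $W^{-1}B$, computed stably by Cholesky whitening of $W$ so
  the eigenproblem stays symmetric. Axes are scaled to unit pooled
  within-group variance ($a'Wa = 1$) and signed so the largest-magnitude
  coefficient is positive; eigenvalues are reported on the conventional
  scatter scale ($S_w^{-1}S_b$), under which no-separation data give values
  near 0. At most min(groups − 1, features) axes are returned. Priors
  default to equal (the original software default is unknown);
  proportional and custom priors are supported.
* `cdaClassify` — nearest group centroid in canonical space, with the
  squared distance adjusted by $-2\log(\text{prior})$; exact ties go to the
  first group in label order. Only resubstitution is offered —
  cross-validation is beyond the scope of the analysis this package
  reproduces.
* `confusionPercentages` — row-normalized percentage matrices
  (rows = true group), plus raw counts and an overall accuracy helper.

## The synthetic world

The generators state a world once; their defaults are not tuned to tests.

**Field tables** (`genFieldTable`). Four groups — non-infested, grass,
broad-leaved, mixture — with covariates drawn from truncated normals at the
field-survey moments: grass weeds 3.6 ± 0.6 cm, 4.8 ± 2.9 plants,
0.7 ± 0.4 g; broad-leaved weeds 2.0 ± 1.1 cm, 3.5 ± 2.9 plants,
0.3 ± 0.3 g; crop 6.6 ± 0.5 cm, 9.7 ± 1.7 plants, 1.6 ± 0.5 g; weed
coverage 0.167 ± 0.103 (fraction). Weed variables are identically zero in
groups lacking that weed type. The ultrasonic height is a linear model over
the covariates whose raw coefficients derive from the reported standardized
ones (β × sd(u)/sd(x), sd(u) = 1.0; the three non-significant covariates
get 0), with intercept set so the equal-mix mean is 3.7 cm and residual sd
$\sqrt{1-0.667} \approx 0.577$ so the model R² is about 0.667. What this
emulates is the *moment and coefficient structure* of a first-date survey;
what it does not emulate is spatial correlation between neighbouring
samples, date effects, or crop–weed canopy overlap, so a green test
establishes correctness of the estimators, not field-level performance.

**Plot images** (`genPlotImage`). Colours are constrained by the
segmentation rules rather than realism: soil is a brown texture with
B ≤ G ≤ R (hue stays below 116) and 2G − R − B ≤ 16 (below the plant
threshold); plants are saturated green with ExG ≥ 120 and hue ≤ 102;
the ring is blue-grey with R = G < B, giving hue exactly 170,
saturation ≤ 77 and value ≥ 130 — comfortably mid-interval of the frame
thresholds, because a pure grey has an unstable hue and would not segment
reliably. The ring is 12 px wide (the frame appears as a 10–20 px structure
in real images) but only its central 6 px band is painted bright; the
borders are shaded below the V threshold, the way outdoor frames segment
only partially. This matters: if the full 12 px ring were segmentable, all
in-band Hough radii would tie within lattice noise and "the" radius would
be ill-defined; with a 6 px band the detected radius is pinned to the ring
centreline, which is the stated truth radius. Frame centres sit on the
integer pixel grid, matching the integer accumulator. Plant blobs are
random ellipses (semi-axes 3–9 px) painted until the target coverage is
exceeded, then trimmed — or padded — pixel-by-pixel at random, so the
painted fraction inside the true ROI equals the requested coverage to
within half a pixel. Blobs extend 3 px beyond the true ROI so a detected
ROI one or two pixels off samples a region with the same expected coverage.

**Voltage traces** (`genVoltageTrace`) invert the calibration exactly, add
Gaussian voltage noise (study default 0.02 V ≈ 0.14 cm, a round value of
the order of the sensor's mm-scale repeatability), and emit the sentinel
for out-of-window distances. All generator randomness flows from one seed
per call; fixed seed means byte-identical output.

**Study simulation** (`simulateStudy`) links the pieces: the before-weeding
image is painted with crop-plus-weed coverage (crop coverage
0.20 ± 0.05, truncated to [0.02, 0.6]; sum capped at 0.92), the
after-weeding image with crop only, and the trace encodes the table's
ultrasonic height under the 80 cm reference.

## Numerical and degenerate-input choices

* Calibration fitting refuses fewer than two distinct voltages; a
  non-positive fitted slope is an error, not a model.
* `referenceDistance` errors on any sentinel or out-of-window reading inside
  its window: a reference taken over weeds or out of range would silently
  bias every height.
* `houghCircle` requires a non-empty mask and positive radii;
  `shrinkRoi` refuses margins at or above the radius; `plantCoverage`
  refuses an empty ROI (the ratio would be 0/0).
* `cdaFit` reports a singular pooled within-group scatter as an error
  suggesting feature reduction, and requires two members per group.
* `multipleRegression` names the exactly collinear predictors in its error.
* Weed coverage from paired images is floored at 0: with weeds-only removal
  the difference is non-negative up to segmentation noise, and small
  negative values are measurement artefacts.
* Per-sample failures inside `runStudy` (missing image, undetectable frame,
  all-sentinel trace) are recorded with machine-readable reason codes and
  never abort the study.

## Known limitations

* The imaging chain carries the ~1 px up-left ROI-centre bias of the even
  median window discussed above; at ROI radii of 100+ px the effect on
  coverage is below 0.01.
* The binary classification features default to the system's own
  measurements (ultrasonic height, weed coverage); the original analysis
  does not enumerate its discriminant inputs, so this is a package choice.
* Before/after image pairs are assumed registered by sample id; no spatial
  registration is attempted.
* TIFF input is not supported (no TIFF reader among the package's
  dependencies); PNG is the native format, JPEG is readable.
* Real-data reproduction of the survey tables is out of reach by design:
  the field data were never deposited, so the statistical layer is
  validated by parameter recovery on the synthetic world instead.
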