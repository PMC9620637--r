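---
title: "Deep keypoint stadiometry for atrial septal defect assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep keypoint stadiometry for atrial septal defect assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Choosing between transcatheter and surgical closure of an atrial septal
defect (ASD) hinges on a handful of millimetre measurements made on three
standard transthoracic echocardiographic views: the defect diameter in each
view, the tissue rims between the defect and its neighbouring structures
(aortic wall in the parasternal short-axis view, superior and inferior vena
cava in the subxiphoid long-axis view, atrial roof and mitral annulus in the
apical four-chamber view), and the atrial septum length. A catheter-delivered
occluder needs a sufficiently small defect, adequate rims all around to
anchor its discs, and a septum long enough to house it; otherwise open
surgical repair is indicated.

`dks` implements this assessment as a transparent three-stage pipeline:

1. **Keypoint localization.** A multiscale-supervised stacked hourglass
   network (MSHNet) regresses per-keypoint heatmaps in each view - 3 points
   in PSSAX, 4 in SXLAX, 4 in A4C, 11 in total - with an anatomical-aware
   supervision (AAS) loss on pairwise/triplet co-occurrence maps and a fully
   convolutional fusion refiner (RegNet).
2. **Stadiometry.** Pixel distances between decoded keypoints are converted
   to millimetres using the image's measuring scale.
3. **Decision.** An explicit Boolean rule engine compares the measurements
   with device criteria and, for eligible cases, sizes the occluder as the
   maximum defect diameter over the three views plus a 4 mm margin, rounded
   up into the device catalogue (integer 8-32 mm waist diameters by
   default).

Only stage 1 is learned. Stages 2-3 are deterministic and auditable: every
decision carries a per-leaf rule trace, and a clinician can override any
keypoint through the file-based review hook before measurements are taken.

## The synthetic data generator

Clinical echocardiograms cannot be shipped, so the package includes a
generator that emulates the features this pipeline actually depends on: a
sector-shaped grayscale frame, a bright septum band interrupted by the
defect gap, landmark blobs at the rim anchor structures, an optional
Doppler-style high-intensity jet across the gap, multiplicative Rayleigh
speckle (unit-mean, mixed in with configurable strength), Gaussian blur, and
a randomized millimetre-per-pixel scale. Keypoints are placed analytically
on the septum line, so ground truth is exact by construction, and labels are
derived by running the decision engine on the true geometry - which is what
makes "the back half reproduces the labels" a meaningful end-to-end
invariant rather than a tautology: the test path goes through rendered
keypoints, pixel distances and the scale, not through the generator's
arithmetic.

Default generator conditions: defect diameters 5-20 mm (eligible cases) with
per-view jitter, rims 5.8-14 mm for eligible cases, a deficient 1.5-4.2 mm
rim or an oversized 32-34.5 mm defect for ineligible ones, septum length
equal to the A4C defect plus both A4C rims (collinear construction), septum
angle within ±25°, and a transcatheter fraction of 0.6, roughly the
prevalence in interventional series. The mm-per-pixel scale is drawn so the
anatomy spans 55-70% of the frame, preferring the 0.08-0.3 mm/px range of
typical acquisitions but rising above it when a large heart must fit a small
frame (the 64 px frames used in the fast tests). Samples stay clear of the
rule thresholds by a margin of at least 0.3 mm so that sub-micrometre
measurement error can never flip a label.

What the generator does **not** emulate: real speckle statistics and
attenuation, curved septa, view-dependent anatomy beyond the septum line,
probe-position variability, cine motion, and Doppler physics (the jet is a
brightness blob, not a flow field). Passing tests therefore demonstrate that
the pipeline is correct and trainable, not that the shipped defaults reach
clinical performance on real TTE.

## Heatmap targets and decoding

Ground-truth heatmaps are unnormalized Gaussians with peak 1 and a default
sigma of 2 px at full resolution - the standard target for hourglass-style
heatmap regression. The pyramid downsamples coordinates and sigma together
(sigma floored at 0.5 px so coarse levels keep a usable peak). Pair and
triplet AAS targets are element-wise maxima of the constituent single-point
maps: a co-occurrence response that stays in [0, 1] and is invariant to
permutation within the pair/triple. Alternatives (sums, line-segment tubes)
were rejected because sums leave [0, 1] and tubes are not
permutation-symmetric. Decoding is argmax plus a quarter-pixel offset toward
the larger axis neighbour, ties broken toward the smaller (row, column);
missing neighbours at borders count as zero, which keeps the decoded point
in-bounds. An exhaustive sweep shows encode-decode error is at most 0.5 px.
All-constant channels fall back to the grid centre with a low-confidence
flag.

## Network and training choices

The exact clinical architecture is not public, so the package uses the
canonical stacked-hourglass design at CPU-friendly sizes: per stack, an
encoder from 1/2 to 1/8 resolution with 3x3 convolutions, ReLU and 2x2 max
pooling, a symmetric nearest-neighbour-upsampling decoder with additive
skips, and 1x1 heads projecting each decoder feature map (1/8, 1/4, 1/2 of
the input) to per-keypoint heatmaps. AAS heads sit on the finest decoder
feature only - the anatomical loss is a training-time auxiliary and keeping
it single-scale bounds cost. Stacks are cascaded with the usual intermediate
remap of predicted heatmaps into features. RegNet upsamples the final
stack's heads to full resolution, concatenates and fuses them with a small
two-layer convolutional refiner. Disabling multiscale supervision and AAS
leaves exactly a vanilla stacked hourglass supervised at its finest scale.

Everything is trained with Adam on a sum of per-scale MSE terms (weights:
multiscale 1, pair 0.5, triplet 0.25, refiner 1; the relative weighting is a
package choice). Two deliberate deviations from common full-size practice:
the default learning rate is 1e-3 rather than 2.5e-4, and 1x1 output heads
are initialized at 0.1x the usual He scale so predictions start near the
zero background of the targets - at the small model sizes and batch sizes
used here both materially speed convergence within a 30-epoch budget.
Gradients are exact: the backpropagation is hand-derived and checked against
central finite differences to 1e-4 in the test suite.

Model selection uses *validation* PCK: although peak training PCK is
sometimes quoted as the tuning objective in this setting, a held-out
validation split exists precisely for that purpose, and selecting on
training PCK would reward memorization at these data sizes. PCK itself
counts a keypoint correct when its pixel error is at most `alpha` times the
measuring-scale length in pixels; `alpha = 0.1` by default (the customary
fraction where none is specified), inclusive at the boundary.

## Numerical and degenerate-input conventions

* Coordinates are 0-based continuous pixel positions, x rightward, y
  downward, origin at the top-left pixel centre; one convention everywhere,
  guarded by encode-decode round-trip tests.
* The PSSAX wall rim uses the nearer defect endpoint (one wall landmark
  serves two endpoints); all other rims pair with their schema-designated
  endpoint. Septum length is the roof-landmark to mitral-landmark distance,
  which coincides with rim + defect + rim for collinear geometry.
* An unavailable catalogue size maps to a surgical plan, not an error.
* Rule leaves comparing against a missing/NA operand evaluate to false;
  unknown measurement names are errors.
* QWK with a degenerate expected matrix and classification ratios with zero
  denominators return NaN with a warning rather than failing.
* The renderer refuses geometry that does not fit the frame at the given
  scale instead of silently cropping keypoints.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on synthetic data at
sizes chosen for a single CPU: 200 cases at 96 px for the back-half
exactness check, 100 noise-free cases for stadiometry soundness, a dense
quarter-pixel sweep of a 32x32 grid for the decoder bound, and, for the
learning checks, 64 px single-view images with a 1-stack, 16-channel model -
50 training cases and 30 epochs for the before/after-PCK comparison, and 40
training cases, 20 epochs and 3 seeds for the ablation ordering (full model
vs vanilla hourglass). At these sizes a training run takes about a minute;
the observed ordering (full model far above the vanilla ablation, which
barely gets off the ground in 20 epochs) matches the direction expected from
multiscale supervision plus full-resolution refinement, but the absolute
PCK values are far below what full-size training on real data reports and
should not be compared to them.

## Known limitations

* The synthetic septum is a straight band; curved or aneurysmal septa are
  out of reach of both the generator and the collinear septum-length
  definition.
* Rim thresholds (5 mm on all rims) and the septum-versus-device leaf are
  configurable defaults standing in for device-specific consensus criteria;
  users fitting a different occluder must supply their own rule set and
  catalogue.
* The black-box baseline is a deliberately small weight-shared multiview
  CNN; it exists as a comparison surface and forward-pass contract, not as
  a tuned classifier.
* Single frames only: no cine loops, no DICOM metadata, no TEE/ICE or
  balloon-sizing workflows.
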