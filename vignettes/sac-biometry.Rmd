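---
title: "Gestational sac biometry: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gestational sac biometry: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sacmetry)
```

## The measurement problem

In the first trimester, the gestational sac (GS) is the earliest reliably
visible structure on ultrasound. Its size anchors two routine clinical
judgements: estimating gestational age (GA) before an embryo can be
measured, and flagging an empty-sac miscarriage when the sac is large but
no yolk sac or embryo is seen (the classical decision point is a mean sac
diameter of 25 mm, equivalently about 7.2 gestational weeks). In practice a
sonographer traces the sac and places calipers on its longest axis and the
axis perpendicular to it. `sacmetry` automates the measurement half of this
workflow: given a binary segmentation of the sac and the physical pixel
spacing, it returns the two in-plane diameters and the GA estimate, plus
the evaluation and agreement statistics needed to validate a segmentation
model against expert annotations.

## From mask to gestational age

`run_biometry()` composes five steps, each exposed on its own:

1. **Component selection.** Segmentation output may contain speckle
   fragments; `extract_largest_component()` keeps the largest 8-connected
   foreground component. Eight-connectivity matches the boundary walk that
   follows (diagonally attached pixels stay part of the sac).
2. **Boundary tracing.** `trace_boundary()` is a Moore neighbor walk: from
   the first foreground pixel in row-major scan order, neighbors are
   examined clockwise starting just after the background pixel the walk
   backtracked from; the first foreground neighbor becomes the next
   boundary pixel. The walk stops when the start pixel is re-entered from
   its original backtrack direction (Jacob's criterion), which is robust on
   one-pixel-wide necks where the naive "stop at start" rule terminates
   early. The mask is padded with a one-pixel zero frame internally so sacs
   touching the image border still have a well-defined outer boundary.
   A subtlety worth recording: the set of pixels such a walk visits is
   exactly the foreground pixels with a background *4*-neighbor. A pixel
   whose only background contact is diagonal (an inner corner of a
   staircase, which occurs even on digitized convex ellipses) is stepped
   over by the diagonal move of the walk. The test suite therefore checks
   the traced set against the 4-adjacent oracle, and separately that every
   traced pixel touches background somewhere in its Moore neighborhood.
3. **Minimum-area rectangle.** `min_area_rect()` first reduces the boundary
   to its convex hull (`grDevices::chull()`), then uses the rotating
   calipers fact that a minimum-area enclosing rectangle is flush with some
   hull edge, so only hull-edge orientations need to be examined. Each
   candidate orientation is evaluated by rotating the hull and taking the
   axis-aligned bounding box. Ties are broken toward the first minimal
   orientation encountered, which makes results deterministic.

   One metrological subtlety lives here. The traced boundary consists of
   pixel *centers*, but a mask pixel is a unit square: a rectangle fitted
   to centers shaves half a pixel off every side, a systematic
   underestimate of about one pixel per diameter that grows with pixel
   spacing (at 0.5 mm/px it alone costs ~0.07 weeks of GA). `run_biometry()`
   therefore fits the rectangle to the four corners of each boundary pixel
   by default (`pixel_extent = "square"`), which makes the measured extent
   an essentially unbiased estimate of the continuous object's extent;
   `pixel_extent = "center"` retains the raw pixel-center convention for
   comparison. Degenerate masks (fewer than three distinct boundary
   pixels) always use centers, so a single pixel measures 0 by convention
   rather than 1 px.
4. **Corner labeling and diameters.** A cyclic list of four corners does
   not by itself say which pairs span the long and the short side, so the
   package fixes a convention: `c1` is the corner with the smallest row
   (then column), `c2` is adjacent along the *longer* side, `c3` adjacent
   along the *shorter* side, `c4` opposite. `measure_diameters()` then
   scales each coordinate difference by its axis spacing before the
   Euclidean distance, giving the maximum length `DM` (over `c1`–`c2`) and
   short diameter `Dm` (over `c1`–`c3`) in cm, with `DM >= Dm` by
   construction. The rectangle is fitted in pixel space and spacing applied
   afterwards; for anisotropic spacing the physical-space figure is
   strictly a parallelogram, but the per-axis scaled distances are the
   quantity clinicians' caliper formulas use, so that is what is reported.
5. **Gestational age.** The Hellman mean-sac-diameter formula,

   $$GW = \frac{0.5\,(DM + Dm) + 2.543}{0.7},$$

   with diameters in cm. It depends on the diameters only through their
   sum, increases strictly in each, and floors at $2.543/0.7 \approx 3.63$
   weeks for an empty measurement. Degenerate masks (a single pixel, a
   line) produce `Dm = 0` (and `DM = 0` for a point) rather than an error,
   since thresholding artifacts should degrade gracefully in a pipeline.

```{r biometry-example}
sac <- generate_sac(sac_params(a = 125, b = 75, angle = 30, spacing = 0.01),
                    seed = 1)
bio <- run_biometry(sac$mask, sac$params$spacing)
tidy(bio)
sac$truth$GW_weeks  # analytic ground truth of the phantom
```

### Units and spacing conventions

All spacings are cm/px internally because the diameters are reported in cm;
DICOM PixelSpacing values (mm) are divided by ten at ingestion
(`spacing_from_mm()`, `read_study()`). DICOM defines PixelSpacing as
*(row spacing, column spacing)*. Some published pipelines read the first
component as the column spacing instead; `read_study(spacing_order =
"paper")` reproduces that literal assignment for comparison purposes. The
two conventions coincide exactly when spacing is isotropic, which is the
common case for the cropped B-mode frames this package targets. Pixels are
treated as points at integer (row, col) centers, 1-based as is idiomatic in
R; every reported quantity is a distance or an area, so the index origin
has no effect on results.

## Segmentation losses, metrics, and agreement

The losses accept probability maps so they can drive training, with the
soft intersection $\sum p\,y$: Dice loss
$1 - (2\sum py + s)/(\sum p + \sum y + s)$, Jaccard loss with the soft
union $\sum p + \sum y - \sum py$, and pixel-wise binary cross-entropy.
Numerical choices, all documented in the function help: the smoothing
constant defaults to $s = 1$ (stabilizes near-empty masks; the exact
identities `dice_loss = 1 - dice` and `jaccard_loss = 1 - iou` on binary
maps hold as $s \to 0$ and are tested with $s = 0$ on non-empty masks);
cross-entropy probabilities are clipped to $[10^{-7}, 1 - 10^{-7}]$ before
the logarithms; region metrics on an empty/empty pair are defined as 1 and
on a mixed empty pair as 0.

`region_scores()` computes IoU, Dice, Recall and Precision on pixel sets;
the algebraic identity $Dice = 2\,IoU/(1+IoU)$ links the first two.
`consensus_mask()` builds the annotator-intersection ground truth (a pixel
is foreground only if every rater marked it), the strictest of the common
fusion rules and the one that makes "foreground" mean unanimous agreement.

`agreement()` performs a Bland–Altman analysis of paired GA estimates:
differences are *test − reference* by default (a `direction` argument
flips it), the bias is their mean, and the 95% limits of agreement are
$\text{bias} \pm 1.96\,SD$ with the sample ($n-1$) standard deviation —
the conventional choice; with $n$ in the hundreds the difference from the
$n$ denominator is far below the precision at which such limits are read.
`autoplot()` draws the standard plot; `glance()` adds the mean absolute
error, which summarizes disagreement magnitude without sign cancellation.

## The segmentation model zoo

Four encoder–decoder architectures are provided behind one interface
(`build_model()`), all sharing a ResNet50 encoder: `unet` (plain two-conv
decoder blocks on channels 256/128/64/32/16 with skip connections from the
five encoder stages), `resunet` (same layout with residual decoder blocks —
a 1×1 projection shortcut across each block — and a 1×1 head), `unetpp`
(nested dense-skip decoder over the same widths), and `deeplabv3` (dilated
final encoder stage for output stride 16, ASPP at 256 channels with atrous
rates 12/24/36 plus image-level pooling, and bilinear ×16 upsampling).
These decoder configurations are pinned by the test suite through
`count_trainable_params()`, so the four totals (32,521,250 / 33,435,410 /
48,985,890 / 39,633,986) are part of the package contract: any change to a
kernel size or channel width breaks a test. The head produces two logits
(background/foreground) reduced to a single-channel probability map by a
channel softmax, $p = \sigma(z_2 - z_1)$ — the two-logit head is what the
pinned parameter totals imply, while downstream code only ever sees one
probability per pixel. `out_channels = 1` gives the plain sigmoid variant.

The engine underneath is a small layer-graph system written for this
package: convolution via im2col and BLAS GEMM (C++ for the memory
shuffle), batch normalization with batch statistics during training and
running statistics at inference, hand-written reverse-mode gradients for
every op, and Adam. Gradients are verified against central differences in
the test suite. Weights are He-initialized from a seed; two builds with
the same seed are bit-identical, and no pretrained weights are required
or downloaded.

### Training protocol

`train_config()` defaults encode the reference protocol: Adam with
learning rate $10^{-4}$, batch size 2, Dice/Jaccard/BCE selectable.
`augment_training_set()` expands each image–mask pair exactly fourfold —
itself, one 45° rotation, a horizontal and a vertical flip — with the
identical transform applied to image and mask (bilinear interpolation for
images, nearest-neighbor for masks so they stay binary, zero fill,
unchanged size). That multiplier is why a 400-image training fold becomes
1,600 images. `make_folds()` deals items into 5 stratified folds
(class-balanced within one item) for the usual 400/100 cross-validation
iterations at a 500-image cohort. Early stopping is made precise as:
patience of 5 epochs without a new best validation Dice, restoring the
best checkpoint — "stop when validation accuracy declines" needs exactly
this kind of operationalization to be reproducible. `train()` can also
stop once training Dice reaches a target (`stop_dice`), which is how the
test suite keeps CPU training short on separable synthetic data.
Grayscale inputs are replicated to three channels to fit the RGB encoder
stem. Prediction binarizes at 0.5 with ties assigned to foreground.

## The synthetic phantom generator

`generate_sac()` rasterizes a rotated ellipse (pixel centers strictly
inside the boundary; no anti-aliasing, so masks are exactly binary) with
an optional smooth radial perturbation — harmonics 2–4 with seeded random
phases, amplitude up to 0.3 of the radius — standing in for the irregular
contours of abnormal sacs. Ground truth is analytic: the unperturbed
ellipse's minimum-area rectangle has sides $2a \times 2b$ in pixels, so
truth diameters and the implied GA are known exactly, which is what makes
end-to-end recovery testable. `render_us_image()` adds the appearance
cues that make a sac recognizable on B-mode — anechoic (dark) lumen,
echogenic (bright) rim, mid-gray background, multiplicative Rayleigh
speckle — and nothing else: no beam physics, no attenuation, no shadowing,
no yolk sac or embryo. Passing tests on these phantoms demonstrates that
the measurement chain and training loop are correct, not that any model
generalizes to clinical scans.

`generate_dataset()` draws cohorts whose implied GA is uniform on 4–10
weeks by inverting the Hellman formula ($MSD = 0.7\,GW - 2.543$ cm),
splits the diameter by an aspect ratio in 0.65–1, orients uniformly in
0–180°, and samples pixel spacing in 0.1–0.5 mm/px constrained so the sac
fits the 512×512 frame with margin; abnormal cases (default fraction
226/500) receive irregularity amplitudes in 0.05–0.2 and the
transvaginal/transabdominal label mix defaults to 195/500. Everything is
reproducible from one integer seed, including the per-case perturbations.

## Problem sizes in the test suite

The suite exercises the full-size configuration where it matters (512×512
phantoms for recovery tests, the 500-item fold protocol, 400→1,600
augmentation) and scales down where only correctness of mechanism is at
stake: gradient checks on 8×8 inputs, forward contracts at 64×64, and the
CPU training check on 20 rendered 128×128 phantoms, where the resunet
reaches training Dice above 0.8 within a few epochs. These sizes are the
package's choices for a reasonable default test run; all entry points
accept full-sized inputs.

## Known limitations

* The biometry is 2-D: it measures the two in-plane diameters of one
  standard plane, not a three-diameter mean from orthogonal views.
* The Hellman formula is a fixed linear calibration; no alternative GA
  curves are provided.
* The DICOM support is deliberately minimal (uncompressed little-endian,
  single frame, PixelSpacing and pixel data) — fixtures and round-trips,
  not clinical archives.
* The training loop is desk-scale: it is exact, deterministic and tested,
  but CPU-bound; it demonstrates the protocol rather than replacing
  GPU-scale experiments.
* Phantom realism is limited as described above; agreement statistics on
  phantoms quantify the measurement chain, not sonographer variability.
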