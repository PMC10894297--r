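---
title: "Hybrid retinal vessel segmentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid retinal vessel segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the approach

Blood vessels in fundus photographs are thin, dark, branching curvilinear
structures on a brighter, vignetted background, best contrasted in the green
channel. `vesselseg` segments them with a three-phase pipeline:

1. **Enhancement (classical front end).** The vessel channel is z-score
   normalized, then three complementary per-pixel descriptors are computed:
   the maximum response of a matched-filter bank, a Hessian-eigenvalue
   multi-scale line-detection (vesselness) score, and a Gaussian scale-space
   stack. Together with the normalized image these form an `H x W x C`
   feature stack.
2. **Segmentation (learned back end).** A compact U-Net with residual
   double-convolution blocks maps the feature stack to a per-pixel vessel
   probability `V(i,j)` in `[0,1]`.
3. **Post-processing.** The probability map is thresholded into a binary
   mask `B(i,j)` and refined morphologically (gap closing, speckle removal,
   hole filling).

The package evaluates segmentations with the standard confusion-based suite
(Jaccard, F1/Dice, recall = sensitivity, precision, accuracy, Cohen's kappa,
specificity), a rank-based AUC, and frames-per-second throughput.

## The pieces in detail

### Normalization

`normalize_image()` computes `(I - mu) / sigma` with the *population* mean
and standard deviation over the computation domain — by default the whole
frame, in the pipeline the circular field of view (FOV), so the uninformative
black border does not pollute the statistics. Constant images are rejected
(`sigma = 0` has no meaningful normalization). Pixels outside the domain are
set to 0, which is exactly the in-domain mean after normalization.

### Matched-filter bank

A vessel cross-section is well approximated by an inverted Gaussian trough.
Each kernel is `-exp(-x^2 / (2 sigma_w^2))` across the vessel, constant
along it over a support of `length` pixels, evaluated analytically in
rotated coordinates and then mean-subtracted so every kernel sums to zero
(zero response on flat regions). Defaults follow classic fundus
matched-filter practice: profile widths `sigma_w` of 1, 1.5 and 2 px, 12
orientations in 15-degree steps, support length 9 px — 36 kernels. The
response is the per-pixel maximum over the bank; ties go to the smallest
kernel index for determinism. Convolution is implemented as
cross-correlation with reflective boundary padding; since the profiles are
symmetric about the vessel axis, the distinction only fixes how orientation
labels read, and the 90-degree kernel is exactly the transpose of the
0-degree one.

### Hessian vesselness

Line detection uses the eigenvalues of the scale-normalized Hessian of the
Gaussian-smoothed, polarity-inverted image (vessels become bright ridges).
With `|lambda1| <= |lambda2|`, tubular structures show `lambda2` strongly
negative and `|lambda1|` small, giving

```
v = exp(-(lambda1/lambda2)^2 / (2 beta^2)) * (1 - exp(-(lambda1^2 + lambda2^2) / (2 c^2)))
```

and `v = 0` where `lambda2 >= 0`. `beta = 0.5` is the conventional blobness
weight; `c` is set per scale to half the maximal Hessian Frobenius norm over
the image, a self-scaling choice that keeps the structureness term
dimensionless. Scales default to 1, 1.5 and 2 px, matching the rendered
vessel half-widths; the reported map is the per-pixel maximum over scales.
Steerable-filter line detection would slot into the same interface but is
not implemented.

### Scale space

`scale_space()` applies separable Gaussian blurs (kernels truncated at 4
sigma, reflective boundaries) at sigmas 0, 1 and 2 by default; sigma 0 is an
exact copy. The blur is a proper averaging, so global maxima are
non-increasing and minima non-decreasing along the stack, and the semigroup
property `blur(sigma = 3) ~ blur(sqrt(5)) o blur(2)` holds to the kernel
truncation error.

### Feature stack

Each selected channel is min–max rescaled to `[0,1]` *within the FOV* and
zeroed outside, giving the network inputs on a common scale. The default
stack is `[normalized image, matched-filter max, vesselness max, 3
scale-space images]`, C = 6. Which channels feed the network is
configurable; the single-channel `"norm"` stack is the raw-image-only
baseline used in the package's own comparison study. How many channels a
hybrid front end should produce is genuinely open; the multi-channel stack
is this package's documented interpretation.

### Residual U-Net

The network is an encoder–decoder with skip connections: each level is a
double 3x3 convolution block with a residual shortcut (identity, or a 1x1
projection when channel counts differ), ReLU activations, 2x max-pooling
down and nearest-neighbour upsampling up, and a sigmoid 1x1 output head.
Defaults: depth 3 with 8 channels at the first level (8, 16, 32, bottleneck
64), patch size 64, batch 8, 20 epochs of 96 random patches,
Adam at 1e-3, BCE + soft-Dice loss computed over in-FOV pixels. The Dice
term addresses the vessel/background class imbalance without sampling
tricks. The engine is written in R: convolutions are im2col gathers plus
one BLAS matrix multiply, with hand-written backward passes verified
against numerical gradients in the test suite. This keeps the package
dependency-free at the cost of raw speed; the defaults are sized so that
the full 20-phantom study trains in a few minutes on one CPU core. Depth,
width, patch and loss are all configurable; no batch normalization is used
at this capacity.

Weight initialisation (He) and patch sampling derive from one seed, so
training is bit-reproducible on a fixed platform; cross-platform BLAS
differences may cause float-level drift.

### Threshold calibration

The sigmoid output need not be calibrated so that 0.5 is the Dice-optimal
operating point; richer input stacks in particular tend to sit high and
over-segment at a fixed cut. After training, the pipeline selects the
operating threshold by maximising mean Dice over (up to 10) training
samples, evaluated through the same post-processing chain used at
deployment. This uses no test data and is applied identically to any input
variant. It can be disabled (`eval$calibrate_threshold = FALSE`), reverting
to the fixed `postproc$threshold`.

### Post-processing

`B(i,j) = 1` iff `V(i,j) >= t`, inclusive, so exact-threshold outputs are
deterministic. Refinement then runs, in order: morphological closing with a
discrete disc (radius 1 by default; the radius-1 disc is a plus shape —
`EBImage::makeBrush(3, "disc")` would give a full 3x3 box, which is harsher
on thin structures), removal of foreground components smaller than 30 px,
and filling of enclosed background holes smaller than 20 px, under
8-connectivity. All steps are deterministic and the composite is idempotent.
Closing is a gap-filler: on an exact, jagged ground-truth mask it
necessarily adds boundary pixels, so pure denoising behaviour is assessed
in the tests with closing off, while the default keeps radius 1 because
network probability maps are smooth and benefit from bridging. The phase
order (threshold before morphology) is itself configurable
(`order = "morph_then_threshold"` applies grayscale closing to `V` first),
since the two readings of "refine the segmentation output, then threshold"
are both defensible.

### Metrics

All counts are taken over in-FOV pixels when a FOV mask exists (the DRIVE
convention); `--no-fov` evaluates full frame. Ratios with zero denominators
are reported as flagged `NaN` rather than silently 0 or 1, and aggregation
excludes them per metric while reporting how many samples contributed.
Recall and sensitivity are the same quantity and are stored once. AUC is the
rank statistic (ties count one half), identical to the trapezoidal ROC area,
and is cross-checked against an independent implementation in the tests.

## The phantom study

Real fundus datasets cannot be bundled, so the package generates seeded
synthetic phantoms with exact ground truth: correlated random walks grow a
branching vessel tree inward from the FOV rim (child width = parent width
x 0.8 per generation), rendered as smooth Gaussian-profile intensity
troughs (peak contrast 0.45) on a radially vignetted background (level
0.75, 30% rim darkening) with additive Gaussian pixel noise (sigma 0.03)
inside a circular FOV, at 128 x 128 px. Default densities land at roughly
10–20% vessel pixels per FOV, comparable to real fundus vasculature. The
rendered cross-section is Gaussian while the matched filter assumes the
same family — deliberately similar but not identical to the binarized
ground truth geometry, so the front end is informative without being tested
against its own kernel.

What phantoms do not emulate: pathology (exudates, hemorrhages), the optic
disc, colour response, JPEG artefacts, inter-image illumination variation,
and expert-annotation ambiguity. Passing the phantom study therefore shows
the pipeline's machinery is correct and that enhancement carries signal; it
does not certify clinical performance on real images.

The package's own study conditions are 20 training + 5 test phantoms at
128 x 128 — small enough to train the pure-R network in minutes, large
enough that held-out Dice is a meaningful recovery statistic. Under these
conditions the hybrid stack reaches mean test Dice above 0.9 and AUC above
0.99, and its advantage over the raw-image-only baseline is small (well
below 0.01 Dice): clean phantoms are learnable from raw intensity alone,
so the margin — clearest in AUC and in early-epoch convergence,
threshold-sensitive in Dice — is the honest phantom-scale restatement of
the claim that classical enhancement helps the network.

## Numerical choices and degenerate inputs

- Boundary handling is reflective everywhere (filters, blurs, Hessians).
- Max-response ties (filter index, scale index) resolve to the smallest
  index.
- Images constant over the normalization domain raise an error naming the
  cause; empty filter banks, non-odd kernel supports, negative scales, and
  thresholds outside (0,1) are rejected at the interface.
- All generator and training randomness flows from named substreams of one
  seed; package functions never touch the caller's RNG stream.
- Probability maps are written as 16-bit TIFF and quantised in memory
  before thresholding, so the stored `V`, the stored `B`, and in-memory
  decisions agree exactly.

## Known limitations

- The pure-R network engine is single-threaded and unsuited to training at
  full fundus resolution; on real datasets one would raise depth/width and
  expect hours, not minutes, per run.
- Steerable-filter line detection and CLAHE-style illumination correction
  are not implemented.
- STARE-style layouts require an explicit split file; the package refuses
  to invent a train/test split silently.
- The sensitivity/specificity row-labelling discrepancy present in some
  published benchmark tables cannot be reproduced from the stated formulas;
  this package stores one recall (= sensitivity) value.
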