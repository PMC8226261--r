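---
title: "Joint vessel segmentation and artery/vein classification with a vessel-constraint network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint vessel segmentation and artery/vein classification with a vessel-constraint network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Pixel-wise artery/vein (A/V) classification in colour fundus photographs is
dominated by two structural difficulties. First, class imbalance: vessels
cover roughly 15% of a fundus image, arteries and veins about 7.5% each, so
a naive per-pixel classifier is rewarded for predicting background. Second,
scale: vessel calibers span an order of magnitude from main trunks near the
optic disc to capillaries, and classification errors concentrate at vessel
edges and thin terminal branches — exactly the pixels whose vessel evidence
is ambiguous.

`retinav` implements a convolutional network that attacks both problems
jointly. A single U-shaped encoder/decoder produces two per-pixel outputs:
a vessel probability map (sigmoid head) and background/artery/vein class
probabilities (softmax head). Two architectural devices carry the method:

* **Multi-scale feature (MSF) blocks** in the encoder. After a 1x1
  convolution the channels are split into `k` subsets `x_1..x_k`; the
  outputs are `y_1 = x_1`, `y_2 = F_2(x_2)`, and `y_i = F_i(x_i + y_{i-1})`
  for `i > 2`, each `F_i` a 3x3 convolution (with batch normalization and
  ReLU). Subset `i` has passed through `i - 1` stacked 3x3 kernels, so one
  block mixes receptive fields from 3x3 up to `(2k - 1)`-sized, matching
  the caliber spread of retinal vessels. The concatenated subsets pass
  through a closing 1x1 convolution and a residual connection from the
  block input.

* **The vessel-constraint (VC) module.** The vessel head's probability map
  `x` is transformed by the Gaussian-bump activation

  `F(x) = alpha * (exp(-|x - 0.5|) - exp(-0.5)) + 1`

  and multiplied, broadcast across channels, onto the A/V feature maps
  immediately before the classifying 1x1 convolution. `F` equals 1 exactly
  at `x = 0` and `x = 1` and peaks at `x = 0.5` with value
  `alpha*(1 - exp(-0.5)) + 1`, so confident background and confident thick
  vessel are left untouched while ambiguous pixels — vessel boundaries and
  capillaries, where A/V errors concentrate — have their features
  amplified by up to ~1.39 (at `alpha = 1`). The same mechanism counters
  the background imbalance: background-prone features are relatively
  suppressed. `alpha` defaults to 1 and can be varied both at training time
  and, on a trained model, at prediction time (`predict_image(alpha = )`).

The training objective is the weighted sum

`Loss = gamma * L_av + delta * L_vessel + beta * ||W||^2`

with `gamma = 0.6`, `delta = 0.4` (`gamma + delta = 1`) and L2 coefficient
`beta = 2e-4`. `L_av` is the categorical cross-entropy over
background/artery/vein on FOV pixels whose ground truth is not UNCERTAIN;
`L_vessel` is the binary cross-entropy of the vessel head over all FOV
pixels, with UNCERTAIN pixels counted as vessel-positive (they are vessels
of unknown type). Both are means over pixels, so the loss is independent of
patch size. The printed A/V loss in the source material is binary in form;
since the task is explicitly three-class (background, artery, vein,
undecided), the categorical generalization is used — it reduces to the
binary form for two classes. `||W||^2` covers convolution kernels only, not
biases or normalization parameters; whether the original regularizer
included biases is unstated, so the narrower, conventional choice is made
and documented here.

## Where the weight map applies, and its gradient

The source architecture says only that the weight map "constrains" the A/V
features. This implementation multiplies the final decoder feature block of
the A/V branch — the last point at which per-pixel vessel evidence is
spatially aligned with A/V features — immediately before the 1x1 classifier
and softmax. `F` is differentiable except at `x = 0.5`, where the
subgradient 0 is used. By default gradients flow through the constraint
into the vessel branch (`vc_detach = FALSE`); setting `vc_detach = TRUE`
treats the weight map as a constant during backpropagation. In scaled-down
experiments on synthetic scenes the two settings were statistically
indistinguishable (both in accuracy and in failure modes), so the default
follows the end-to-end reading of the published training setup.

## Training procedure

Training follows the published schedule: random square patches (512x512 at
full scale), scaling and rotation augmentation, stochastic gradient descent
with momentum on a fixed iteration budget (4,000 at full scale), and an
initial learning rate of 0.001 halved every 1,500 iterations. One iteration
is one optimizer step on one batch. At inference the image is tiled into
ordered patches, each patch is forwarded, and the predictions are stitched;
overlapping pixels are averaged and the A/V distribution renormalized.
Binary vessel maps use a 0.5 threshold (ties count as vessel); A/V
decisions take the argmax of the artery and vein probabilities only, over
the evaluation domain (all ground-truth A/V pixels by default — the
stricter convention — or the predicted vessel mask behind a flag), with
ties going to artery.

Values the source leaves unstated, fixed here once:

* momentum 0.9; batch size 2 at full scale;
* augmentation scales {0.8, 1.0, 1.2} and rotation angles 0°–345° in 15°
  steps, applied jointly to image (bilinear), labels and validity
  (nearest-neighbour), with rotated-in regions marked invalid;
* reflection padding for patch tiling and for images smaller than the
  patch;
* test-time stride defaults to half the patch (overlap averaging
  suppresses border artifacts); stride = patch size reproduces the minimal
  ordered tiling;
* multi-dataset fusion (`fuse_datasets()`) concatenates and shuffles train
  entries at native resolution — patch sampling makes mixed resolutions
  compatible, so no global resizing is applied.

## The tiny preset

The package ships a documented CPU-scale preset used throughout its tests:
`tiny_model_config()` (base 8 channels, depth 3, k = 4) and
`tiny_train_config()` (128x128 patches, batch 2, 1,000 iterations, initial
rate 0.01). The preset keeps every architectural and procedural component
of the full-scale configuration — MSF blocks, VC module, both heads, the
stepped decay, momentum, augmentation — while shrinking capacity and budget
so that a complete train/evaluate cycle runs in minutes on one CPU core.
The higher initial rate compensates for the much shorter schedule and
smaller batches; the decay step is scaled with the budget for the same
reason.

## The synthetic scene generator

`render_scene()` builds a fundus-like scene from a seeded specification:
a circular field of view on black background, binary branching vessel trees
rooted on the FOV boundary and growing inward with per-step heading jitter,
calibers decaying geometrically along the hierarchy (floored at 1 px),
smooth background drift, radial vignetting, and Gaussian pixel noise.
Arteries render brighter red, slightly thinner, and with a central reflex
(the bright midline stripe of real arteries); veins render darker and
wider; overlapping artery/vein tubes are labelled UNCERTAIN, mirroring the
crossing convention of real A/V ground truth. Default geometry targets the
real class balance: vessels average ≈13–15% of the FOV with arteries and
veins within a factor of two of each other.

What the generator deliberately does **not** model: optic disc and macula,
pathology (lesions, hemorrhages), choroidal texture, camera vignetting
profiles, or inter-device colour variation. Consequently, synthetic
A/V discrimination is a local-appearance task that is easier than the real
one; passing the package's training checks demonstrates that the
architecture, losses, optimizer and evaluation chain are correct and that
the VC module does not impair learning — it does not certify benchmark
accuracy on real fundus datasets, which requires the original data and
full-scale training.

## FOV masks

Some datasets ship hand-made field-of-view masks; where none exists,
`compute_fov_mask()` builds one by thresholding the mean-RGB luminance
(default 0.06), keeping the largest connected component above a minimum
area (default 1% of the image), and filling holes. This is a deliberately
simple, documented pipeline — published FOV masks are produced by a
variety of unspecified procedures, so the package makes no claim of
matching any particular one; the defaults recover the illuminated disc of
both synthetic scenes and typical fundus photographs, and the mask can
always be supplied explicitly through the manifest instead.

## Numerical choices and degenerate inputs

* Probabilities are clipped to `[1e-7, 1 - 1e-7]` inside both losses.
* Batch normalization uses eps 1e-5 and running-statistics momentum 0.1;
  inference uses running statistics.
* AUC is computed by threshold sweep with tied scores collapsed onto one
  ROC vertex and trapezoid accumulation — algebraically the Mann–Whitney
  pair statistic with ties counted 1/2. Metrics with empty denominators
  (e.g. AUC with single-class truth) are reported `NA`, never 0.
* Degenerate batches (no valid pixels) and images with no FOV-sized bright
  component raise errors rather than returning silent zeros.
* Weight init is He-normal fan-in, seeded; training, generation and
  prediction are bitwise reproducible given their seeds, with all
  randomness derived from named substreams of one master seed.

## Decoder design and the input skip

The exact decoder schedule of the original architecture is not published,
so the decoder here is the package's own design: at each level, 2x
bilinear upsampling, a 1x1 channel-reducing convolution, concatenation
with the encoder skip, and one fusing 3x3 convolution (all with batch
norm + ReLU). Both output heads read the fused full-resolution features
*concatenated with the raw input image* — a full-resolution input skip.

The input skip earns its place empirically. Without it, a minority of
training seeds at CPU scale converge to a "vesselness-only" local
minimum: the vessel head is excellent (AUC > 0.99) but the A/V head
leaves artery and vein logits almost tied, and probing the trained
network with flat artery-coloured versus vein-coloured patches shows its
output has become essentially colour-blind — the shared trunk features
have specialized for vessel geometry and no longer carry the colour
contrast the A/V decision needs. Detaching the vessel-constraint gradient
does not change this failure mode, and neither does the learning-rate
schedule, which is why the remedy is architectural: concatenating the raw
RGB directly before the heads guarantees per-pixel colour evidence
reaches the A/V classifier at every stage of training. With the skip the
plateau is not observed across seeds. At full scale the published
training schedule is used unchanged.

## Evaluation conventions

All metrics are restricted to FOV pixels. Vessel metrics (ACC/SE/SP/F1 at
threshold 0.5, AUC on continuous probabilities) score the binary vessel
map; A/V metrics score artery-as-positive/vein-as-negative counts on
ground-truth A/V pixels: SE_AV, SP_AV, BACC = (SE_AV + SP_AV)/2, and
per-class F1. Published per-dataset numbers do not state whether pixels
are pooled across test images or per-image metrics averaged; the package
reports both (`macro` is the headline; `pooled` accompanies it). UNCERTAIN
ground truth is excluded from A/V scoring and counted vessel-positive for
segmentation by default (`strict_uncertain = TRUE` removes it from the
vessel truth too). Reports round to 4 decimals for display only; JSON
output keeps full precision.

## Known limitations

* The encoder is trained from scratch; externally pretrained encoder
  weights can be loaded through checkpoints but no pretrained model is
  bundled or downloaded.
* Compute: the network is dense per-pixel; full-scale training (512²
  patches, 4,000 iterations) is feasible but slow on one CPU. The tiny
  preset exists precisely to keep the method testable at interactive
  speed.
* The synthetic generator's simplifications above mean synthetic scores
  overstate real-data performance by construction.
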