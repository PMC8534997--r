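---
title: "Markerless gait-type classification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markerless gait-type classification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gaitkit)
```

## The problem

Several neurological and musculoskeletal conditions alter the way people
walk. Five clinically recognizable gait types anchor this package: *scissor*
gait (associated with diplegia), *spastic* gait (hemiplegia), *steppage*
gait (peripheral neuropathy with foot drop), *propulsive* gait (Parkinson's
disease) and *normal* gait. gaitkit classifies which of these five a person
exhibits from nothing more than a sagittal-view 2D video recorded against a
uniform chroma background, making the analysis deployable with a phone
camera and a remote server rather than a marker-based motion-capture
laboratory.

The pipeline is appearance-based: video frames are segmented into binary
silhouettes, silhouettes are condensed into a single grayscale *Gait Energy
Image* (GEI), and a compact convolutional network maps that image to class
probabilities. A parallel route rasterizes per-frame body keypoints
(OpenPose BODY_25 convention) into skeleton images and averages them into a
*Skeleton Energy Image* (SEI) that emphasizes movement over body shape.

## The gait energy image

Given $N$ cropped, height-normalized, horizontally aligned binary
silhouettes $B_i(x, y)$ covering one gait cycle (or a whole sequence), the
energy image is the pixel-wise mean

$$\mathrm{GEI}(x, y) = \frac{1}{N} \sum_{i=1}^{N} B_i(x, y).$$

Static body parts (head, trunk) appear near-white; moving parts (legs,
arms) trace gray motion envelopes whose shape is characteristic of the gait
type. `compute_energy_image()` implements exactly this mean and is tested
against an independent brute-force per-pixel oracle; the SEI is the same
code path applied to `rasterize_skeleton()` output.

Normalization (`normalize_silhouette()`) crops the silhouette's bounding
box, scales it so the box height is 224 while preserving aspect ratio,
binarizes again at 0.5 after bilinear resampling, and pastes it on a
224 × 224 canvas with the silhouette's column centroid at column 112,
clipping any horizontal overflow. Degenerate masks (e.g. a single pixel)
scale to the full canvas under the same aspect-preserving rule. The
whole-silhouette centroid was chosen as the alignment anchor over
alternatives such as the torso-only centroid; it is simple, deterministic
and stable on both silhouettes and skeletons.

## Silhouette segmentation

Segmentation exploits the chroma backdrop. A background-only frame is
converted to HSV and each channel's histogram summarized by a valid
interval: the [1st, 99th] percentile range widened by 25% of its width
(with a 0.002 absolute floor), the hue handled circularly around its
circular mean. The widening matters: a bare 98%-mass interval would
misclassify about 2% of background noise as foreground speckle. A pixel is
foreground when its **hue** falls outside the hue interval, *or* when both
its saturation and value do — hue separates anything colorful from the
green screen, while the S/V clause catches gray and desaturated clothing
whose hue is numerically unstable. The raw mask is cleaned by morphological
opening then closing with a 5 × 5 elliptical element, and only the largest
connected component is kept (a single walking subject is assumed). On
synthetic chroma sequences this recovers silhouettes at IoU ≥ 0.95 against
ground truth.

## Gait-cycle detection

The bounding-box width of the silhouette oscillates twice per gait cycle —
once per step, as the legs pass each other. `detect_gait_cycles()` smooths
the width signal with a 3-frame moving average (at the canonical 10 fps),
finds local minima, merges minima closer than 3 frames, and takes
*alternate* minima as cycle boundaries so a cycle spans two strides. A
constant signal yields an explicit "no cycle" result. On simulated walkers
with known 14- and 20-frame periods the detected lengths are within ±1
frame.

## The classifier

The network is deliberately small: five 3 × 3 convolutions with stride 2
("same" padding), widths 32, 32, 32, 64, 64, each followed by batch
normalization and a rectified-linear activation; then a 512-unit dense
layer, dropout 0.5, and a 5-way softmax. The grayscale energy image is
replicated across 3 input channels. Spatial sizes halve per layer
(224 → 112 → 56 → 28 → 14 → 7), so the flattened feature length is
7·7·64 = 3136 and the total parameter count — counting the two
normalization statistics per channel alongside scale and shift — is exactly
1,684,421. That total is pinned by a test: counting only trainable values,
using one input channel, or using valid padding all break it, which is how
the three otherwise-open architecture choices were fixed.

Training minimizes categorical cross entropy with the Nesterov-Adam
optimizer (learning rate 0.001, moment decays 0.9/0.999). Defaults are 50
epochs, batch size 32, and early stopping on a stratified validation split
with patience 10; all are configurable, and the reduced-scale experiments
in the test suite use 6–10 epochs, which the well-separated synthetic
classes need. The rectifier placement (after normalization) follows the
VGG-style lineage of such networks.

Two numerical choices deserve a note:

* **Normalization statistics.** The moving mean/variance used at inference
  are zero-initialized exponential averages (momentum 0.9) debiased by
  $1 - m^t$, exactly as Adam debiases its moment estimates. Without the
  correction, a model trained for only tens of steps carries moving
  statistics dominated by their initialization: inference accuracy
  collapses — and early stopping, which monitors inference-mode validation
  loss, can fire during that transient and restore useless early-epoch
  weights. The debiased estimates are unbiased from the first update step,
  so validation curves are meaningful from epoch one.
* **Convolution biases.** In front of batch normalization a convolution
  bias is mathematically inert (the normalization subtracts any constant
  shift, and its gradient is identically zero). The biases are kept as
  parameters — they are part of the stored model and of the parameter
  count — but the forward pass skips adding them while they are zero,
  saving a full memory pass per layer.

The engine itself (im2col convolution, fused batch-norm/ReLU, dense,
dropout, softmax) is implemented in the package with the two hot loops in
C++; gradients of every layer are verified against central finite
differences in the test suite, away from the rectifier's kink where the
one-sided numerical derivative is undefined.

## Evaluation protocol

Evaluation is subject-wise: the test set of fold $k$ is the 3-subject
window $V_k = \{S_{2k-1}, S_{2k}, S_{2k+1}\}$ over the ordered subject
list, so 10 folds cover 21 subjects with every subject tested at least
once; consecutive folds overlap by one subject, and per-fold accuracies are
averaged unweighted. Train and test subjects are asserted disjoint on
every fold. Reports carry a 5 × 5 row-percentage confusion matrix in the
canonical class order (scissor, spastic, steppage, normal, propulsive);
rows without support are reported as undefined rather than zero. Scoring is
sequence-level — a sequence's label is the argmax over its whole-sequence
representation — with per-cycle representations available for analyses
that want them. Cross-dataset evaluation trains once on one domain and
tests on another whose labels map 1-to-1 onto the gait types
(diplegic ↔ scissor, hemiplegic ↔ spastic, neuropathic ↔ steppage,
Parkinsonian ↔ propulsive, healthy ↔ normal).

## Explanations

Both diagnostic maps differentiate the *pre-softmax* class score, the
standard choice that makes maps invariant to a constant shift of all class
scores. The saliency map is the per-pixel gradient magnitude, max-reduced
over the replicated input channels and rescaled to [0, 1] (an identically
zero map is left at zero). Grad-CAM weighs a convolutional layer's
activation channels by their spatially averaged gradients, clips negative
evidence, upsamples to the input size and rescales; the last (fifth)
convolutional layer is the default, offering the best trade-off between
semantic depth and spatial resolution at 7 × 7. Feature-map dumps expose
each layer's activations at their native sizes (112/56/28/14/7).

## The synthetic walker

Because the real studio datasets are external downloads, the package ships
a procedural stand-in that makes every stage testable. A 2D stick figure —
15 animated keypoints mapped onto the BODY_25 index set, with facial and foot
detail points emitted at confidence 0 — walks across a saturated-green
background (hue at one third of the hue circle, small per-pixel noise).
Joint angles follow a sinusoidal base gait; limbs are rendered as thick
capsules (stroke ≈ 6% of figure height) plus head and trunk ellipses so
silhouettes are single plausible blobs. The truth mask *is* the rendered
support, and pose confidences are drawn in [0.6, 1].

Each gait type perturbs the base gait the way the clinical descriptions
read: scissor adds forward trunk lean, shortened steps, stiffened knees and
a circular sweep of both legs; spastic applies the circular sweep to the
right leg only and freezes the right arm (held at the waist at severity 1,
flexed against the chest at severity 2); steppage multiplies knee flexion
and adds foot drop; propulsive stoops the trunk, halves step length,
doubles cadence, holds both arms to the chest and adds per-joint jitter.
Severity 2 scales every deviation parameter by a single documented factor
of 1.6 — the severity contrast is described only qualitatively in the
clinical protocol, and one constant keeps the classes separable yet
overlapping. A small left/right knee asymmetry (factor 0.88) makes the
full cycle, not the half cycle, the fundamental period of the width
signal, as in real gait. For the propulsive type the cadence doubling
halves the effective gait period relative to the configured
`frames_per_cycle`.

The default study conditions mirror a studio capture protocol: 10 fps, a
20-frame (2 s) cycle, 224 × 224 representations, and a session layout of
9 conditions × 2 directions × 2 repetitions = 36 sequences per session —
hence 23 sessions total 828 sequences, with sessions 22 and 23 revisiting
earlier subjects (21 distinct subjects). The labelled training sets used by
the tests draw per-sequence cycle periods from 16–24 frames, body scales
from 0.92–1.08, both directions (canonicalized before averaging) and both
severities, at 2 cycles per sequence — sizes chosen so the full class-recovery
experiment (5 classes × 40 sequences, three training seeds plus a
label-permutation null) completes in minutes on a single CPU.

The test suite pairs the class-recovery check with a label-permutation
null: classifiers trained on permuted labels should perform at the 20%
chance level. The null is scored as the *expected* accuracy under the
predicted class probabilities rather than argmax accuracy: a model fit to
permuted labels maps each appearance cluster to one arbitrary class, so
its argmax accuracy is quantized in steps of 1/5 and a single run
fluctuates wildly around chance, while the probability-weighted score
retains the concentration a binomial chance analysis assumes. Two
independent permutations are averaged.

What the simulator does *not* model is as important as what it does: there
is no clothing texture, occlusion, shadow, camera shake, perspective
foreshortening or pose-estimation error, and the biomechanics are
qualitative caricatures rather than patient kinematics. Passing the
synthetic class-recovery check therefore demonstrates that the pipeline is
wired correctly and that the representations carry the intended signal — it
does not certify clinical accuracy on real video, which requires the real
capture datasets.

## Known limitations

* Single subject per frame; multi-person scenes are out of scope (the pose
  reader keeps the highest-confidence person, the segmenter the largest
  component).
* The chroma-key segmenter assumes a near-uniform colored backdrop; general
  background subtraction is not attempted.
* Cycle detection assumes a roughly steady walking pace over at least
  about 1.5 periods.
* Training the full-resolution network on a CPU is feasible for the
  reduced experiment sizes used here (seconds per batch) but not for
  dataset-scale training, where hours-long schedules would be required.
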