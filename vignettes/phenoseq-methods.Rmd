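---
title: "Classifying rosette growth sequences: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying rosette growth sequences: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

phenoseq classifies top-view time-lapse sequences of rosette plants (one
frame per day) into genotype classes — accessions — from image-derived
phenotypes. The interesting scientific signal is *temporal*: accessions that
look alike in any single frame can differ in how fast they add and expand
leaves. The package therefore implements and compares five systems on the
same data: per-frame hand-crafted features with an SVM and frame voting;
the same features fed to an LSTM; a per-frame CNN with frame voting; the
CNN's deep features aggregated by a linear-chain CRF; and the CNN's deep
features modelled by a stacked LSTM.

## Segmentation

A frame is converted to L\*a\*b\*; green tissue separates from brown soil in
the a\* (low side) and b\* (high side) chromatic channels. Each channel is
binarised with Otsu's method (implemented over a 256-bin histogram of the
channel rescaled to its own range; ties break to the smallest level). The
binary mask is dilated with a disc (radius 5 px at a 256 px image, scaled
proportionally) and added to itself, giving a three-level mask per channel —
0 definite background, 1 the dilation ring (probable), 2 the core — whose
ring protects leaf borders that fade into the soil. The two trinary masks
combine element-wise into the four-level GrabCut seed (0 definite background,
1 definite foreground, 2 probable background, 3 probable foreground): both
cores agree → definite foreground; both zeros → definite background; a core
on either side → probable foreground; remaining 0/1 mixtures → probable
background.

GrabCut then alternates, with the bounding box fixed to the whole image:
5-component full-covariance Gaussian mixtures (k-means initialised, fixed
internal seed) model foreground and background colour; a grid graph with
contrast-weighted 8-neighbour links (`gamma = 50`, `beta` set to the inverse
of twice the mean squared neighbour difference) and likelihood terminal links
is cut by max-flow (igraph); five alternations by default. Definite seed
cells are hard terminal constraints and can never flip, also not during the
final morphological opening-then-closing (disc radius 2 at 256 px).

Two numerical choices deal with degenerate frames. A constant channel has a
single occupied histogram bin; it carries no foreground evidence. And on a
plant-free frame Otsu still splits the soil noise somewhere, so each channel
is gated on the separation of its two Otsu class means in native Lab units
(`min_contrast = 8`): real soil/vegetation contrast in a\* is tens of units,
soil-internal splits are a few. Below the gate the channel yields an
all-background trinary mask, and a seed without foreground evidence gives an
empty plant mask. The same gate makes very small seedlings (below roughly
half a percent of the frame) register as absent; the feature table encodes
such frames as all-zero rows, a documented "plant absent" code that keeps
sequences rectangular.

## Hand-crafted descriptors

Per segmented frame, 1056 numbers in a fixed layout: 12 colour statistics
(mean/max/min of R, G, B over foreground pixels; mean H, S, V of the same
pixels), 8 shape statistics, 1024 Fourier contour components, 12 GLCM
texture statistics.

Shape follows the conventions stated with the battery: *roundness* is the
ratio area/perimeter (the conventional `4*pi*A/P^2` is available behind a
flag), *compactness* is area over convex-hull area (hull taken over pixel
corners so a filled rectangle scores exactly 1), *eccentricity* is the
hull's major/minor axis-length ratio (from the analytic second moments of
the hull polygon; always ≥ 1), the equivalent-ellipse axis lengths come from
the region's second moments, and *extent* is area over bounding-box area.
Perimeter is the traced boundary length of the region's outer contours
(unit and diagonal steps). A collinear region has a degenerate minor axis
and errors.

The Fourier descriptor resamples the outer contour of the largest connected
component to 512 points equally spaced in arc length, reads them as complex
coordinates, transforms, and zeroes the DC coefficient — the translation
carrier — leaving 512 real and 512 imaginary parts. 512 points is the only
resampling count consistent with the 1024-element layout. "Centre element"
is read as the DC term, since that is what carries translation.

GLCM statistics quantise foreground grey levels (Rec. 601 luminance) to 32
bins over the foreground range — the battery is thereby invariant to global
illumination shifts — and accumulate one distance-1 co-occurrence matrix per
direction (0°, 45°, 90°, 135°), counting only pairs with both pixels in the
mask, symmetrised and normalised. Energy, Contrast and Homogeneity are read
off each. 32 levels keeps the matrices dense at rosette sizes; the count is
configurable.

## Deep features and sequence models

Plants change size drastically over a sequence, so a genotype's frames are
a visually incoherent class. Before CNN training each genotype is split
into five sub-classes by the 20/40/60/80% quantiles of segmented plant area
(inverse-ECDF quantiles; ties to the lower bin), and the network is trained
on L×5 flat labels. The training set is quadrupled by rotating every frame
90°, 180° and 270° about its centre — top-view pot orientation is arbitrary,
so rotations are label-preserving.

The per-frame network is deliberately small: three blocks of 3×3
convolution + ReLU + 2×2 max-pooling with 16/32/64 maps, a dense layer of
128 units (the deep features), and a softmax head. Frames are resized to
32×32 and normalised per channel with training-set statistics; 32 px keeps
single-CPU training practical while preserving the rosette-scale cues
(arrangement, size, hue) the sub-class problem needs. Training is SGD with
mini-batches of 32, learning rate 0.001, momentum 0.9, weight decay 1e-6;
initialisation is He-scaled and fully seeded. Epochs are configurable; the
default (16) is set where the training-loss curve plateaus on the bundled
benchmark. The forward/backward passes are exact (verified against finite
differences); convolution is im2col + BLAS, and the input gradient is the
transposed convolution of the upstream gradient.

The sequence classifier implements the standard LSTM recurrences exactly —
input, forget and output gates squashing affine maps of `(x_t, h_{t-1})`,
a tanh candidate, `c_t = f⊙c_{t-1} + i⊙g`, `h_t = o⊙tanh(c_t)` — as both
didactic single-step functions (`rnn_step()`, `lstm_step()`, tested against
scalar brute-force evaluation) and a batched two-layer network trained by
full backpropagation through time (tested against finite differences and
against iterated `lstm_step()`). Layer 2 consumes layer 1's hidden states;
both layers use 256 hidden units. Class scores are read out at the final
step — the simplest readout that uses the entire sequence — with per-step
averaging behind a flag. SGD uses mini-batches of 32, learning rate 0.01,
momentum 0.9, weight decay 0.005; forget-gate biases start at +1; features
are z-scored with training statistics (the hand-crafted battery spans six
orders of magnitude). Default 40 epochs, again a loss-plateau choice.

Two baselines complete the comparison. The SVM baseline standardises
per-frame hand-crafted features (dropping constant columns), fits a
radial-basis SVM, and labels a plant by majority vote over its frames (ties
to the lowest class index). The CRF baseline is a linear-chain model over a
plant's frames in which all frames share one label — the natural reduction
of sequence-labelling CRFs to sequence classification: per-frame unaries are
a linear map of deep features, an L×L transition matrix rewards
persistence, and the shared-label path score of class y is
`sum_t u_t(y) + (T-1) A[y,y]`. Maximum likelihood is convex here and solved
by BFGS with a small L2 penalty. Note what this model can and cannot do: it
aggregates per-frame evidence in a learned, soft way (hence it should beat
hard frame voting) but its score is invariant to frame order, so it cannot
exploit growth dynamics — exactly the contrast with the LSTM the comparison
is meant to expose.

Train/test splits are always stratified by plant; a guard trips if any
plant's frames appear on both sides. The benchmark protocol is a single
75/25 plant split; 5-fold stratified cross-validation is available where a
protocol with pooled predictions is preferred.

## The synthetic generator

No chamber imagery ships with the package; a generator stands in for it.
Each accession is a parameter bundle: a non-decreasing leaf-addition
schedule, a leaf expansion rate (px/day at a 256 px reference canvas,
scaled with the canvas), a leaf length/width aspect, a hue centre and
jitter, and a phyllotactic angle. A plant draws one random stream from its
seed: soil texture (low-frequency brown noise plus speckle), a whole-rosette
rotation uniform on [0°, 360°), a germination offset uniform on {0,1,2,3}
days, per-leaf angle and length jitter, a plant-level hue offset, and a
foreground value-noise field that gives leaves GLCM-visible texture. Leaves
are rotated filled ellipses whose base touches the rosette centre — the
simplest shape family that exposes the area, aspect and arrangement
phenotypes the descriptors measure. Because the stream is drawn
independently of the day, a plant is consistent across its sequence and a
dataset reproduces byte-for-byte from its seed.

The default four-accession panel is the benchmark's study condition, fixed
in advance of any measurement. Classes 1–2 ("dyn-fast", "dyn-slow") share
every static parameter and differ only in dynamics, with schedules chosen so
that a fast plant at day t resembles a slow plant at day ~1.6t in both area
and leaf count — a per-frame observer cannot tell a young fast plant from an
older slow one, while a sequence observer sees the rate directly. Classes
3–4 differ from the pair and from each other mainly in phyllotaxy (137.5°,
90°, 72°) with subtle aspect (2.6/2.6/2.2/3.0) and hue offsets (95/95/103/87,
per-plant jitter sd 6°) that overlap across plants. This difficulty
structure mirrors the real problem: accessions are all green rosettes;
colour and outline statistics are noisy cues, arrangement and dynamics the
informative ones. The random whole-plant rotation specifically handicaps
raw contour coordinates (the Fourier block) while the CNN sees arrangement
through rotation augmentation. An `easy_accession_panel()` with strongly
separated hue, shape and dynamics serves segmentation fixtures and sanity
checks.

What the generator does *not* emulate: leaf occlusion and self-shadowing,
perspective and lens distortion, colour-card drift (though
`color_correct()` implements the affine card correction real images would
use), moss/algae on soil, and between-day lighting changes. Passing the
bundled benchmarks therefore demonstrates that the pipeline's machinery and
its temporal contrasts behave as designed, not that these accuracies
transfer to chamber imagery.

## Problem sizes and defaults

The bundled benchmark runs 4 classes × 20 plants × 22 daily frames at a
128 px canvas with ground-truth masks (segmentation quality is scored by its
own 40-frame IoU benchmark at the same canvas), a 75/25 plant split, CNN as
above, LSTM with 256 hidden units. The dynamics-only contrast
(`temporal_contrast()`) uses the class 1–2 pair at the same sizes and
compares CNN frame voting with the CNN-LSTM. These sizes were chosen so a
full five-variant comparison runs on a laptop-class single CPU in minutes;
all of them are configuration, not constants.

## Known limitations

A per-frame classifier aggregated by majority vote cannot resolve the
dynamics-only accession pair: that is the point of the pair's construction,
and it costs the CNN variant the whole of one class on the bundled
benchmark. On real chamber imagery, deep features tend to dominate
hand-crafted descriptors by a wide margin; on clean synthetic renders the
hand-crafted battery reads the generative parameters almost noiselessly, so
the gap between the CNN variant and the hand-crafted+LSTM baseline is much
narrower here than on real data — the two can even swap places. The
temporal contrasts (sequence model vs frame voting) are the robust part of
the comparison.

Segmentation assumes one plant per frame and green-on-brown contrast; the
minimum-contrast gate makes sub-0.5%-of-frame seedlings read as absent.
The CRF's shared-label reduction discards frame order by construction.
Stage outputs inside one experiment run are computed once and shared across
variants, but runs do not resume from disk-cached intermediates. The
`alexnet-finetune` backbone hook is intentionally not provided: pretrained
ImageNet weights cannot ship with the package, and the small network
preserves the method at this scale.
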