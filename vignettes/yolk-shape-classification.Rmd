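---
title: "Identifying double-yolked duck eggs from candling images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying double-yolked duck eggs from candling images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyegg)
```

## The problem

Double-yolked (DY) duck eggs fail to hatch and are removed before
incubation in hatcheries, while egg producers pick them out for sale at a
premium. The traditional detection method is candling: a bright light is
shone through the egg and the yolks cast visible shadows. In a
transmittance image of a single-yolked (SY) egg the yolk shadow is roughly
circular; in a DY egg the two overlapping yolk shadows form an "8". This
package automates the distinction with two classifiers that share one
image-preprocessing front end:

* an interpretable route — segment the yolk shadow, trace its boundary,
  summarize the boundary shape with normalized Fourier descriptors (NFDs),
  and classify the 14-dimensional descriptor vector with Fisher's linear
  discriminant (FLD); and
* a learned route — feed the preprocessed 32x32 grayscale region of
  interest directly to a small LeNet-style convolutional network (CNN).

No public image set of candled duck eggs exists, so the package ships a
synthetic scene generator with exact ground truth; all quantitative
statements made by the test suite are statements about that generator
(see *What the generator does and does not emulate* below).

## Preprocessing

Candling images put different information in different colour channels:
the egg silhouette is sharpest against the dark background in the red
channel, while the yolk shadow has the strongest contrast against the
surrounding albumen in the blue channel. `preprocess_egg()` therefore:

1. splits the RGB channels and median-filters (3x3, edge-replicated
   border) the red and blue channels;
2. thresholds the red channel with Otsu's method (the integer threshold
   maximizing between-class histogram variance; pixels above it are
   foreground) and keeps the largest 8-connected component as the egg;
3. expands the component's bounding box symmetrically into a square,
   pads it by 30 px on every side, and clamps it to the frame (shifting
   inward if needed);
4. crops the blue channel and the binary egg mask with that window,
   multiplies them so the background is exactly zero, and resizes both to
   32x32 with bicubic (Catmull-Rom) interpolation, re-binarizing the mask
   at 0.5.

```{r preprocess-example}
scene <- egg_scene("DY", yolk_overlap = 0.25, seed = 7)
img <- render_egg(scene)
rp <- preprocess_egg(img)
rp
```

Numerical choices worth recording:

* *Squaring before padding.* A bounding rectangle does not define a
  square; we expand the shorter side symmetrically so the egg stays
  centred, then pad. When padding runs past the frame the window is
  shifted inward, which preserves squareness except when the image itself
  is smaller than the requested side.
* *Downsampling with a widened kernel.* Plain bicubic sampling at a 8:1
  reduction aliases hard edges; the kernel support is therefore scaled by
  the zoom factor when downsampling (the behaviour of mainstream image
  resizers). At the native size the resize is exactly the identity.
* *Otsu degenerate input.* A constant image has no between-class variance
  anywhere; `otsu_level()` returns the constant itself with a warning, so
  that binarization yields an all-background mask and the pipeline fails
  loudly ("no egg found") rather than inventing a segmentation.
* Coordinates are 1-based `[row, col]` with the origin at the top left;
  contours store `(x = column, y = row)`.

## Yolk segmentation and shape description

`segment_yolk()` re-thresholds the masked ROI with Otsu's method so the
bright albumen separates from the darker yolk shadow, subtracts the
albumen image from the egg mask (leaving yolk plus a thin shell rim), and
removes the rim with another 3x3 median filter. The threshold is computed
over egg pixels only: the background is exactly zero by construction and
would otherwise dominate the histogram.

The boundary of the largest 8-connected yolk component is traced with
Moore-neighbour tracing (Jacob's stopping criterion, start at the
topmost-then-leftmost pixel) and encoded as the complex sequence
`s(k) = x_k + i y_k`. Its discrete Fourier transform

```
a(u) = sum_{k=0}^{N-1} s(k) exp(-i 2 pi u k / N)
```

gives the Fourier descriptors. They are normalized to

```
d(0) = 0,   d(u) = |a(u)| / |a(1)|  for u >= 1,
```

which removes translation (drop the DC term), scale (divide by the
fundamental), and rotation and start-point (take magnitudes). `d(0) = 0`
and `d(1) = 1` hold exactly for every non-degenerate contour, carry no
shape information, and are discarded; the feature vector is
`[d(2), ..., d(15)]`, fourteen numbers.

Design choices in this module, made where the underlying conventions are
genuinely open:

* *Which coefficients count as "the first n"?* Reconstruction keeps the
  `n` coefficients of lowest absolute frequency, interleaved
  `0, +1, -1, +2, -2, ...` (negative order `-u` lives at index `N - u`).
  Raw indices `0..n-1` alone cannot reproduce closed shapes well, and a
  circle should be (and is) recovered exactly from `n = 2`.
* *Reconstruction error.* `epsilon_n` is the mean, over original boundary
  points, of the distance to the *nearest* reconstructed point. Pairing
  points by index instead would make the minimum vacuous; the
  nearest-point reading keeps `epsilon_N ~ 0` for the full
  reconstruction and is the reading we adopt.
* *No fixed-length resampling.* Contours are used at their native traced
  length `N`. NFDs are magnitude ratios and insensitive to `N`; the
  truncation length (`m = 16`) is a parameter of `normalize_fds()`.
* *Orientation.* Traced contours are normalized to positive shoelace
  area so that the fundamental frequency is `+1` regardless of the
  tracer's direction.

```{r shape-example}
yolk <- segment_yolk(rp)
ct <- trace_boundary(yolk)
error_curve(ct)
```

The error curve falls quickly and is negligible well before 16
descriptors — the justification for truncating at `m = 16`.

## Fisher's linear discriminant

`fit_fld()` computes per-class means, the pooled within-class covariance
`S_p`, and the two Fisher classification functions
`f_g(x) = mu_g' S_p^-1 x - 1/2 mu_g' S_p^-1 mu_g + log p_g`; a sample goes
to the class with the larger score, and `fld_loocv()` implements
leave-one-out cross-validation. Priors default to equal — the reference
design is a balanced sample, where equal and proportional priors
coincide — and are configurable. Near-circular yolks make some
descriptors nearly collinear, so a singular pooled covariance falls back
to a small ridge (`1e-6 * trace / p` on the diagonal) with a warning.
Exact ties are broken toward SY; the direction is arbitrary but fixed and
documented.

Eggs whose two yolk shadows are fully *separated* (no overlap) are the
known failure mode of this route: boundary tracing takes the largest
single component, which is one circular disc, indistinguishable from an
SY yolk. The package reproduces this limitation deliberately — the
generator renders a configurable fraction of separated-yolk DY scenes
(default 5%), and they surface as DY-to-SY errors.

## The convolutional network

`build_cnn()` constructs the fixed architecture: 32x32 input, four 5x5
convolution kernels (sigmoid) to 4x28x28, 2x2 average pooling, six 5x5
kernels fully connected across the four input maps (sigmoid) to 6x10x10,
2x2 average pooling, flatten to 150, and a fully connected softmax layer
with two units — 1012 trainable parameters. Output order is `(DY, SY)`:
DY targets are `[1, 0]`, SY targets `[0, 1]`. Training is plain
minibatch SGD with a fixed learning rate of 0.2, batch size 50 and 100
epochs (full passes), no momentum, decay or schedule. Inputs are the
preprocessed ROIs divided by 255.

Two ambiguities are resolved behind flags:

* *Loss.* A softmax output pairs canonically with cross-entropy, which is
  the default; summed squared error on the softmax outputs (the default
  of some older toolboxes) is available via `loss = "mse"`.
* *Pooling activation.* Descriptions of this architecture sometimes place
  a sigmoid after the pooling layers as well; classic LeNet-style
  implementations activate only the convolutions. Conv-only sigmoid is
  the default, `pool_activation = "sigmoid"` enables the variant.

Weight initialization is unspecified in the reference description; we use
the uniform fan-based (Glorot) scheme `±sqrt(6 / (fan_in + fan_out))`,
seeded, with zero biases. All gradients are verified against central
finite differences in the test suite (relative error below 1e-4 across
every layer type, both losses and both pooling variants).

`evaluate_repeated_splits()` implements the evaluation protocol:
stratified 95:5 training/validation splits with equal class counts in
each group, a fresh initialization per repeat, and per-class accuracies
averaged over repeats.

## What the generator emulates — and what it does not

`make_dataset()` draws egg position, ellipse axes, yolk size, overlap,
intensity levels and noise from the frozen ranges in
`egg_param_ranges()`, renders each scene, and keeps exact ground truth
(label, scene parameters, yolk mask). The model is deliberately minimal:
a bright ellipse with a gentle radial falloff, disc-shaped yolk shadows
strongest in the blue channel, additive Gaussian noise (optional
salt-and-pepper noise is *not* rendered by default; the median filter is
motivated by sensor noise in general). Yolk shadows occupy a large
fraction of the egg interior and are strongly darker than the albumen in
the blue channel, as they are in real transmittance images; separated-
yolk scenes use smaller discs, consistent with the over-thresholding
mechanism that produces them in real images. Defaults were chosen once so
that both classification routes have a realistic, solvable task, and are
frozen; the end-to-end accuracy benchmarks in the test suite are defined
against exactly these settings.

The generator does **not** emulate shell texture or speckling, spectral
properties of the light source, candler-aperture glow, multi-egg scenes,
or burst/scattered yolks. Passing tests therefore demonstrate that the
algorithms are implemented correctly and behave as designed on images
with the documented structure — they do not certify accuracy on real
eggs, for which no public data exist.

Problem sizes used by the checks: the frozen benchmark is 400 images
(200 SY, 200 DY, 5% of DY with separated yolks, seed 101) at 400x300 px;
the network evaluation uses 3 stratified 95:5 splits. These sizes were
chosen as the smallest at which the accuracy statements are stable across
seeds.

## Known limitations

* The FLD route inherits the separated-yolk failure by design; the CNN
  route usually survives it.
* Boundary tracing requires at least four boundary pixels; yolks smaller
  than a few ROI pixels are rejected as degenerate rather than guessed.
* The timing figures printed by `run_train_eval()` are informational
  only; they depend on hardware and are asserted nowhere.
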