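---
title: "ResMini: model, pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ResMini: model, pipeline and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resmini)
```

## The problem and the model

Brain age classification assigns an age group (here: 3–5 years,
7–12 years, adult — or four dementia stages) to a 2D axial middle slice
of a brain MRI volume. The point of ResMini is parameter economy: a
residual network of only 10 weighted layers that stays competitive with
far larger networks while using a fraction of their parameters, which
matters when models must run on clinical hardware.

The architecture, expanded by `layer_specs()`:

* a stem `Conv_BN_ReLU` — 3×3 convolution, stride 1, padding 3, `f`
  filters (default `f = 9`), batch norm, ReLU;
* a 3×3 max pool with stride 2 and padding 1;
* four residual modules. Module *i* carries two main-path 3×3
  `Conv_BN_ReLU` blocks with `f·2^(i−1)` filters (the width-doubling
  rule) and a 1×1 projection `Conv_BN` on the shortcut, joined by an
  add and a final activation. Modules 2–4 downsample with stride 2 on
  the first main convolution and the shortcut;
* global average pooling, a dense layer with `K` outputs, and softmax.

Counting main-path convolutions plus the dense layer — the convention
behind names like "ResNet-18" — gives 1 + 4·2 + 1 = 10 weighted layers.
Projection-shortcut convolutions, batch norms, pooling and activations
do not count toward depth.

### Parameter counting

`count_parameters()` is a pure function of the symbolic plan: a
convolution holds `kh·kw·c_in·c_out` weights (convolutions followed by
batch norm carry no bias), batch norm holds 2 trainable parameters per
channel plus 2 running statistics (counted by default, matching the
"total params" convention of framework model summaries), and the dense
layer holds `in·out + out`. For the all-projection shortcut policy the
total collapses to the closed form

$$ 1195 f^2 + f\,(9 c_0 + 184) + 8 f K + K $$

which the test suite checks against the per-layer sum for
`f ∈ {1,2,4,8,9,16}`, `c0 ∈ {1,3}`, `K ∈ {3,4}`. The reference
configuration (`f = 9`, grayscale input, `K = 3`) totals **98,751**
parameters. The published total for this network is 98,907; no
structural variant we enumerated (stem width, input channels, shortcut
policy, bias placement) reproduces that figure exactly — the closest
are 98,751 (grayscale) and 98,913 (three-channel input). We therefore
treat the published figure as an upper reference point: the package
documents the 156-parameter gap rather than tuning filter counts
blindly, and the acceptance checks assert a `≤` bound instead of
equality. The ResNet-18 comparison summary is built from the canonical
18-layer plan (7×7/64 stem, stages 64/128/256/512); its exact published
count depends on an unstated input adaptation, so only the order of
magnitude is compared. BHCnet is defined in its own publication; only
its published count (196,595) enters the comparison report.

### Structural readings the source leaves open

Three points of the architecture description are ambiguous, and the
package fixes them as follows:

* "three Conv_BN_ReLU blocks" per residual module is read as two
  main-path 3×3 convolutions plus the 1×1 projection shortcut — the
  only reading consistent with a depth of 10 (a third main conv per
  module would give 13);
* the stem is implemented exactly as printed (3×3, stride 1,
  padding 3) even though padding 3 exceeds "same" for a 3×3 kernel;
  the parameter count is unaffected, and a 7×7 stem (the classic
  residual-network convention) would change it, so it is recorded as an
  alternative but not implemented;
* downsampling placement is unstated; we use the standard residual
  convention (stride 2 at modules 2–4, module 1 at stride 1).

The main path applies ReLU after the second batch norm *before* the
shortcut add (the module is literally a chain of `Conv_BN_ReLU`
blocks), followed by one more activation after the add. The classic
residual ordering (no activation between the second batch norm and the
add) differs only in nonlinearity placement, not in parameters or
depth.

## The pipeline

`extract_middle_axial_slice()` takes the plane at 0-based index
`floor(D/2)` along the axial axis (third array axis by default,
overridable). For 4D fMRI series the first time frame is sliced — the
choice is arbitrary but deterministic; any per-voxel summary statistic
would be equally valid. Slices are min-max normalized to `[0, 1]`
per image (a constant image maps to zeros) and exported as 8-bit
grayscale PNG; labels live only in the manifest CSV, never in file
names.

Augmentation doubles the dataset: each original receives exactly one
variant, produced by a uniform integer offset in
`[-0.1·dim, +0.1·dim]` per axis followed by a horizontal flip. The
offset magnitude is our choice (the source specifies offsets and
flipping but no magnitudes); 10% keeps the brain inside the frame, and
vacated pixels are filled with the dark background value 0. Applying
offset *and* flip to a single copy per image is the only reading
consistent with 155 originals becoming 310 samples while both
transforms are described.

Splitting is stratified 8:2 into train/test, then 8:2 again into
train/validation, with floor-per-class rounding: class sizes 130/114/66
give a test set of 26 + 22 + 13 = 61, matching the published test-set
size. (The published per-class test counts 27/21/13 sum to 61 but match
no standard rounding rule for these class sizes at 20%; we treat them
as an internal inconsistency of the source and keep the floor rule.)
By default augmentation runs *before* splitting — reproducing the
published design, in which augmented copies can land in the test set —
and `leakage_safe = TRUE` (or `--leakage-safe`) splits first and
augments only training records, which is the defensible choice for any
real study.

## Training

`train()` runs mini-batch ADAM (β₁ = 0.9, β₂ = 0.999, ε = 1e-7) with
categorical cross-entropy — the standard pairing with a softmax head;
the source does not name its loss. The published regime is learning
rate 2e-5, batch size 24, 200 epochs, and those are the
`training_config()` defaults. No early stopping, schedule or weight
decay are used. Weight initialization is He-normal for convolutions and
Glorot-uniform for the dense layer, seeded; epoch shuffling is seeded
separately, so a run is reproducible from two integers (in
`run_pipeline()` both fan out from one top-level seed).

Batch norm uses ε = 1e-3 and updates running statistics with the 0.9
exponential-average convention. At this dataset scale an epoch is only
a handful of batches; with a 0.99 average the inference-mode statistics
lag hundreds of steps behind the weights, and we observed exactly that
failure mode (perfect batch-mode training accuracy, collapsed
inference-mode accuracy) before settling on 0.9.

The forward/backward engine is part of the package: im2col gathers plus
BLAS matrix products for convolutions, with the scatter-add transpose
(`col2im`) and pooling argmax in C++. Gradients are verified against
central finite differences in the test suite; agreement is limited only
by ReLU/max-pool kink crossings under the 1e-5 probe, so the test
tolerance is 1%.

## The phantom generator

Clinical MRI cannot ship with a package, so every stage is exercised on
synthetic brain phantoms: an elliptical brain with a brighter cortical
ring and a dark central ventricle on a zero background, plus clipped
additive Gaussian noise. The three default classes mimic the direction
of real age effects — larger ventricles, thinner cortex, slightly
smaller brain with age — because that is the kind of morphological
contrast the classifier must exploit; any separable signal would do for
pipeline testing. Defaults mirror the study material: 95×79 grayscale
slices, 65/57/33 samples across the three classes (155 originals).

The `separation` knob scales every class's deviation from the
across-class mean morphology: 1 is the designed contrast, 0 makes all
classes identically distributed. The zero-separation setting is a
negative control — a pipeline that "learns" it above chance is leaking
labels. `phantom_volume()` stacks attenuated copies of the designed
slice so the middle-plane extraction can be verified exactly.

What phantoms do *not* model: MRI physics, partial-volume effects,
registration error, scanner variation, within-class anatomical
variability beyond additive noise. Passing the phantom tests shows that
the architecture, optimization and bookkeeping work — it says nothing
about accuracy on clinical data, and the published real-data accuracies
are deliberately not reproduction targets here.

## Desk-scale problem sizes

The verification runs use sizes chosen to make the full suite complete
in minutes on one CPU while still being informative:

* *end-to-end learnability*: 60 phantoms per class (separation 1, noise
  s.d. 0.05), 30 epochs, batch 24 — held-out accuracy must reach 0.9;
* *negative control*: 20 per class at separation 0, 8 epochs, five
  seeds — mean held-out accuracy must stay at chance (≤ 0.5);
* *smoke training*: 40 phantoms, 2 epochs — training loss must strictly
  decrease, bit-identically across reruns.

These short runs use learning rate 1e-3 (a conventional ADAM default):
at the published 2e-5 a 30-epoch budget moves the weights by too little
to separate even easy phantoms, which is a statement about step counts,
not about the architecture. The published 2e-5/200-epoch regime remains
the package default for full-scale training.

## Known limitations

* The engine is CPU-only and tuned for this network's scale (~1 s per
  24-image batch at 95×79); it is not a general deep-learning
  framework.
* `count_parameters()` trusts its layer plan; exotic plans built by
  hand are counted by the same per-kind rules but not validated for
  realizability.
* Per-class accuracy figures published for the real data (0.961/0.954)
  match neither per-class recall nor one-vs-rest accuracy derivable
  from the published confusion description; they are not reproduced.
* Training determinism is guaranteed per platform/BLAS, not across
  platforms.
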