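---
title: "Edge-enhanced adversarial segmentation of pulmonary nodules: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-enhanced adversarial segmentation of pulmonary nodules: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Pulmonary nodules — roughly spherical lesions of 3–15 mm — are the earliest
CT-visible manifestation of lung cancer. Delineating them per pixel is hard
for three reasons: the foreground occupies a tiny fraction of each slice
(extreme class imbalance), ground-glass nodules have hazy boundaries, and
the surrounding parenchyma is full of confusable structure, above all blood
vessels. `nodulegan` implements a complete, CPU-testable training and
inference framework for this task: an adversarially trained, deeply
supervised U-Net operating on 2.5D pseudo-colour composites, together with
a synthetic phantom generator so every mechanism can be exercised and
verified without any external data.

## 2.5D pseudo-colour encoding

A full 3D network is expensive and, for lesions that span only a few
slices, mostly wasted. Instead, each annotated slice is encoded with its
two axial neighbours as the R (previous), G (current) and B (next) channels
of one three-channel image. Vessels, which persist across slices, appear in
all three channels along their track; a nodule, concentrated on one slice,
is dominated by the G channel. This gives a 2D network genuine inter-slice
context at 2D cost. At the volume ends the boundary slice is replicated.

Preprocessing maps HU to `[0, 1]` through a lung window. The window phrase
"−600–1200 HU" is interpreted as *level −600 / width 1200*, i.e. the
interval `[−1200, 0]` HU: the literal clip range `[−600, 1200]` would
exclude all aerated lung (below −600 HU), which cannot be the intent for a
lung task. Both readings are expressible through `window_spec()`. The crop
is a 128×128 region of interest centred on the mask centroid computed from
raw image moments (`m10/m00`, `m01/m00`). A "second-order moment" is a
matrix, not a location; the centroid is the only coherent reading of
"centred at the moment of the ground truth", and the self-consistency test
(re-centroiding the cropped mask lands within 1 px of the ROI centre)
pins the implementation down. Coordinates are 1-based `(row, col)`
throughout, following R convention.

## Auxiliary label pyramids

Two 4-level label pyramids accompany every composite:

* the **mask pyramid** `y_d` — the ground-truth mask downsampled by factors
  1, 2, 4, 8;
* the **edge pyramid** `y_g` — the 1-pixel boundary of the mask,
  downsampled the same way.

Downsampling is **max pooling**, not averaging: a 1-px edge or a 3-px
nodule would be erased by mean-pool-and-threshold, whereas max pooling
provably preserves any structure at least one output cell wide (tested as
the single-positive-pixel invariant). Boundaries are extracted as the exact
morphological boundary (mask pixels with a 4-neighbour outside), which on a
binary step edge is what a Canny detector returns, minus the
nondeterminism; a conventional Canny (Gaussian σ = 1, hysteresis 0.1/0.2)
is available behind `extract_edge_map(method = "canny")`.

## Generator

The generator is a four-stage encoder/decoder. Each encoder stage is
(conv 3×3 → norm → ReLU) ×2 followed by 2×2 max pooling; the decoder
mirrors it with bilinear upsampling and skip concatenation. Stage widths
default to (32, 64, 128, 256) and are configurable; the acceptance-scale
runs use (8, 16, 32, 64).

**Side outputs.** Every decoder depth `k = 1..4` emits a single-channel
logit map `s_k` through a 1×1 convolution `p_k`; `F_k` is its bilinear
upsampling to the input resolution. A parallel 1×1 convolution `q_k`
produces attention logits which, after upsampling and a softmax **across
depths**, give per-pixel attention weights `F'_k` with `sum_k F'_k = 1`
everywhere. The fused pre-sigmoid output is `sum_k w_k * F'_k * F_k` with
trainable scalars `w_k` (initialised to 1); the final probability map is
its sigmoid. The fusion equation itself carries no activation, so the
sigmoid placement is a design choice, recorded here. Binarisation for
metrics uses threshold 0.5.

**Inverted residual stem.** Two inverted residual blocks (1×1 expansion →
3×3 depthwise convolution → squeeze-excitation channel gating through two
fully connected layers → 1×1 projection, with a residual skip) sit before
the encoder. Their stated purpose is fusing the three-channel composite's
inter-slice information, which implies early placement; the expansion
kernel is 3×3 stride 1 (unstated in the source, chosen as the MobileNet
lineage default). Output width always equals input width.

**Ablation toggle.** With `use_hed = FALSE` the side outputs and fusion are
replaced by a single 1×1 head on the last decoder stage — a plain U-Net.
With `use_inverted_residual = FALSE` the stem disappears. These two flags,
plus the adversarial/minibatch flags below, span the ablation matrix.

## Critic

The critic scores *masked composites*: the element-wise product of the
composite with either the predicted probability map (`x·ŷ`) or the ground
truth (`x·y`). It has four stride-2 stages (conv 4×4 → batch norm →
LeakyReLU(0.2) → dropout 20%). The LeakyReLU slope is a community default
(unstated in the source).

**Feature matching.** The four stage feature maps have different
resolutions, so "concatenating the input with intermediate features" is
realised as the minimal consistent construction: global-average-pooled
descriptors of every stage and of the input are concatenated into the
score head's input.

**Minibatch discrimination.** Flattened final features `X ∈ R^{b×n}` are
projected to `Z = XW + β ∈ R^{b×k}`; `D_ij = ||z_i − z_j||²`;
`K_ij = exp(−D_ij / (2σ²))`; `M_i = mean_j K_ij`. The per-sample
similarity `M_i` joins the descriptor, letting the critic detect collapsed
batches (it is a layer output, not a separate loss term). The printed
bandwidth formula is typographically garbled; both readings are
implemented: `mb_sigma_mode = "as_printed"` gives `σ = k/(2n)`, `"fixed"`
gives a constant (default 1.0). Training defaults to the fixed mode
because with `n` in the thousands `σ = k/(2n)` drives `exp()` below the
smallest double, making the layer constant (`K` exactly 0 off-diagonal) —
the test suite demonstrates exactly this underflow.

**Lipschitz constraint.** After every critic update, every trainable
critic parameter (including norm-layer affine terms) is clipped to
`[−0.012, 0.012]`. The generator is never clipped.

## Losses

With `σ(·)` the sigmoid and labels `y ∈ {0,1}`:

* **Adversarial** `L_a = |D(x·ŷ) − D(x·y)|` on batch-mean critic scores.
  The generator minimises it, the critic maximises it (its loss is
  `L_d = −L_a − L_ds`).
* **Self-balanced multi-level BCE** `L_ds = sum_k L_dk`, where each level
  uses the class weight `w_k = N_neg/N_pos` (1 if the level is empty),
  recomputed per level and per image, and the per-pixel terms are *summed*,
  following the printed form; the batch is reduced by the mean of
  per-image sums. A mean-per-pixel reduction is not used by default.
* **Multi-level edge loss** `L_ge`: the same weighted BCE against the edge
  pyramid.
* **Dice** `L_gs = 1 − (2Σyŷ + ε)/(Σy + Σŷ + ε)` with `ε = 1e−6` so an
  empty prediction against an empty truth is defined (loss 0).
* **Generator composite** `L_g = L_a + w_e·L_ge + w_s·L_gs`. The weights
  `w_e`, `w_s` are never stated in the source; both default to 1.

**Where `L_ds` acts.** The bookkeeping places `L_ds` inside the critic loss,
but it contains no critic parameters — its gradient in a critic update is
identically zero. Its described effect (gradient feedback to the
generator's per-level feature maps, faster convergence) only exists through
the generator, so the implementation applies its gradient during the
generator step; `literal_lds_in_disc = TRUE` restores the literal ledger
for reported `L_d` values. The supervised maps are the **native-resolution**
side outputs `s_k` (matching the downsampled labels), not the upsampled
`F_k` — the two descriptions in the source conflict, and native resolution
is the one consistent with "labels downsampled to match the side outputs".

**Plain U-Net ablation.** Without side outputs `L_ds`/`L_ge` do not exist;
the single head is trained with the same class-balanced BCE plus Dice, the
standard recipe for this architecture. The ablation matrix only requires
the configuration to be constructible and trainable.

## Training protocol

Both networks use Adam (lr 0.001, β = (0.9, 0.999)), batch size 64, and a
cosine-annealed learning rate; annealing runs over the epoch budget down to
a floor of 1e−5 (floor and epoch count unstated in the source; the plateau
rule "train until convergence" is operationalised as a fixed epoch budget).
Each iteration takes one critic step (on detached generator output,
followed by weight clipping) and one generator step — a 1:1 ratio,
configurable. Batch indices are drawn per iteration from the seeded RNG,
which makes runs exactly resumable: a checkpoint stores parameters, norm
statistics, optimizer moments and the RNG state, and the test suite asserts
that save → load → continue is bit-identical to an uninterrupted run.
A NaN in any loss aborts with a diagnostic (iteration, loss components,
parameter norm range).

## The phantom generator: what it emulates, and what it does not

`generate_phantom()` produces seeded `(slice, row, col)` HU volumes with:

* background: low-frequency Gaussian field around −800 HU (air-dominated
  parenchyma) plus fine texture, values chosen to land inside the default
  lung window;
* vessels: tubes of radius 1–3 px whose axes run along the slice direction
  with mild drift and curvature, guaranteed to cross every slice — this is
  the property that makes vessels polychromatic in composites;
* one nodule: an oblate ellipsoid with in-plane radius drawn uniformly
  from 3–15 px whose central slice is a full disc and whose neighbours
  carry only thin caps, so most mask voxels lie on a single slice (the
  slice-local, monochrome signature);
* solid nodules step to +50 HU with a sharp edge; ground-glass nodules add
  a smooth Gaussian falloff peaking at −450 HU, so their boundary gradient
  is strictly smaller — both contrasts survive the default windowing.

Deliberately absent: pleural attachment, fissures, bronchi, dose/noise
physics, anatomical lung shape. A green test on phantoms establishes that
the *mechanisms* (encoding, supervision, losses, adversarial plumbing)
work as specified — it does not establish clinical segmentation accuracy,
which requires real CT data and training at full scale.

## Numerical choices

* All tensors are dense double arrays `[H, W, C, N]`; the autodiff engine
  is reverse-mode with creation-order topological ordering, and every
  kernel (grouped convolution, max pool, bilinear resize, batch norm,
  minibatch discrimination, losses) is finite-difference checked.
* Bilinear resizing uses the half-pixel convention, so resizing to the
  same size is the exact identity (`F_1 = s_1` at full resolution).
* BCE uses stabilised log-sigmoid branches; no logit magnitude overflows.
* Max pooling breaks ties toward the first (row-major earliest) element.
* Batch norm: momentum 0.1, ε = 1e−5, unbiased running variance.
* Weight init: He for convolutions, scaled Gaussian for projections;
  fusion weights start at 1, so all depths contribute equally at start.

## Known limitations

* No NIfTI reader exists in the offline dependency set, so `read_volume()`
  supports MetaImage only and fails loudly on `.nii/.nii.gz`.
* The critic's batch-norm statistics are updated separately on fake and
  real batches; with tiny batches this adds noise (standard for this
  construction, but worth knowing).
* Composite archives are R-native RDS rather than a cross-language format.
* Training at benchmark scale (thousands of samples, hundreds of epochs,
  full 128×128) is possible but slow on one CPU; the packaged acceptance
  runs use 32×32 crops and narrow networks and are sized to minutes.
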