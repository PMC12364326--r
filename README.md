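# nodulegan

Adversarial, edge-enhanced segmentation of pulmonary nodules on 2.5D
pseudo-colour CT composites — implemented as a self-contained R package
that trains and runs on a single CPU with no external data.

## Who this is for

Researchers in medical image analysis who want a fully inspectable,
dependency-light reference implementation of a deeply supervised
segmentation GAN: every mechanism (multi-scale deep supervision, attention
fusion, minibatch discrimination, class-balanced and edge-aware losses,
critic weight clipping) is implemented in plain R with small compiled
kernels, unit-tested against independent oracles, and exercised end to end
on a packaged synthetic phantom generator.

## The model

Each annotated axial slice is encoded with its two neighbours as the
R/G/B channels of one composite, so a 2D network sees inter-slice context:
vessels (present on all three slices) are polychromatic, a nodule
(concentrated on one slice) is monochrome.

The **generator** is a four-stage U-Net with per-depth single-channel side
outputs. Depth *k* emits native logits `s_k = p_k(d_k)` (1×1 convolution),
upsampled maps `F_k = u_k(s_k)`, and attention logits `q_k(d_k)` that are
softmax-normalised **across depths** into weights `F'_k`
(`sum_k F'_k = 1` per pixel). The prediction is

    y_hat = sigmoid( sum_k  w_k * F'_k * F_k )

with trainable fusion weights `w_k`. Two inverted residual blocks
(expand → depthwise conv → squeeze-excitation gates → project, with a
residual skip) form an optional stem that fuses the three-channel input.

The **critic** scores masked composites `x·y` (real) against `x·y_hat`
(predicted) with four stride-2 convolution stages, pooled-descriptor
feature matching, and Gaussian-kernel minibatch discrimination

    Z = XW + beta,   D_ij = ||z_i - z_j||^2,
    K_ij = exp(-D_ij / (2 sigma^2)),   M_i = mean_j K_ij,

whose similarity vector `M` lets it detect collapsed batches. After every
critic update all critic parameters are clipped to `[-0.012, 0.012]`.

**Losses.** Adversarial `L_a = |D(x·y_hat) - D(x·y)|`; self-balanced
multi-level BCE `L_ds` on the mask pyramid (per-level class weight
`N_neg/N_pos`); the same form `L_ge` on the boundary pyramid; Dice `L_gs`;
generator objective `L_g = L_a + w_e L_ge + w_s L_gs` (plus `L_ds`, whose
gradient only exists through the generator). Evaluation uses IoU, DSC,
SEN, PRE from pixel confusion counts.

See `vignettes/methods.Rmd` for assumptions, defaults and design choices.

## Worked example

```r
library(nodulegan)

# 1. simulate: 64 training + 16 held-out solid-nodule phantoms
pcfg <- phantom_config(volume_shape = c(5L, 64L, 64L),
                       nodule_radius_range = c(5, 12),
                       nodule_kind = "solid", n_vessels = 3L)
train_ds <- preprocess_dataset(generate_dataset(64, pcfg, seed = 1000),
                               size = 32L)
test_ds  <- preprocess_dataset(generate_dataset(16, pcfg, seed = 5000),
                               size = 32L)

# 2. train the adversarial model with minibatch discrimination
cfg <- ablation_config("gan_mb", batch_size = 8L, epochs = 19L,
                       image_size = 32L,
                       gen_widths = c(8L, 16L, 32L, 64L),
                       disc_widths = c(8L, 16L, 32L, 64L),
                       max_iters = 150L, seed = 42L)
model <- train_model(train_ds, cfg)

# 3. evaluate on held-out phantoms
pred <- predict_masks(model, test_ds)
ev <- evaluate_masks(pred$masks, lapply(test_ds, `[[`, "mask"))
print(ev$summary)
```

On the fixed seeds above this run (about 4 minutes on one CPU) prints

```
IoU 0.8208  DSC 0.8971  SEN 1.0000  PRE 0.8208
```

An untrained generator on the same held-out set scores DSC 0.2602, so 150
CPU iterations on 64 phantoms lift held-out Dice overlap from noise level
to ~0.90 (perfect recall, some over-segmentation). The numbers measure
phantom segmentation only — the phantoms are a mechanism test, not a
clinical benchmark.

The same pipeline is available from the shell:

```sh
Rscript exec/nodulegan simulate   --n 8 --seed 1 --out runs/sim
Rscript exec/nodulegan preprocess --in runs/sim --out runs/pre
Rscript exec/nodulegan train      --in runs/pre --out runs/model
Rscript exec/nodulegan predict    --checkpoint runs/model/checkpoint.rds \
                                  --in runs/pre --out runs/pred
Rscript exec/nodulegan evaluate   --pred runs/pred --truth runs/pre \
                                  --out runs/eval
```

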