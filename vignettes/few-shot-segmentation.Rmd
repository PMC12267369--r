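---
title: "Prototype-based few-shot segmentation: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prototype-based few-shot segmentation: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsseg)
```

## The problem

Organ segmentation models normally need thousands of annotated slices.
One-shot episodic segmentation asks for far less: each *episode* provides a
single annotated support pair $(I_s, M_s)$ and an unlabeled query image
$I_q$, and the model must predict the query mask $\hat M_q$. Training
samples many such episodes so that the network learns a *procedure* for
transferring one annotation to a new image, rather than memorising one
organ's appearance.

`fsseg` implements this as a complete, CPU-trainable pipeline: a synthetic
phantom generator, a preprocessing module for real CT slices, the network
itself, the composite training loss, evaluation metrics, and an episodic
training engine. Because no automatic-differentiation framework is assumed,
the package carries its own small reverse-mode tape engine with compiled
convolution, pooling, and upsampling kernels; its gradients are verified
against central finite differences in the test suite.

## Model

**Encoder.** Support and query images pass through the *same* weights
(shared-branch design). Each of `n_levels` stages is a residual block

$$F_\text{out} = \mathrm{ReLU}\big(\mathrm{SE}(\mathrm{BN}(W_2 *
\mathrm{ReLU}(\mathrm{BN}(W_1 * F_\text{in})))) + \mathrm{proj}(F_\text{in})\big),$$

with 3×3 "same" convolutions, a 1×1 projection where channel counts differ,
and squeeze-and-excitation (SE) recalibration: channel means
$z_c = \frac{1}{HW}\sum_{ij} F(c,i,j)$ are mapped through a two-layer
bottleneck $s = \sigma(W_2\,\mathrm{ReLU}(W_1 z + b_1) + b_2)$ and each
channel is rescaled by its gate $s_c \in (0,1)$. The block output is kept as
the skip feature for that level; 2×2 max pooling halves the resolution.
Stage widths double per level from `base_width` (the 64→512 scheme at full
scale).

**Prototype module.** At the bottleneck, support features are SE-refined,
L2-normalised along channels, and flattened into $N = H'W'$ tokens of
dimension $C$ for a stack of transformer blocks: scaled dot-product
attention $\mathrm{softmax}(QK^\top/\sqrt d)\,V$ with $h$ heads, output
projection, then residual + layer-norm, a two-layer ReLU feed-forward
network, and a second residual + layer-norm. The support mask, downsampled
by nearest neighbor, drives masked average pooling

$$P = \frac{\sum_{ij} M(i,j)\, X''(i,j)}{\sum_{ij} M(i,j) + \varepsilon},$$

and a channel-attention head gates the prototype:
$P_\text{attn} = \sigma(W_2\,\mathrm{ReLU}(W_1 P + b_1) + b_2)\odot P$. The
query stream runs SE → transformer → L2-normalise, is concatenated with the
broadcast prototype, and fused by a 1×1 convolution + normalisation + ReLU.
The per-pixel cosine between the fused features and $P_\text{attn}$ (both
L2-normalised; an all-zero vector is guarded to raw similarity 0) is
rescaled by $(S+1)/2$, clipped to $[0,1]$, and multiplies the fused features
— a soft spatial attention mask highlighting query regions that resemble
the support organ.

**Decoder.** From the modulated bottleneck upward, each level bilinearly
upsamples by 2, halves channels with a 1×1 convolution, gates the
corresponding query-branch skip with an attention gate
($\alpha = \sigma(\psi\,\mathrm{ReLU}(W_x x + W_g g))$, gating signal $g$ =
the upsampled decoder feature), concatenates, and refines with one
SE-residual block. A 1×1 convolution and sigmoid produce the probability
map; `binarize()` thresholds it at 0.5 by default.

**Loss.** Training minimises
$\alpha L_\text{Dice} + \beta L_\text{Focal} + \gamma L_\text{Tversky} +
\delta L_\text{BCE}$ on soft probabilities with weights
$(0.30, 0.25, 0.30, 0.15)$, the best row of the tuning grid the
architecture was selected with. The focal term multiplies *both* the
positive and negative cross-entropy terms by $\alpha_f (1-p)^{\gamma_f}$, as
the model's loss is defined; `focal_params(symmetric = TRUE)` switches to
the conventional $p_t$ form. Identities used as test oracles: Tversky with
$\alpha_t=\beta_t=0.5$ *is* the Dice loss, and focal with
$\alpha_f=1,\gamma_f=0$ *is* BCE.

**Optimisation.** Adam at a fixed learning rate 0.001
($\beta_1 = 0.9, \beta_2 = 0.999$, no weight decay — unstated elsewhere, so
the customary values), global gradient-norm clipping at 1.0, and a batch of
one episode per step. Evaluation freezes the weights (enforced by an
internal checksum): episodes are scored with hard masks by Dice, IoU, and
specificity and aggregated as mean ± SD (population SD by default).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `base_width` | 8 (desk scale) | channels at level 1; doubles per level |
| `n_levels` | 3 at 64×64, 4 at 256×256 | residual+pool stages |
| `se_reduction` | 16 | SE bottleneck ratio, clamped so $C/r \ge 1$ |
| `dropout_rate` | 0.3 | after each residual block, train mode only |
| `transformer_layers` | 2 | prototype-stack depth (1 suffices at desk scale) |
| `n_heads` | 1 | attention heads; must divide the token dim |
| `ffn_mult` | 2 | FFN hidden width as a multiple of the token dim |
| `modulate_target` | `"fused"` | what the similarity map multiplies |
| learning rate / clip | 0.001 / 1.0 | fixed |
| loss weights | 0.30/0.25/0.30/0.15 | must sum to 1 |

`modulate_target` exists because the similarity mask is described in two
ways — as modulating the raw query features and as modulating the fused
features; the fused-feature account is the more detailed one, so it is the
default, with `"raw_query"` preserving the alternative.

## Design choices where the design was open

* **Normalisation in one-episode batches.** With a batch of one episode,
  batch normalisation degenerates to per-feature-map statistics. The package
  therefore normalises over the spatial extent of each channel (instance
  style) in both train and eval mode, instead of tracking running estimates:
  evaluation is exactly deterministic and no train/eval statistics drift is
  possible. This is the one place the implementation deliberately departs
  from a textbook train/eval BN split.
* **Shared prototype-module weights.** The query stream's SE block and
  transformer stack reuse the support stream's parameters. The construction
  stays symmetric in its two inputs and halves the module's parameter count;
  nothing requires separate weights.
* **Ordering of L2 normalisation.** The support stream normalises before its
  transformer stack (so the pooled prototype inherits a normalised scale);
  the query stream normalises after its stack, immediately before fusion and
  the cosine — the two statements of the pipeline imply different orders,
  and this choice keeps both similarity inputs freshly normalised.
* **Positional encodings** are omitted: the tokens feed a *pooled* prototype
  and a per-pixel cosine, both of which are position-symmetric uses, and no
  encoding is part of the module's description.
* **Upsampling** is bilinear with half-pixel alignment plus a 1×1
  channel-halving convolution (no transposed convolutions, avoiding
  checkerboard artifacts); `"nearest"` is available.
* **Attention-gate skips** use the pre-pool encoder features of the query
  branch (standard U-Net symmetry); support skips are unused at decode time.
* **Episode eligibility.** Support slices must contain foreground — a
  prototype pooled over an empty mask is degenerate — while query slices
  may be anything; the slice-pair sampler never pairs a slice with itself.
* **Numerical guards.** $\varepsilon = 10^{-6}$ in pooling, normalisation,
  and overlap denominators; probabilities are clipped at $10^{-7}$ before
  logarithms; a zero-norm cosine is mapped to raw 0 (scaled 0.5, neutral);
  empty-vs-empty masks score 1.0 on all overlap metrics.

## The phantom generator

Real CT volumes are large and access-controlled, so the package ships a
generator of CT-like episodes instead: each slice is a low-intensity
textured background (bilinearly upsampled coarse noise) plus one or more
bright superellipse blobs with low-order radial boundary perturbation —
mimicking the variability of soft-tissue organ cross-sections — with
additive Gaussian noise and clipping to $[0,1]$. Defaults: foreground offset
drawn from $[0.4, 0.7]$, noise SD 0.03, shape jitter 0.1, one blob, 64×64
for testing (256×256 for demos). Support and query share a blob family,
texture, and brightness; the query shape is perturbed by at most
`shape_jitter` in radius, ellipticity, position, and orientation, so the
two masks overlap with Dice $\ge 1 - 2\,\texttt{shape\_jitter}$ in
practice.

What the phantoms do *not* emulate: Hounsfield-unit physics, neighbouring
organs with confusable intensity, pathology, partial-volume effects, or
inter-patient protocol variation. A model that segments phantoms well has
demonstrated that the architecture, loss, gradients, and episodic engine
work end to end — not that it would reach any particular accuracy on
clinical CT. Published full-scale results require the real datasets and
GPU-scale training and are out of scope here; the package's own numbers are
whatever `scripts/acceptance.R` and the test suite compute at desk scale.

## Problem sizes used by the tests and the acceptance script

The shipped experiments run on one CPU in a few minutes: the main run
trains the 64×64 / base-width-8 / 3-level / 1-transformer-layer model for
300 episodes (3 epochs × 100) and scores 50 held-out phantom episodes; the
overfit probe takes 200 steps on a single fixed episode; contract checks
log 500 steps of a 32×32 model. Unit tests use 16×16–32×32 models. These
sizes are the package's desk-scale study conditions; scaling up is a matter
of configuration, not code.

## Known limitations

* CPU-only and single-threaded; at 256×256 with base width 64 a training
  step is minutes, so full-scale training is impractical here by design.
* Strictly 1-shot: no multi-shot prototype averaging.
* Binary foreground/background only; no multi-class heads, no deep
  supervision, no boundary losses, no Hausdorff/ASSD metrics.
* The NIfTI path extracts axial slices by index and binarises labels; it
  does no 3D resampling, spacing harmonisation, or bias-field correction.
* Determinism is exact for fixed seeds on a given platform; across BLAS
  implementations results may differ in the last bits.

## A worked episode

```{r example}
cfg <- model_config(image_size = 32, base_width = 4, n_levels = 2,
                    transformer_layers = 1)
model <- init_model(cfg, seed = 1)
tc <- train_config(epochs = 1, episodes_per_epoch = 40, val_episodes = 5,
                   seed = 1)
run <- fit(model, tc, train_source = phantom_config(image_size = 32, seed = 1))
report <- evaluate(run$model, phantom_config(image_size = 32, seed = 99),
                   n_episodes = 10, seed = 2)
report
```

The report prints mean ± SD Dice, IoU, and specificity over the held-out
episodes; `scripts/acceptance.R` runs the same computation at the package's
standard desk scale and writes the numbers as JSON.
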