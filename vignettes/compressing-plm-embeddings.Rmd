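---
title: "Compressing protein language model latents with an hourglass autoencoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compressing protein language model latents with an hourglass autoencoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cheap)
```

## The problem

Per-residue latents of protein language models — in particular the
`L x 1024` embedding sitting between a pLM and a structure-prediction
trunk — jointly encode sequence and (emergent) structure information, which
makes them attractive as a general-purpose protein representation. Two
pathologies stand in the way of using them directly:

1. **Massive activations.** A handful of channels carry values orders of
   magnitude (up to thousands of times) larger than the median channel,
   independently of the input sequence. Any isotropic treatment of the
   latent (diffusion priors, 8-bit quantization, dot-product search) is
   dominated by these channels.
2. **Excess dimensionality.** The intrinsic dimensionality of the latents
   is far below 1024, and the per-residue length makes attention-based
   downstream models pay an `O(L^2)` cost for no informational gain.

This package implements the remedy stack: per-channel min-max
normalization, and the **hourglass protein compression transformer
(HPCT)** — an autoencoder that compresses lengthwise by a factor `S` and
channelwise by a factor `K` around a continuous or discrete bottleneck —
plus the evaluation surface (masked reconstruction error, sequence
recovery, RMSD/RMSPD/TM-score on coordinates) and latent-space experiments
(linear interpolation, token corruption).

## Per-channel normalization

For each channel `j`, extrema `x_min[j]`, `x_max[j]` are estimated over all
valid positions of a calibration sample, and values are mapped through the
affine min-max transform onto a common target interval:

```
x' = (x - x_min) / (x_max - x_min) * (c_max - c_min) + c_min
```

with `c_min = -1`, `c_max = 1` by default. Because statistics are
per-channel, outlier channels cannot dominate the scaling of ordinary ones.
One formulation in circulation parenthesizes the affine shift inside the
product, which would collapse the map to a plain scaling by `c_max`; since
the stated goal is rescaling *to* `[c_min, c_max]`, this package adopts the
standard min-max map above, under which calibration extrema land exactly on
the target bounds.

Numerical choices:

* **Divide guard.** Channels whose calibration range is below `1e-12` are
  flagged constant and mapped to `c_min`; inversion refuses them. This
  avoids NaNs while keeping the map invertible everywhere else.
* **No clipping.** Values outside the calibration range map outside
  `[c_min, c_max]` — deliberately, so no information is destroyed at
  inference time on unseen data.

```{r norm-demo}
d <- gen_embeddings(synthetic_config(n_samples = 8, n_channels = 64,
                                     outlier_channels = c(7, 33, 50),
                                     length_range = c(16, 32), seed = 1))
rep <- activation_report(d, k = 3)
rep$top_k$channel                 # the planted outlier channels
st <- estimate_channel_stats(d)
range(normalize_embedding(d$embeddings[[1]], st))
```

## The hourglass compression transformer

The encoder runs pre-norm transformer blocks at full length, then:

1. **Linear downsampling** (lengthwise): groups of `S` consecutive rows are
   flattened and multiplied by a learned `(S*D) x D` matrix — equivalent to
   a 1-D convolution with filter size and stride `S`.
2. **Mask reduction**: a shortened block is valid iff any of its `S` source
   positions is valid (sum-then-threshold).
3. **Attention resampling**: the shortened positions cross-attend over the
   full-length sequence, so they can gather what the strided projection
   discarded.
4. **Channel downprojection** `W_d` (`D x D/K`, no bias), giving the
   bottleneck input of width `d_c = D / K`.

The bottleneck is `tanh` (continuous), VQ-VAE, or FSQ. The decoder mirrors
the encoder: upprojection `W_u`, linear upsampling, mask expansion
(repeat-then-threshold), attention resampling of full-length queries over
the shortened keys, and transformer blocks. There are **no skip
connections** across the bottleneck — they would make reconstruction
trivial — so zeroing the code provably removes all input dependence from
the output (this is asserted in the test suite).

Design points the architecture sketch leaves open, resolved here as
configurable defaults:

* Transformer blocks are pre-norm with GELU feedforward (expansion 4 by
  default) and a learned relative-position bias clipped at `rel_window`;
  layer and head counts are configuration (`n_layers_enc/dec`, `n_heads`).
* The upsampling step is read as operating on the *upprojected* code (the
  alternative reading has inconsistent channel dimensions).
* `tanh` is applied only on the continuous path; FSQ applies its own tanh
  bound internally, and VQ quantizes the raw projection.
* `W_d`/`W_u` and the resampling matrices are scaled-orthogonal at
  initialization, attention/FFN weights `N(0, 0.02)`; all init is seeded.
* When `L` is not a multiple of `S`, inputs are zero-padded to the next
  multiple and the mask is extended with zeros; the reconstruction loss
  never includes padded positions. Masked attention assigns *exactly* zero
  weight to padded keys (the mask logit underflows `exp()` to 0), and rows
  are re-zeroed after every block, so padded content cannot leak into valid
  outputs — a property the acceptance tests check to `1e-6`.

```{r hpct-demo}
cfg <- hourglass_config(d_model = 64, shorten_factor = 2,
                        downproject_factor = 8, bottleneck = "tanh",
                        n_layers_enc = 1, n_layers_dec = 1, n_heads = 4,
                        rel_window = 8, ffn_mult = 2, seed = 1)
model <- init_hourglass(cfg)
x <- matrix(rnorm(30 * 64), 30, 64)
lat <- hpct_encode(model, x)
dim(lat$values)            # ceiling(30/2) x 64/8
compression_ratio(cfg, 30)
```

## Bottlenecks: tanh, VQ-VAE, FSQ

**tanh** bounds the code to `(-1, 1)`, which downstream latent-generative
models rely on.

**VQ-VAE** assigns each position the nearest codebook vector in Euclidean
distance (ties to the lowest index, deterministically). Training follows
the printed objective exactly: reconstruction loss (realized as masked MSE,
consistent with the HPCT objective) plus the codebook loss
`||sg[c] - e||^2` and the commitment loss `beta ||c - sg[e]||^2`
(`beta = 0.25` by default; the reference gives it only symbolically).
Gradients are straight-through: the reconstruction gradient is copied from
the quantized output to the continuous input; the codebook learns *only*
from the codebook loss. No EMA updates and no codebook resets are applied —
collapse is a finding to be observed (via utilization and VQ-perplexity),
not masked by interventions.

**FSQ** is parameter-free: per channel, `tanh` bounds the value and
rounding snaps it to one of `L_j` bins (`q = round(floor(L_j/2) * tanh(z))`
for odd `L_j`; even level counts use the half-integer offset scheme of the
original method, so odd defaults keep the plain formula). The implicit
codebook size is `prod(levels)`; the per-position token is the mixed-radix
encoding of the per-channel integers with channel 1 most significant. The
straight-through estimator wraps only the rounding — the tanh derivative is
kept. Because every bin is reachable from a bounded input range, wide
inputs force full codebook utilization, in contrast to VQ. The specific
level sets are configuration (`fsq_levels`, default 5 levels per channel).

Rounding uses R's `round()`; its round-half-to-even behavior differs from
round-half-away only on a measure-zero set of inputs and on no grid value,
so grid idempotence is unaffected.

```{r fsq-demo}
fsq_quantize(matrix(0.3), levels = 5)$ints   # round(2 * tanh(0.3)) = 1
vq_perplexity(c(3, 1))                       # exp entropy of code usage
```

## Training

Training is masked-MSE in normalized space, end to end through the
bottleneck, with AdamW (decoupled weight decay on weight matrices only) and
a linear warmup followed by a constant learning rate (the post-warmup
schedule is unspecified upstream; constant is the simplest consistent
reading). Defaults mirror the full-scale settings — `8e-5` with 5000 warmup
steps for continuous models, `1e-4` with 1000 for discrete ones — while the
desk-scale experiments in this package set small warmups (~100 steps) and a
`1e-3` rate explicitly, appropriate for models three orders of magnitude
smaller. Auxiliary sequence- and structure-space losses are deliberately
not implemented (they were found not to help materially upstream); the
objective is MSE only, plus the VQ auxiliary terms for discrete models.

All stochasticity (initialization, batching, corruption) flows from
explicit seeds; a fixed seed reproduces a loss trace bit-for-bit on one
device. Checkpoints bundle weights, the hourglass configuration and the
channel statistics, so compression artifacts are self-describing.

The per-residue **sequence decoder** is a two-affine-layer head (hidden
width 1024, GELU) with exactly 21 output classes (20 amino acids plus the
unknown placeholder), trained with cross-entropy on a seeded random 90/10
per-protein split. The **linear probe** harness mean-pools latents, applies
a trainable projection back to width 1024 (so probe capacity is matched
across compression levels), and fits a 2-layer MLP; regression tasks report
R-squared and Spearman correlation, classification tasks accuracy.

Both heads center their input features per channel and apply a single
global scale, fitted on the training split and stored with the head.
Centering is what neutralizes massive activations for these consumers
(their pathology is an enormous constant mean); a per-channel variance
rescale is deliberately avoided because it would inflate low-variance
noise directions to unit scale and drown the signal. Regression probes
additionally standardize the target on the training split and map
predictions back, which leaves R-squared unchanged but keeps optimization
well-conditioned when targets inherit large offsets from outlier channels.
Neither head uses weight decay: the targets are (near-)separable and decay
caps the margins.

## Structure metrics

* **RMSD** with optimal rigid-body superposition (Kabsch via SVD with the
  reflection-excluding determinant correction), or raw without.
* **RMSPD** compares all intra-structure pairwise distances; it needs no
  superposition and is therefore invariant under rigid motions — and blind
  to chirality (mirror images score 0), a documented limitation.
* **TM-score** with the standard normalization distance
  `d0(L) = 1.24 (L-15)^{1/3} - 1.8`, clamped below at 0.5 (covering short
  chains). Residue correspondence is assumed — reconstruction pairs share
  it — so no alignment search is run. The maximization over superpositions
  uses iteratively reweighted Kabsch fits with weights
  `1/(1 + (d_i/d0)^2)^2` (the stationary condition of the score), keeping
  the best score seen; the normalization length is that of the reference
  argument. Whether all-atom RMSD should cover all heavy atoms is left to
  the caller: the metrics operate on whatever atom set is supplied, with
  CA-only toy backbones as the built-in fixture.

## The synthetic generator: what it does and does not emulate

Every experiment in this package runs on seeded synthetic latents, built to
reproduce the statistical structure the compression stack actually relies
on:

* **Low intrinsic rank.** Rows are `c * f_t B^T + noise` with a shared
  orthonormal basis `B` of rank `r` (default 16); `c` scales the
  per-element signal variance to 1.
* **Token cluster structure.** Real per-residue latents cluster strongly by
  residue identity — that is why token information is recoverable from them
  at ~100% by a small head. The generator reproduces this: each residue's
  factor is one of 21 fixed cluster centers plus isotropic spread
  (`token_spread`, default 0.25), and each center is rejection-sampled
  (deterministically, under the seed) until its top-two label-score gap
  clears the within-cluster score spread by four standard deviations, so a
  residue's cluster — not boundary luck — determines its label. Without
  this margin structure, label boundaries estimated from finite data carry
  an irreducible few-percent error that real latents do not exhibit.
* **Massive activations.** A fixed set of outlier channels (default
  `c(274, 641, 37)`, the convention observed in real latents — whether
  three channels is universal across model scales is unknown, so the list
  is a parameter) receives a constant additive offset with alternating
  sign, calibrated so the outlier-to-median mean-magnitude ratio is at
  least `outlier_scale` (default 3000, matching the reported magnitude
  ratio). The offset is additive, not multiplicative, because the
  phenomenon is input-independent.
* **Recoverable token labels.** `labels = argmax(signal %*% P)` for a fixed
  Gaussian `D x 21` projection `P` on the noiseless, pre-offset signal —
  deterministic in the embedding, linearly recoverable, and (because of the
  cluster margins above) recoverable nearly perfectly by a trained head,
  giving the sequence decoder a non-trivial but learnable target and a
  clean 100% upper bound.
* **Toy structures.** Ideal helices (radius 2.3, rise 1.5/residue, 100
  degrees/residue) with rigid-motion copies, exercising the metric suite
  with known-zero answers.

What it does **not** emulate: the true activation distribution of any
particular pLM, residue chemistry, length-correlated structure, or the
coupling between embedding content and 3D coordinates. Passing tests
therefore demonstrate that the machinery is correct and that the documented
trends (compressibility of low-rank signal, bottleneck-width monotonicity,
FSQ utilization vs VQ) hold under controlled conditions — not that any
particular accuracy will be attained on real latents, which require
external model inference that is out of scope here.

## Desk-scale experiment sizes

The test-suite experiments use deliberately small problem sizes, chosen
once as realistic for the properties being measured: trainability runs use
32 proteins of 12–24 residues at `d_model = 64` with 2+2 layers, 400
optimization steps (well within the 2000-step budget the trainability
property allows), and the bottleneck-width sweep uses 200 steps with
3 seeds per width; the sequence-decoder experiment uses 120 noiseless
proteins of 24–48 residues at 64 channels. Larger configurations change
constants, not conclusions, for the properties asserted.

## Known limitations

* No GPU path and no minibatch vectorization across proteins; the
  optimizer is adequate for desk-scale models, not for `d_model = 1024`
  production training.
* The VQ codebook, faithful to the printed loss, can and does collapse for
  small codebooks — measured, not corrected.
* RMSPD's chirality blindness means a mirrored reconstruction scores 0.
* Interpolation operates in whatever space the caller supplies; the
  package does not hard-code the raw-vs-compressed comparison, it provides
  the pieces (`interpolate_latents()`, `smoothness_curve()`, the CLI
  `interp` recipe).
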