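---
title: "Model and methods: patch-based hyperspectral crop classification with semantic-guided attention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the model it implements, the
choices that were genuinely open, and what the synthetic tests do and do not
establish about real data.

## Data model and sampling

A scene is a reflectance cube (`rows × columns × bands`) with a co-registered
integer label map in which 0 marks unlabeled pixels and classes are 1-based.
The classifier input is the `s × s` patch centered on a pixel (`s` odd), and
the patch inherits the center pixel's label. Pixels near the border get
full-size patches by mirror (edge-included) reflection of the cube. We chose
reflection over zero padding because the attention block gates channels with
a sigmoid: zero "spectra" injected at the border would look like a real,
very dark material rather than absent data. Coordinates throughout the
package are 1-based `(row, col)`, the R convention.

Normalization is per-band min–max to [0, 1] over the whole cube, applied
before splitting; constant bands map to 0. It is the least parameterized
choice and keeps the inputs of sigmoid and attention nonlinearities bounded.
Water-absorption band lists for the AVIRIS benchmarks are shipped as
editable YAML (`inst/extdata/water_bands.yaml`), since the literature fixes
the retained counts (220 → 200, 224 → 204) but not the indices.

## The split rule

Per class with total `n`:

* `n_train = floor(f_train · n)`
* `n_val = floor(f_val · (n − n_train))` — a floor of the *remainder*
* `n_test = n − n_train − n_val`

This exact arithmetic is the only reading we found that reproduces every
per-class row of the published benchmark split tables (for example,
Corn-notill 1428 → 142/128/1158; a validation floor on the class total would
give 142 instead of 128 for the validation column). Membership is drawn
uniformly at random under a seed, so subset sizes are seed-independent while
membership is seed-dependent — which is what makes repeated experiments
meaningful. The tables themselves ship with the package
(`benchmark_split_tables()`) and the reproduction is asserted in the test
suite.

## MSIE: the multi-branch feature extractor

All convolutions have 64 filters, stride 1, size-preserving padding, and a
ReLU. The four branches over an `s × s × c` input:

1. 1×1 convolution → 3×3 average pooling. The pooling divisor is the number
   of *valid* (in-image) cells, so constant fields stay constant at the
   borders; zero-diluting padding would darken patch edges.
2. 1×1 convolution only (pure spectral mixing).
3. 1×1 stem, then 1×3 and 3×1 convolutions **in parallel**, summed.
4. 1×1 stem, then a **serial** 1×3 → 3×1 chain; the intermediate (post-1×3)
   and final maps are summed.

Branch outputs are merged by element-wise summation (all emit 64 channels).
The parallel/serial readings for branches 3 and 4 are declared
interpretations: the textual description of the block admits more than one
wiring, and we pinned the one whose total parameter count matches the
published 0.22 M budget (a serial-then-extra-parallel-pair reading of
branch 4 overshoots it). There is no batch normalization anywhere; adding it
would also break that budget.

The ablation substitute for MSIE is a two-layer standard 3×3 convolution
(c → 64 → 64) with the same size-preserving contract.

## SGA: the semantic-guided attention block

The stage input is flattened row-major to `s²` tokens of width `c`:

1. **Channel gate**: `x_c[i, j] = sigmoid(w_c[j]) · x[i, j]` with a
   learnable `w_c ∈ R^{1×c}` that filters spectral channels. The block's
   defining equations use one symbol for two roles; we resolved the gate to
   `w_c` because it is the only dimensionally consistent reading (`w_c` has
   length `c` and cannot gate the widened `(c+1)`-column tokens, so gating
   must precede the concatenation below).
2. **Pixel weight**: a learnable `w_p ∈ R^{s²×1}` is appended as the *last*
   token column (the position is not fixed by the block's description;
   last-column is declared here and tested).
3. **Encoder**: one pre-normalized transformer layer,
   `z = x_p + MultiHead(LN1(x_p))`, `out = z + MLP(LN2(z))`, with a single
   head, depth 1 (both configurable), a GELU MLP of hidden width 152, and no
   positional encoding — the block is deliberately permutation-equivariant,
   and `w_p` is the only carrier of spatial identity.
4. **Weight map**: the sigmoid of the last column of `out`, reshaped
   row-major to `s × s`. Every entry is strictly inside (0, 1). The other
   encoded channels are discarded: the weight map is the block's sole
   product, and each stage multiplies its MSIE output by it (one map per
   stage, broadcast over all 64 channels).

The MLP hidden width 152 is pinned so the full model lands on the published
0.22 M parameter budget for all three benchmark configurations
(IP 222,828; SA 223,196; PU 216,501 — all round to 0.22 M). `w_p` and `w_c`
are independent per stage.

## Assembly, training, and metrics

`sgtn_forward`: 1×1 spectral reduction (bands → 64, ReLU) → stage 1 →
stage 2 → global average pooling → FC(64→32, ReLU) → FC(32→classes), logits
out; softmax lives in the loss and metrics. Both branches of a stage consume
the stage input (the main branch is MSIE, the other is SGA).

Training: mini-batch Adam, learning rate 0.001, batch 64, cross-entropy,
100 epochs by default ("iterations" in the protocol is read as epochs, since
it is stated alongside a batch size). The checkpoint with the best
validation OA is evaluated on test — the protocol describes a validation
split but not its use, and best-checkpoint selection is the standard
reading. Each of the five protocol repeats redraws the split *and*
reinitializes the model under its own seed; subset sizes are
seed-independent, so the reported standard deviations require membership
variation. No learning-rate schedule, weight decay, or augmentation.

Metrics: `OA = tr(C)/n`; `AA` is the unweighted mean of per-class recalls
(empty classes are excluded with a warning); `κ = (p_o − p_e)/(1 − p_e)`.
`κ ≤ OA` for every matrix with `p_e > 0`, and the implementations are
checked against `e1071::classAgreement` and `caret::confusionMatrix` to
1e-12 on random matrices.

## Numerical and implementation choices

* The network forward/backward passes are authored here: 1×1 convolutions
  are BLAS matrix products over token matrices; spatial convolutions use
  im2col gathers; gathers, scatter-adds, bias+ReLU, pooling, GELU, layer
  norm, and per-patch attention are C++ kernels (`src/ops.cpp`), the last
  calling BLAS `dgemm` per token block. Everything is double precision.
* Gradients of every parameter group are verified against central finite
  differences (relative tolerance 1e-4) in the test suite; attention,
  convolutions, and the full block structure are additionally checked
  against brute-force nested-loop oracles.
* Initialization: Kaiming-uniform fan-in for convolution and linear weights,
  zero biases, `w_p = w_c = 0` (so the channel gate and weight map start at
  0.5). The residual output projections of the encoder (`W_O` and the second
  MLP linear) start at 0.1× Kaiming scale so the encoder output is
  near-identity and the weight map opens near-neutral; at full scale the
  sigmoid gate saturates at random values per token, which multiplies the
  main branch by noise and can stall optimization — we observed exactly this
  failure mode on harder scenes before adopting the scaled initialization
  (a standard device in transformer practice).
* Softmax uses a max-shift; ReLU subgradient at 0 is 0; argmax ties break
  toward the lowest class index.
* All randomness (weights, splits, shuffling, scenes) flows through explicit
  integer seeds, and seeded initializers restore the caller's RNG state.

## The synthetic-scene generator

`generate_scene()` emulates the features of the benchmark scenes the model
is sensitive to: per-class smooth spectral signatures (sums of Gaussian
bumps over band index), spatially contiguous class regions (rectangle tiling
or Voronoi cells, mimicking fields), pairs of spectrally confusable classes
(one class's signature is the other's with bump centers shifted by a small
offset), additive white Gaussian noise, and an unlabeled background whose
pixels keep their region spectrum. It does **not** model spectrally
correlated noise, mixed pixels/endmember abundances, sensor striping,
atmospheric effects, or class-dependent texture. Passing the synthetic
end-to-end tests therefore establishes that the pipeline, optimization, and
metrics are correct and that the architecture can exploit spatial context —
not that benchmark-level accuracies transfer to real sensors.

## Problem sizes used by the tests

The end-to-end recovery check uses a 64×64 scene, 32 bands, 5 well-separated
classes, noise SD 0.05, patch side 9, a 10 %/10 % split, 15 epochs, and five
seeds (test OA ≥ 0.90 required in at least four). The ablation-direction
check uses a 64×64 scene with 6 classes and two strongly confusable pairs
(bump-center offset 0.5 band at bump width 4, noise SD 0.25 — chosen so that
nearest-signature per-pixel classification fails on the pairs, the regime
the attention block targets), 3 seeds, and compares mean test OA of the full
model against the SGA-disabled variant. These sizes were chosen as the
smallest scenes that still exhibit the phenomena of interest; the published
benchmark protocol itself (five repeats × 100 epochs on the real cubes) is
available via `scripts/benchmark_protocol.R` for users with the data.

## Known limitations

* MAT v7.3 (HDF5) containers are not readable; convert to v5 or ENVI.
* Single-threaded CPU training: full benchmark runs take hours.
* The two open wiring questions (MSIE branch topology, the gate's symbol
  clash) are resolved as described above; alternative readings would change
  the parameter count away from the published budget.
* `predict_map` classifies every pixel, including unlabeled background, so
  rendered maps outside labeled regions are extrapolations.
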