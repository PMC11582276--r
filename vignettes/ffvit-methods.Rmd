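---
title: "Estimating pCLE probe orientation from image blur: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating pCLE probe orientation from image blur: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffvit)
```

## The problem

Probe-based confocal laser endomicroscopy (pCLE) images cellular-scale tissue
morphology through a fiber-bundle miniprobe during surgery. Image quality
depends critically on holding the probe perpendicular to the tissue surface:
a tilt about the probe's x axis defocuses one lateral half of the frame more
than the other, and a tilt about the y axis does the same top-to-bottom,
because parts of the tissue drift out of the confocal plane. This package
regresses the two tilt angles, in degrees, from a single grayscale frame —
no force sensor, no external camera, no 3D reconstruction — so that a
robotic scanner can servo the probe back to perpendicular.

The estimator is a frequency-domain vision transformer. Blur is
fundamentally a spectral phenomenon (defocus suppresses high spatial
frequencies), so each image patch is represented by its Fourier spectrum
rather than its pixels; a transformer then compares patches against each
other (self-attention) and against an explicit per-patch blur measurement
(cross-attention) to locate and quantify the blur gradient that encodes the
tilt.

## Model

**Input geometry.** Frames are single-channel, nominally 256×488 as
acquired, center-cropped to 256×448 so that 32×28 patches tile the image
into an 8×16 grid of `Np = 128` patches. (The grid arithmetic is exact only
at width 448; the crop discards 20 border columns on each side, which lie
outside the circular fiber-bundle field of view anyway.)

**Spatial-shift augmentation.** The frame is stacked with four copies
shifted by 1 px (up, down, left, right, zero-filled at vacated borders),
giving 5 channels. Shifted copies sharpen the embedding's sensitivity to
local gradient structure; zero fill was chosen over reflect fill as the
less informative (hence less distorting) boundary convention.

**Frequency-domain patch embedding.** Each 5×32×28 patch is transformed by a
real-input FFT per channel, keeping the non-redundant half spectrum
`32×(28/2+1)`; real and imaginary parts are stacked into 10 channels,
flattened (4800 values), layer-normalized, and linearly projected to the
token width `C = 192`. A learnable cls token (drawn once from N(0, I) at
initialization) is appended, giving 129 tokens.

**Transformer backbone.** A single learnable position vector `v_p ∈ R^C` is
added to every token (one shared vector, not a per-position table — the
blur-gradient cue is translation-structured, and in practice the patch
identity is carried by the spectra themselves). Then 12 post-norm blocks
follow. Each block projects tokens to Q, K, V with one `C×3C` matrix, splits
3 heads of width 64, forms logits `QK^T` scaled only by a learnable per-head
temperature τ (initialized at √64 = 8, replacing the usual fixed 1/√d), masks
the diagonal to −∞ so no token attends to itself (self-similarity otherwise
swamps the informative cross-patch comparisons at this training scale), and
applies softmax. The attended values pass an output projection, residual +
layer norm, then an MLP `192→768→192` (GELU) with residual + layer norm.

**Blur map and its embedding.** Independently of the network, a
no-reference blur score is computed for each 32×28 tile: the tile is
re-blurred with a 9-tap uniform separable kernel and the fraction of
neighbor-difference energy that survives is measured — an already-blurry
tile loses little and scores near 1, a sharp tile near 0; a constant tile
scores 1 by convention. Each of the 128 scores is quantized to 100 levels
and replaced by the sinusoidal absolute positional encoding of its level at
width C (quantization is what makes an *absolute positional* encoding of a
continuous value well defined; 100 levels keep the quantization error an
order of magnitude below the score's sensitivity to a 0.5° tilt step).

**Pyramid angle regressor with blur-mapping attention.** Three supervised
scales. At each scale: a cross-attention block takes queries from all
tokens and keys/values from the blur tokens (no diagonal masking — token i
*should* read its own patch's blur), with the same residual/MLP structure as
a backbone block; the cls token is set aside while the patch grid is
compressed — width-3 stride-1 average pooling along grid rows (w → w−2)
followed by channel-concatenation of adjacent row pairs projected `2C→C`
(h → h/2) — then re-attached; two self-attention blocks mix the compressed
tokens; and two regression heads emit scalar angles, one from the mean of
the patch tokens and one from the cls token. The grid ladder over scales is
8×16 → 4×14 → 2×12 (with 0–3 compressions: 8×16, 4×14, 2×12, 1×10). Blur
keys at compressed scales are the original blur map pooled with exactly the
compression footprint (width-3 mean, then row-pair mean), re-embedded, so
key counts always match the patch count. The final output is the cls head
of the last scale.

Two readout choices are genuinely open in this design: how many
self-attention blocks follow each compression, and the form of the
regression heads. We fix two blocks per scale — the coarser grids carry
more abstract summaries and benefit from extra mixing before readout — and
2-layer MLP heads with the same 768 hidden width as the block MLPs, keeping
the readout consistent with the rest of the network. This places the full
model's budget at 11.3 M parameters, in the ≈11 M class the architecture
is designed for (single blocks with linear heads would land near 9 M).

```{r params}
cfg <- ffvit_config()
P <- ffvit_init(cfg, seed = 1)
ffvit_n_params(P) / 1e6
```

**Loss.** With N scales, predictions `theta^n_m` (m ∈ {patch, cls},
n = 0..N−1) and ground truth θ:
`L = 1/(2N) Σ_m Σ_n γ^n |θ − θ^n_m|`, γ = 0.5. The sum runs over the N
scales that exist (six predicted terms at N = 3), and the 1/(2N) prefactor
makes L the γ-weighted mean absolute error of the individual heads.

**Training.** AdamW (decoupled weight decay 0.01 applied to weight matrices
only), L1 objective as above. The reference recipe is batch size 512 at
learning rate 1e-4; desk-scale runs use proportionally smaller batches with
a correspondingly larger step (see below).

**Two-axis inference.** The network is trained on left-right blur contrast.
At inference, two crops of the source frame are batched through the shared
network: `I_x`, a full-width centered horizontal band (50% of the height),
preserves the left-right contrast and yields θx; `I_y`, a full-height
centered vertical band, is transposed — mapping its top-bottom contrast onto
the network's left-right axis — and yields θy. Transposition rather than a
second network keeps one set of weights sufficient; the band fraction is
configurable and warns below 25%.

**Acting on the estimate.** A scanning robot whose rotation pivot sits at
its base sweeps the probe tip across the tissue when correcting orientation.
Translating the base by `Δx = −l sin θ`, `Δy = l (cos θ − 1)` during a
rotation θ (arm length l from base to tip) relocates the pivot to the probe
tip: the tip stays on its tissue spot, `Δy` is always non-positive, and
`(Δx, Δy + l)` stays on the radius-l circle.

## The synthetic frame generator

The real orientation-labelled pCLE recordings are not distributable, so the
package ships a generator that emulates the one property the estimator
relies on: *a tilt produces a monotone lateral (or vertical) gradient of
defocus across the field of view*. Bright Gaussian blobs (amplitude
0.35–1, radius 0.8–2.2 px) approximate Acriflavin-stained cellular speckle
at 8 blobs per 1000 px², inside a circular field of view of radius 0.95×
half the short image side; the area outside the fiber bundle is dark. A
spatially varying Gaussian blur is applied whose width at pixel (r, c) is

    sigma(r, c) = base + gain * (theta_x (cx − c)/W + theta_y (cy − r)/H)

with base 1.5 px and gain 0.25 px/degree, then Gaussian intensity noise
(sd 0.01) is added and values are clipped to [0, 1]. The sign convention —
positive θx makes the *left* half blurrier, positive θy the *top* half — is
a package convention fixed so that direction accuracy is well defined on
synthetic data. `base` and `gain` are chosen so that sigma stays strictly
positive over the ±10° range (no clipping plateau), making the
tilt-to-blur-asymmetry map strictly monotone; the linear dependence of
sigma on tilt is an assumption, not measured optics. The spatially varying
blur is approximated by blending a bank of 9 uniformly blurred copies with
per-pixel linear interpolation in sigma — exact at the bank levels,
first-order in between.

What the generator does *not* emulate: fiber-bundle honeycomb structure,
staining inhomogeneity, motion artifacts, tissue deformation, specular
highlights, or the true (unknown) tilt-to-defocus optics of a Cellvizio
miniprobe. Tests passing on synthetic data therefore demonstrate that the
*estimator recovers the tilt signal the generator encodes* — correctness of
the machinery, not clinical performance.

Frames are bit-reproducible from (parameters, angles, seed); dataset sweeps
cover −10°..10° in 0.5° steps (41 grid points per axis) with per-frame seeds
derived from a base seed, so disjoint base seeds give disjoint train/test
streams.

## Focus metrics and the working range

Five classical no-reference focus measures support a distortion study across
a tilt sweep: MoI (intensity moment of inertia about the intensity
centroid), NFBM (the re-blur comparison score above), H-FFT (fraction of
non-DC spectral energy above one quarter of Nyquist, configurable), LAPV
(variance of the 4-neighbor Laplacian), and GEDR (gradient energy of the
image over that of a σ=1 re-blurred copy). All are offset-invariant except
MoI. The distortion rate between adjacent sweep angles is the absolute
difference of metric values normalized by the series mean magnitude (in %);
the working range is the widest symmetric interval around 0° in which every
rate stays below half (configurable) the mean rate outside. The max-inside
form, rather than mean-inside, is what makes a flat-band-plus-steep-tail
series return exactly its flat band; an everywhere-flat series returns the
full span.

## Numerical choices

* Layer norm uses ε = 1e-5; the normalized value of an all-zero row is zero,
  so a zero image embeds to exactly the projection bias.
* Softmax rows are computed with row-max subtraction; masked (−∞) logits
  contribute exact zeros and each row sums to 1 within 1e-6.
* τ ≤ 0 is clamped to 1e-4 with a warning (it never triggers under AdamW at
  the tested scales).
* GELU is the exact Φ form; its derivative is Φ(x) + x φ(x).
* The L1 loss uses the sign subgradient (0 at exact equality).
* Gradient correctness of the entire backward pass is enforced by a central
  finite-difference test on a miniature architecture; parameters whose
  analytic gradient is below 1e-7 are compared absolutely, since the
  numerical quotient there is dominated by floating-point cancellation.
* `max.col(…, ties.method = "first")` is used for row maxima so that no RNG
  state is consumed inside the forward pass; all stochastic stages
  (initialization, shuffling, generation) run under locally scoped seeds and
  restore the caller's RNG state.

## Desk-scale study conditions

All empirical checks in the package run a reduced configuration chosen to
train in minutes on one CPU while exercising every component: input 64×112,
16×14 patches (4×8 grid, 32 patches), C = 64, depth 2, 2 heads, MLP 256,
one latent compression (two scales), 0.56 M parameters. The surrogate
recovery study trains on a 1640-frame x-axis sweep (40 frames per 0.5° step)
for 10 epochs at batch 32 and learning rate 1e-3, and evaluates on 328
held-out frames (8 per step) from a disjoint seed stream. Two ingredients
matter at this scale:

* **Mirror augmentation** (`augment = "flip"`): a left-right mirrored frame
  with negated angle is, by the generator's construction, exactly another
  valid frame; presenting each training frame per epoch in a random
  orientation doubles texture diversity and anchors the sign decision
  boundary at zero. Without it the model's held-out direction accuracy
  plateaus in the low 70s (the generalization gap, not optimization, is
  binding: longer training keeps lowering the training loss without moving
  held-out accuracy).
* **Global gradient-norm clipping** (`clip_norm = 1`) **and a one-epoch
  linear learning-rate warmup** (`warmup_epochs = 1`): at small batch sizes
  the occasional exploding step otherwise throws the network into the
  constant-prediction attractor of the L1 loss (predicting the target
  median everywhere), from which it rarely escapes; post-norm transformers
  are particularly sensitive in their first few hundred steps, and some
  initialization seeds collapse without the warmup. Learning rates of
  3e-3 and above diverge even with the larger batch; 1e-4 (the full-scale
  recipe at batch 512) is stable but too slow for a 10-epoch budget at
  batch 32.

Success criteria are direction accuracy ≥ 80% (chance 50%) and MAE below
the predict-zero baseline (the mean |θ| of the sweep, ≈5.1°). A closed-loop
check applies the negated predictions as corrections and verifies the mean
residual tilt shrinks accordingly. For orientation, an oracle linear
regression on blur-map column means reaches only ≈80% direction accuracy
under the same conditions, so the transformer's spectral features are doing
real work beyond the explicit blur map.

## Known limitations

* The generator's linear tilt-to-blur model is an assumption; nothing here
  validates transfer to real endomicroscopy optics or stained tissue.
* The parameter-budget-guided readout (two post-compression blocks, MLP
  heads) is the most parsimonious reading consistent with the stated budget,
  not a published description.
* Training is CPU-bound, single-threaded R; the full-size configuration is
  instantiable and runs forward passes, but training it to convergence is
  out of desk-scale scope.
* The pyramid requires an even grid height and width ≥ 3 at every
  compression; configurations violating the ladder are rejected with an
  error rather than padded.
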