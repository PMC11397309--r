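---
title: "Models and methods behind leafpad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind leafpad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafpad)
```

leafpad implements an end-to-end pipeline for classifying foliar disease in
RGB leaf imagery: classical image enhancement, pixel-space augmentation, a
denoising-diffusion generator for data augmentation, a parallel-attention
Transformer classifier trained with a composite objective, and the
evaluation machinery around it. This vignette explains the models, the
choices that were genuinely open, and what the synthetic-data experiments
do and do not demonstrate.

## Image representation and preprocessing

Images are integer rasters with levels $0..L-1$ ($L = 256$ throughout).
The network path uses float tensors in $[-1, 1]$, via $x \mapsto 2p/(L-1)-1$;
the symmetric range matches the zero-mean Gaussian noise the diffusion
process injects, and the raster–tensor roundtrip is exact up to one level.

Four classical operators are provided:

* **Histogram equalization** maps level $k$ to
  $\mathrm{round}((L-1)\,\mathrm{CDF}(k))$ under the empirical cumulative
  histogram. For RGB input the default policy equalizes the BT.601 luma and
  rescales chroma proportionally, since independent per-channel
  equalization shifts hue (a per-channel mode exists).
* **Contrast stretching** maps $[r_{\min}, r_{\max}]$ affinely onto
  $[0, L-1]$, clipping outside values first. The conventional division form
  $s = (r - r_{\min})/(r_{\max} - r_{\min}) \cdot (L-1)$ is used; the
  bounds default to the image's own extremes.
* **Median filtering** over $k \times k$ neighborhoods (replicate padding).
* **Gaussian filtering** with kernel $\propto e^{-(x^2+y^2)/2\sigma^2}$,
  truncated at radius $\lceil 3\sigma \rceil$ and renormalized.

Two conventions are fixed globally: rounding is always half-up wherever
levels are produced (base R rounds half-even, which breaks exact-oracle
comparisons), and border handling is replicate padding (zero padding would
darken the borders of small test images).

## Augmentation

CutOut zeroes a rectangular region ($I_{\text{new}} = I \odot (1-M)$);
CutMix splices a region from a second image
($I_{\text{new}} = M \odot I_A + (1-M) \odot I_B$); Mosaic tiles regions
of four images split at a random center point. Masks have *exact* pixel
counts: the requested area fraction is honored even when no integer
rectangle fits, by trimming part of the rectangle's last row. Labels
become probability vectors: CutMix mixes labels by the mask-area fraction
$\lambda = \mathrm{area}(M)/HW$, Mosaic by quadrant-area fractions. Mixing
labels is the standard semantics; training on composited images with a
single hard label would be ill-posed. The mosaic center is confined to the
central 50% band so every quadrant contributes a nonempty region.
Augmentation operates in pixel space, before tensor normalization.
Defaults (probability 0.5, area fraction drawn from $[0.1, 0.4]$) are
config-exposed conventions, not measured quantities.

## Diffusion model

The forward chain adds Gaussian noise over $T = 64$ steps,
$q(x_t \mid x_{t-1}) = \mathcal N(\alpha_t x_{t-1}, (1-\alpha_t) I)$,
and the reverse step reconstructs
$x_{t-1} = \frac{1}{\alpha_t}\left(x_t -
\frac{1-\alpha_t}{\sqrt{1-\alpha_t^2}}\,\hat\epsilon_\theta(x_t, t)\right)$.

This mean-coefficient parameterization (the package's **literal**
convention, the default) is deliberately kept as stated, although it
differs from the standard DDPM scaling by $\sqrt{\alpha_t}$ — the forward
and reverse relations above are not mutually consistent under the standard
derivation, and the reverse relation is not the algebraic inverse of the
forward marginal. A **ddpm** convention flag switches both relations to the
sqrt-parameterization, under which predicting the exact injected noise
recovers $x_0$ exactly; tests that rely on that identity use the flag.
Marginal moments are maintained by the recursions
$m_t = \prod_{s\le t} c_s$ and $v_t = c_t^2 v_{t-1} + (1 - \alpha_t)$
(with $c_t$ the per-step mean coefficient), verified against their
unrolled closed forms and by Monte-Carlo moment tests.

The $\epsilon$-prediction network is convolutional: a 1×1 in-projection to
128 channels, a body of 3×3 convolutions at 128 channels with ReLU, and a
1×1 out-projection, with a sinusoidal timestep embedding projected to a
per-channel bias. Three choices were open and resolved as follows:

* 3×3 convolutions cannot simultaneously use *no padding* and keep the
  image size constant; padding 1 is the only option satisfying size
  constancy and is used.
* One network is shared across all 64 steps, conditioned on $t$ through
  the embedding, rather than 64 per-step networks — the parameter-sane
  reading of "a small network per step".
* The reverse-process variance is fixed to the forward-posterior variance;
  only the mean is learned.

Training minimizes a Monte-Carlo estimate of the variational lower bound
$\sum_t \mathrm{KL}[q(x_{t-1}\mid x_t, x_0)\,\|\,p_\theta(x_{t-1}\mid x_t)]
- \log p_\theta(x_0 \mid x_1)$, with one uniformly drawn step per batch
element (the $t=1$ draw contributes the Gaussian decoder term), reported
per pixel. The schedule default — $\alpha$ linear from 0.999 to 0.95 —
keeps $m_T \approx 0.09$ (strong noising) while $v_t$ stays bounded; no
reference value exists for these, so they are config-exposed.

Sampling starts from $x_T \sim \mathcal N(0, I)$ and applies the reverse
step $T$ times (one denoiser evaluation per step), clipping the final
output to $[-1, 1]$. For classifier training, diffusion augmentation is a
label-preserving round trip: forward-noise a real training image to
$T/4$, then denoise back, producing a variant with subtle differences
while keeping its label — a class-unconditional generator cannot label
free samples.

## Parallel-attention Transformer

Images are cut into $p \times p$ patches ($T_{\text{seq}} = (I/p)^2$
tokens), linearly embedded to $d_{\text{model}} = 512$ (8 heads × 64), and
a learned positional embedding is added (the architecture description is
silent on positional information; learned embeddings are the least-
structured choice). Each of 12 encoder blocks runs $N$ parallel multi-head
attention branches on the same input:
$\mathrm{Attention}_i = \mathrm{softmax}(Q_i K_i^\top/\sqrt{d_k}) V_i$,
fused by weighted summation with softmax-normalized weights. The two
printed facts — a 512-wide concatenation of 8 heads, and fusion by
weighted summation — are reconciled the only way they can be:
heads *within* a branch concatenate to 512; branches *across* are
weighted-summed. $N$ defaults to 3, motivated by the color/texture/shape
branch narrative; every branch has independent Q/K/V/output projections.

Block order is pre-norm ($x + \mathrm{Attn}(\mathrm{LN}x)$, then
$x + \mathrm{FFN}(\mathrm{LN}x)$, FFN 512→2048→ReLU→512), and the forward
pass is validated end to end by a finite-difference gradient check (the
backward passes are hand-written). Classification mean-pools the final
tokens into $K$ logits — no class token, which keeps the reconstruction
head symmetric: reconstruction is a linear map of the same final tokens
back to patches. Three attention modes support the ablation axis:
**self** (one branch, a standard ViT-style encoder), **cross** (two
branches; the second takes keys and values from the embedded
histogram-equalized version of the same image — the enhancement-stream
reading of cross attention), and **parallel** ($N$ fused branches).
Parameter counts increase strictly in that order. A **temporal** fusion
mode weights branches by $w_j = \mathrm{softmax}_j(-(a\,\Delta T_j +
b\,\Delta D_j))$ over history deltas; it is exposed as an optional mode
and off by default, since history weighting is a time-series construct
with no defined role in single-image classification.

## Training objective and loop

The composite ("parallel") loss is
$L = \lambda_{\text{cls}} L_{\text{cls}} + \lambda_{\text{recon}}
L_{\text{recon}} + \lambda_{\text{adv}} L_{\text{adv}}$ with defaults
$(1.0, 0.5, 0.1)$ (no reference values exist; these are config-exposed).
$L_{\text{cls}}$ is soft-label cross-entropy, $L_{\text{recon}}$ the MSE
between reconstruction and input, and $L_{\text{adv}}$ the non-saturating
generator loss $-\log \sigma(D(\text{recon}))$ against a 3-layer
strided-conv discriminator on reconstructions vs. real images (updated
once per generator step) — the smallest standard instantiation, since no
discriminator is specified anywhere. The discriminator exists only in
parallel loss mode, is initialized from an independent seed stream, and
receives updates only when $\lambda_{\text{adv}} > 0$; consequently a
parallel-loss run with weights $(1, 0, 0)$ is bit-identical to a plain
cross-entropy run, which a test asserts. Ablation losses: plain
cross-entropy, and focal loss $-(1-p_t)^\gamma \log p_t$ (exactly
cross-entropy at $\gamma = 0$).

The learning rate follows $0.001 \times 0.9^{\lfloor e/10 \rfloor}$.
The default optimizer is Adam: the reference training setup names a
PyTorch workflow with initial rate 0.001 — Adam's conventional default —
and names no optimizer; plain SGD with momentum at transformer-typical
widths fails to move the loss at that rate, so Adam is the faithful as
well as the practical reading (SGD with momentum 0.9 remains available
via `train$optimizer = "sgd"`). L2 weight decay is $10^{-4}$ and dropout
0.1 on attention and feed-forward outputs (both techniques are named
without rates; these are the community-standard values). Dropout, data
order, augmentation draws and initialization all derive from one master
seed, so single-threaded runs are bit-reproducible.

Splitting uses largest-remainder apportionment (70/15/15 by default) with
class stratification, reconciled so the global sizes are exactly the
apportionment of $n$ while per-class proportions stay within one record.
Both evaluation protocols are supported: the 70/15/15 holdout and
stratified 5-fold cross-validation (every record validates exactly once).
Metrics are macro-averaged precision/recall/F1 plus accuracy, confusion
matrix, and one-vs-rest ROC/PR curves; a class absent from both truth and
prediction has undefined precision/recall and is excluded from macro
means. Macro averaging is a documented choice — reported single P/R/F1
values for a 6-class task are not reproducible from any averaging
convention we could identify (with P = 0.95 and R = 0.92 the harmonic
mean is 0.9348, not 0.94), so the convention cannot be recovered from the
printed numbers.

## Synthetic leaf generator

The field dataset behind the reference results is not deposited, so the
package ships a seeded class-conditional generator: an elliptical leaf on
a soil-colored background, with per-class lesion statistics (count
$\sim$ Poisson($\lambda$), radius range in pixels, RGB color mean/sd,
shape disc/ring/blotch) and global Gaussian pixel noise. The six default
classes are mnemonic stand-ins for common jujube foliar diseases (powdery
mildew = pale blotches, black spot = dark discs, anthracnose = brown
rings, rust = many small orange discs, leaf mottle = yellow blotches,
stem rot = few large dark-brown blotches), with per-class counts
configurable to a field tally such as (897, 901, 1082, 1169, 1043, 965).
A single **difficulty** scalar interpolates lesion colors toward the leaf
color, making separability controllable for graded tests.

What the generator emulates: class-conditional color/shape/count
statistics, leaf-background structure, pixel noise, controllable class
balance. What it does not: photorealism, illumination and pose variation,
occlusion, multiple diseases per leaf, seasonal progression. Passing the
synthetic-recovery tests therefore demonstrates that the pipeline can
learn class-conditional lesion statistics end to end — not that it
reaches any particular accuracy on field imagery.

## Experiment sizes and expectations

The test-suite experiments are sized for a single CPU:

* **Parameter recovery**: 200 two-class 32×32 images (black spot vs.
  rust, fully distinct colors), a tiny parallel-attention model (2
  layers, 2 heads, head dimension 16, 3 branches), 30 epochs, batch 16,
  no pixel augmentation (recovery isolates the classifier; label-mixing
  augmentation would confound it). Validation accuracy reaches ≥ 0.9 on
  every seed 0–2; in our runs it reaches 1.0.
* **Loss ablation**: 600 six-class 32×32 images at difficulty 0.6, same
  tiny model, 12 epochs, batch 32, three seeds per loss mode. The
  expectation is directional only — mean macro-F1 ordered parallel ≥
  focal ≥ cross-entropy — because at this scale per-seed variance is
  large; the composite loss's reconstruction and adversarial terms act as
  regularizers that help most when lesions are hard to see.
* **Diffusion moments**: $10^4$ pooled pixel samples per schedule, five
  random schedules, 3-standard-error bands.
* **Denoiser training**: 8 grayscale 8×8 images, 10 epochs, fixed
  evaluation noise so per-epoch losses are comparable.

## Numerical details and degenerate inputs

* Softmax is computed with max-subtraction; cross-entropy clips
  probabilities at $10^{-12}$; the adversarial loss uses the stable
  softplus form.
* `reverse_step` refuses $\alpha_t = 0$ (division by zero) and
  $\alpha_t = 1$ with a nonzero noise prediction (degenerate
  denominator); the VLB requires $\alpha_t < 1$ at sampled steps.
* Largest-remainder ties break by bin order; grid-search ties by
  lexicographic cell order; `which.max` semantics make both
  deterministic.
* Gradient checks compare analytic and central-difference gradients at
  relative tolerance $10^{-4}$ on tiny configurations, for the plain,
  cross-attention, adversarial and diffusion paths.

## Known limitations

* Pure-R training limits practical problem sizes to desk scale; the
  package is a reference implementation, not a production trainer.
* The literal diffusion convention reproduces the stated equations but is
  not self-consistent; generative quality under it is not meaningful, and
  no FID-style evaluation is attempted.
* The adversarial component is the minimal standard design; GAN dynamics
  at these scales are noisy, and $\lambda_{\text{adv}}$ defaults low.
* Growth-state scoring is treated as a second K-class classification over
  growth-stage specs; no regression target is defined anywhere we could
  anchor one.
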