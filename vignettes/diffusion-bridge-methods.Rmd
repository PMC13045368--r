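---
title: "Omics-conditioned diffusion bridges: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Omics-conditioned diffusion bridges: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Histopathology image patches live in visually distinct *domains*:
cryosection versus FFPE preparation, H&E versus IHC stains, one tumor
type versus another. Beyond these categorical domains, the appearance of
tissue also reflects *molecular* state — which genes carry somatic
mutations, and how strongly transcriptional programs are expressed.
`histobridge` implements a single conditional denoising-diffusion model
that translates patches between any pair of such conditions, including
counterfactual "edits" in which only a mutation bit or an expression
value is changed between the source and target condition.

## The model

A denoising diffusion model corrupts an image $x_0$ through a variance
ladder $\bar\alpha_t$ (the cumulative product of per-step retention
factors $1-\beta_t$), so that
$x_t = \sqrt{\bar\alpha_t}\,x_0 + \sqrt{1-\bar\alpha_t}\,\varepsilon$.
A U-Net $f_\theta(x_t, t; c, G, T)$ is trained to predict the injected
noise $\varepsilon$ by mean-squared error, with timesteps drawn
uniformly. The conditioning information enters every residual block: a
combined embedding vector is projected by a per-block linear layer and
added to the block's hidden activations, alongside the sinusoidal
timestep embedding. The combined vector is the sum of three parts:

* **categorical**: a learned per-label embedding table;
* **genomic**: $\sum_i \mathrm{MLP}_{gen}(e_{g_i}\ \text{or}\
  \tilde e_{g_i})$ over the registered gene set, where each gene owns a
  wild-type embedding $e_g$ and a mutant embedding $\tilde e_g$ selected
  by its Boolean mutation status;
* **transcriptomic**: $\sum_i \mathrm{MLP}_{txn}(e_{g_i}) \odot
  \mathrm{MLP}_{exp}(e_{g_i}, t_i)$, where $t_i$ is the
  quantile-normalized expression value of gene $i$.

The product in the transcriptomic term is element-wise between two
embedding-width vectors; $\mathrm{MLP}_{exp}$ receives the gene
embedding concatenated with the scalar expression value. This keeps
"which gene" and "how much" in separable pathways while producing
shapes that close. Absent omics members contribute zero vectors, so a
categorical-only model is a strict special case rather than a separate
architecture.

Translation composes two deterministic DDIM solves of the probability
flow ODE: encode the source image to its diffusion latent under the
*source* condition, then decode that latent under the *target*
condition:

$$x^{lat} = \mathrm{ODESolve}(x^{src}; f_{src}, 0 \to T), \qquad
  x^{trg} = \mathrm{ODESolve}(x^{lat}; f_{trg}, T \to 0).$$

Both solves use the deterministic ($\eta = 0$) DDIM update
$x' = \sqrt{\bar\alpha'}\,\hat x_0 + \sqrt{1-\bar\alpha'}\,\hat\varepsilon$
where $\hat x_0$ and $\hat\varepsilon$ come from a single network call
linked by the identity
$x_t = \sqrt{\bar\alpha_t}\hat x_0 + \sqrt{1-\bar\alpha_t}\hat\varepsilon$.
Because both passes are deterministic, translation is a pure function of
the inputs and the checkpoint.

### Timestep conventions

Internally `t` is 0-based: the network evaluated at time
`t ∈ {0, …, T−1}` assumes its input sits at signal level
`alpha_bars[t+1]` (R's 1-based vector). A clean image sits at a notional
level $\bar\alpha = 1$ and the terminal latent at `alpha_bars[T]`. The
first encode step therefore treats the clean image as if it were at the
first plan step's level; the discrepancy is of order $\beta_1$ and is
the standard convention for DDIM inversion.

## Training setup

The training loss draws each batch item's timestep and noise from an RNG
stream keyed by the item's stable identifier hashed together with the
step seed, which makes the loss invariant to batch ordering and the
whole run reproducible on one CPU. Optimization is Adam
(`lr = 2e-3`, default betas) with a 50-step linear warmup, cosine decay
to a tenth of the base rate, and global gradient-norm clipping at 1.
Without the decay and clipping, runs at these widths can converge for a
thousand steps and then collapse to the zero-noise predictor; the
standard recipe removes that failure mode and is the package default.
The variance schedule is linear with the
conventional `1e-4`–`2e-2` range at 1000 steps (rescaled, with a cap,
for shorter ladders); the diffusion literature's pixel scaling to
$[-1, 1]$ is used at the model boundary. These are package choices — the
schedule's β range, the training step count and the pixel scaling are
not prescribed by the translation method itself.

No normalization layers are used: residual blocks end in a
zero-initialized convolution (likewise the attention output projection
and the final output layer), which stabilizes early training at these
widths without the bookkeeping of group normalization in a hand-written
backward pass. Long skip connections across resolution levels are
*additive* (after the first up-path block of each level) rather than
concatenated; at these model widths this halves the cost of the most
expensive convolutions and did not change the round-trip behavior that
the bridge depends on.

## Reduced-timestep calibration

Sampling with every schedule step is needlessly slow. The calibration
procedure (1) computes reference outputs with the full plan, (2) scores
candidate step counts (balanced across the two schedule halves) by mean
SSIM against the reference, (3) picks the smallest candidate within an
*elbow tolerance* (default 0.01 SSIM) of the best achieved score — a
reproducible operationalization of the elbow rule — and (4) searches
allocations of that budget across the two halves on the fraction grid
{0.5, 0.6, 0.7, 0.8, 0.9}, since spending more steps in the first half
of sampling (low noise) tends to preserve structure better. When the
candidate equals the full count the balanced plan *is* the reference
plan and the SSIM is exactly 1 by determinism, so it is reported without
re-running.

## The synthetic study system

Real cohorts (whole-slide images with paired mutation calls and
expression profiles) cannot ship with a package, so `histobridge`
carries a generator whose ground truth is recoverable from pixels:

* two **domains** that differ in base hue (0.08 vs 0.58, i.e. orange
  vs blue at saturation 0.35) — a stand-in for stain or preparation
  identity, measurable as a circular mean hue;
* a mutation gene `BLOB1` bound to **blob count** (wild-type 5, mutant
  15): dark nuclei-like disks placed on a jittered grid that guarantees
  non-overlap, counted by Otsu thresholding plus connected components
  (minimum area 4 px);
* an expression gene `SHADE1` bound to **background brightness**
  (linear response 0.95 − 0.15·t, noise s.d. 0.005);
* pixel grain noise of s.d. 0.02.

Default problem sizes are 32×32 patches, 64 training images per domain,
and 2000–2500 optimizer steps — the scale at which the whole train →
translate → measure loop runs comfortably on one desktop CPU core. The
generator emulates *controllable, measurable* appearance factors; it
does not emulate tissue microanatomy, stain variability, focus
artifacts, or the correlation structure of real omics profiles. Passing
tests therefore demonstrate that the conditioning pathways steer
generation and that the bridge preserves content at this scale — not
that the model reaches histology-grade fidelity on real slides.

## Evaluation suite

* **FID family** on a pluggable feature extractor. The default desk
  extractor is a frozen random projection of a 16×16 pooled image plus
  global color/texture statistics — deterministic and dependency-free.
  Absolute values are not comparable to Inception-V3 FIDs; all package
  checks use relative or ordinal behavior (ΔFID sign, ratio scores),
  which is robust to the extractor choice. The matrix square root in the
  Fréchet distance uses the symmetrized eigendecomposition
  $\mathrm{Tr}\,(\Sigma^{1/2}\Sigma_0\Sigma^{1/2})^{1/2}$ with negative
  eigenvalues clipped within a 1e-6 relative tolerance.
* **SSIM / structural distance** with a uniform sliding window
  (default 7, constants $(0.01L)^2$, $(0.03L)^2$, data range $L = 1$)
  using population moments; structural distance is $(1-\mathrm{SSIM})/2$
  per window.
* **Isolation-forest inlier scores** in $[-1, 1]$ (higher = more
  in-distribution), from a compact reimplementation of the standard
  algorithm (100 trees, subsample 256, depth cap $\lceil\log_2\psi\rceil$),
  scored as $1 - 2\cdot 2^{-E[h]/c(\psi)}$.
* **Retrieval**: majority vote among the k nearest neighbors by cosine
  distance, ties broken toward the nearer neighbor; and editing
  effectiveness as the percentage reduction in mean top-K cosine
  distance (K = 5 by default).

## Preprocessing front end

Slides are masked by Otsu's threshold on a Gaussian-blurred (σ = 5 px)
HSV saturation channel — bright unsaturated background drops out.
Constant-saturation inputs return an empty mask with a warning rather
than an error. Tiling emits 0-based, half-open windows in row-major
order; windows need ≥ 50% tissue by default (the per-patch threshold is
a package choice). Patch triage labels a patch positive when its best
cosine similarity to a positive anchor set beats the negative side, with
ties negative. DAB positivity uses the Ruifrok–Johnston H-DAB stain
matrix on optical densities (log10, clamped at 1e-6), with negative
unmixed concentrations clipped at zero.

## Numerical and degenerate-input choices

* `q_sample`/`predict_x0` validate timestep ranges; composing them with
  the true noise is an exact algebraic identity (tested to 1e-5
  relative).
* Latents are not clamped or re-noised between encode and decode, and
  $\hat x_0$ is not clipped during sampling; clipping is available but
  off by default.
* Quantile normalization maps ranks to `rank/(n+1)` with average ranks
  for ties; an all-tied gene maps to 0.5 (documented, not an error).
* Constant-saturation slides, blob-free images (a degenerate unimodal
  Otsu split yields a dark fraction above one half) and empty gene
  registries (zero-vector embeddings) are all defined, tested cases.

## Known limitations

* Resolution is config-bounded by compute, not by the architecture; the
  reference configuration is 32×32 and 128×128 is reachable by config,
  but CPU training at 128×128 is slow.
* The desk feature extractor cannot reproduce published FID magnitudes;
  plugging in exported features from a pretrained network restores
  comparability.
* Single-head attention only at configured levels; no learned
  variances, cosine schedules, v-prediction or classifier-free guidance
  — the sampler is the plain deterministic DDIM that the bridge
  composition requires.
* The training loop is single-process and CPU-bound by design; its
  determinism contract (same seed, same trajectory) is part of the
  package's test surface.
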