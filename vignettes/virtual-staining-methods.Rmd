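---
title: "Virtual histological staining: models, objectives and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual histological staining: models, objectives and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Hematoxylin and eosin (H&E) staining is the workhorse of histopathology,
but the chemical workflow is slow, operator-sensitive, and consumes the
section. Virtual staining replaces it computationally: an unstained
autofluorescence image of the tissue is translated into an H&E-appearance
image by a learned generator. The practical obstacle is supervision. A
paired training set (the same section imaged unstained, then stained)
is laborious to collect, and in the regime this package targets the data
are badly unbalanced: hundreds of stained tiles but only a small pool of
autofluorescence tiles from other tissue.

`virtstain` implements a two-stage answer:

1. **Stage 1 (weakly supervised pair construction).** An unpaired
   cycle-consistent translation model learns to map stained tiles into
   the unstained domain. It is extended with (a) per-domain *input
   buffers* of heavily augmented real tiles, (b) a *domain-consistency
   network* — a two-input discriminator judging whether two images belong
   to the same domain — and (c) a *depthwise-separable generator* with
   normalization removed from its body. Running the trained generator
   over every stained tile yields a synthetic paired data set.
2. **Stage 2 (paired virtual staining).** A multi-scale *parallel feature
   fusion* generator is trained on those pairs under a conditional patch
   critic with a Wasserstein gradient-penalty objective plus pixel-L1 and
   feature-matching terms. The trained model stains unseen unstained
   tiles.

Evaluation uses distributional image metrics (Fréchet distance,
Inception Score, Mode Score) over pluggable embedders and a
classifier-based stand-in for expert visual review.

## Stage-1 model

Two generators \(G_1 : X \to Y\) (stained to unstained) and
\(G_2 : Y \to X\) train against per-domain patch critics with the
least-squares adversarial objective, the cycle loss
\(\lVert G_2(G_1(x)) - x\rVert_1 + \lVert G_1(G_2(y)) - y\rVert_1\),
and the domain-consistency game.

**Domain consistency.** Each domain keeps a bounded FIFO buffer that is
refilled every step with freshly augmented real tiles (flips, jitter
translation, the zoom–rotate–crop "jitter rotation" path, and elastic
deformation with a Gaussian-smoothed displacement field). The
domain-consistency network \(C_1\) receives two tiles; it is trained to
score a pair of buffer draws as "same domain" and a (buffer draw,
\(G_1(x)\)) pair as "mixed", while the generator tries to make the mixed
pair indistinguishable from a same-domain pair. The published min–max
form of this objective,
\(\mathbb{E}[C(\mathrm{Aug}(Y_1),\mathrm{Aug}(Y_2))^2] +
\mathbb{E}[(1 - C(\mathrm{Aug}(Y_1),G_1(x)))^2]\),
is unbounded for the maximizing player (the first term grows without
limit in \(C\)), so training uses the standard least-squares convention
— same-domain target 1, mixed target 0, both players minimizing their
own quadratic — and `domain_consistency_loss(mode = "as_printed")`
evaluates the raw published expression for audit.

**Why one buffer per domain.** The same-domain pair for \(C_1\) must be
drawn from the unstained domain and the pair for \(C_2\) from the
stained domain, so the buffers cannot be shared; a single mixed buffer
would make "same domain" ill-defined.

**Separable generator.** Dark hole artifacts in the sparse unstained
domain are attributed to instance normalization interacting with
residual summation: per-feature-map normalization discards cross-channel
correlation, and the residual sum amplifies the effect. The redesigned
generator replaces every residual body block with a separable
(depthwise-then-pointwise) block *without* normalization and uses
depthwise-separable convolutions for the stride-2 down- and upsampling;
upsampling is nearest-neighbour followed by convolution, which avoids
checkerboard artifacts from transposed convolutions. The baseline
residual generator (`build_resnet_generator()`) is retained for
ablation.

## Stage-2 model

**Pyramid and extractors.** The input tile is average-pooled with window
= stride = \(2^{s-1}\) for steps \(s = 6,\dots,1\), giving the 8–256 px
scale ladder on a 256 px tile (average pooling preserves the global mean
at every scale). Each scale enters a FromRGB module — three parallel
sampling branches (stride-2 convolution, average-pool + convolution,
max-pool + convolution), concatenated and fused by a 1×1 convolution to
the fixed feature width (512 at full scale) — and then a UNet-style
extractor whose sampling depth grows with resolution: depth 2 for 8/16
px images, 4 for 32/64, 6 for 128/256. Every internal feature map has
the same channel width, the network-wide 512-channel convention.

**Extra skips.** Each extractor carries the conventional same-level skip
connections plus one extra skip from every encoder level to the decoder
level one step deeper (the shallower encoder feature is pooled once and
concatenated); fusion is by concatenation followed by a 1×1 convolution
back to the feature width. Skips to still-deeper levels are deliberately
omitted — with extractors of at most six levels they add cost without
measurable benefit. The deepest extractor has 6 sampling levels, versus
8 for the classic encoder–decoder baseline (`build_unet_baseline()`).

**Fusion decoder.** Scale features are merged coarse to fine: upsample
the running feature, concatenate the next scale's feature, fuse 1×1,
and finish with an upsample, a 3×3 head and a tanh onto \([-1,1]\).
Concatenation (rather than addition) was chosen for the scale injection
because it lets the fusion layer weight scales adaptively.

**Critic.** A fully convolutional patch critic scores (condition,
target) channel concatenations: three stride-2 4×4 convolutions, then
three stride-1 3×3 convolutions to a single-channel score map. The
receptive field works out to 70×70 px and the map has 1/8 the input
resolution — by construction the same spatial size as the
domain-consistency network's output (three stride-2 stages then 1×1
convolutions), so both discriminators supervise at the same patch
granularity. The critic carries no normalization layers, keeping the
gradient-penalty functional well defined, and exposes all six per-layer
activations for feature matching.

## Objectives

With critic scalar scores defined as patch-map means:

- **Wasserstein + gradient penalty** (default): the critic minimizes
  \(\mathbb{E} D(x, y) - \mathbb{E} D(x, G(x)) + \lambda_{gp}
  \mathbb{E}(\lVert\nabla_{\hat y} D(x,\hat y)\rVert_2 - 1)^2\) at
  per-sample interpolates \(\hat y = \epsilon y + (1-\epsilon) G(x)\),
  \(\epsilon \sim U(0,1)\); the generator minimizes
  \(\mathbb{E} D(x, G(x))\). The published objective carries a
  fake-minus-real sign with the critic maximizing; the package keeps
  that game by having the critic minimize the negated expression, which
  is equivalent. Only the target image is interpolated; the condition is
  held fixed.
- **Logistic + R1** and **least-squares** variants are provided for the
  loss ablations.
- **Pixel L1** \(\mathbb{E}\lVert y - G(x)\rVert_1\) and **feature
  matching** (mean over the critic's \(N\) layers of the mean absolute
  activation difference) complete the total
  \(L = L_{gan} + \lambda_{pix} L_{pix} + \lambda_{fm} L_{fm}\).

Reductions are means over batch and elements throughout (the source
formulations are silent on sum versus mean; means make weights
resolution-independent).

**Defaults** (community-standard; the source gives none):
\(\lambda_{gp} = 10\), \(\lambda_{pix} = 100\), \(\lambda_{fm} = 10\),
\(\lambda_{cyc} = 10\), \(\lambda_{dc} = 1\), \(\gamma_{R1} = 10\);
Adam with learning rate \(2\times10^{-4}\), \(\beta = (0.5, 0.9)\);
5 critic steps per generator step for the Wasserstein variant, 1
otherwise.

## The gradient engine and second-order terms

No deep-learning framework is available to this package, so the
architectures run on a compact engine of its own: compiled
im2col/BLAS convolution, pooling and upsampling kernels with exact
forward and backward passes, and a dynamic tape for reverse-mode
differentiation. Every builder is verified end to end against central
finite differences in the test suite.

The gradient penalty and R1 terms need second-order information: the
penalty *value* uses exact reverse-mode input gradients, while its
*parameter gradient* is a Hessian-vector product evaluated by central
differencing of the first-order gradient (two extra forward/backward
passes at perturbed inputs, perturbation scaled to \(10^{-3}\) of the
direction's largest component). This is accurate to \(O(h^2)\) and is
the package's own numerical choice; it is also why the penalty tests
compare against independent finite-difference oracles.

## Synthetic histology

The simulator provides both domains with shared geometry so the whole
pipeline is testable without external data. Nucleus counts are Poisson
with a density of 12 per \(10^4\) px² (about 79 nuclei on a 256 px tile,
a plausible low-magnification field), centers uniform, elliptical nuclei
with semi-axes 3–7 × 2–5 px, cytoplasm as the 1.8× scaled ellipse union.
The stained render paints an H&E-like palette (blue-purple nuclei, pink
cytoplasm, near-white background); the unstained render is a single
fluorescence intensity map (dim background, bright cytoplasm, darker
nuclei) spread over the channels with fixed weights, hence near-perfect
channel correlation — the autofluorescence channel statistics are not
characterized in the source, and the near-monochrome assumption is this
package's own. The default data regime mirrors the study: 400 stained
and 80 unstained tiles, unpaired, with disjoint geometry seeds; paired
mode reuses the geometry so foreground masks coincide exactly.

The tumor class (K = 4) rotates the cytoplasm hue by ±0.075 in the
mid-range G/B channels. Two deliberate choices here: the shift avoids
the near-saturated R channel, because a shift that clamps against the
value range destroys the class signal for the extreme classes; and
classifier fixtures use a higher density (60 per \(10^4\) px² on 32 px
tiles) because a tile with no cells carries no class information at all
— at the dataset default an appreciable fraction of 32 px tiles would be
empty and no classifier could exceed ~77%.

What passing tests on this simulator do **not** show: robustness to real
stain variability, optics and point-spread blur, tissue-type diversity,
or whole-slide artifacts. The simulator has flat backgrounds, exact
palettes and white noise; results on it bound correctness of the
machinery, not clinical performance.

## Metrics

`fid()` computes the Fréchet distance
\(\lVert\mu_1-\mu_2\rVert^2 + \mathrm{tr}(\Sigma_1 + \Sigma_2 -
2(\Sigma_1\Sigma_2)^{1/2})\) with \((n-1)\)-normalized covariances and
the matrix square root by eigendecomposition of the symmetrized product
(negative eigenvalues clipped at \(-10^{-8}\), below which a
numeric-error is raised). Embedders are pluggable: flatten, average-pool
+ flatten, or a trained classifier for probability-based metrics — so
all metric math is verifiable without pretrained weights.

`inception_score()` is \(\exp \mathbb{E}_x \mathrm{KL}(p(y|x) \,\|\,
\bar p(y))\), bounded in \([1, K]\). `mode_score()` implements the
standard definition \(\exp(\mathbb{E}_x \mathrm{KL}(p(y|x)\|p^*(y)) -
\mathrm{KL}(\bar p\|p^*))\); note that this expression is algebraically
identical to the Inception Score (the \(p^*\) terms cancel), which the
implementation faithfully reflects — distinct published MS values imply
an unstated variant that cannot be recovered from the definition.
Because a *lower-is-better* Inception Score is only coherent as a
gap-to-real reading, `evaluate_metrics()` reports raw IS for both sets
plus `is_gap`, the absolute difference.

The visual-evaluation harness trains a reduced convolutional classifier
(tiles pooled to 16 px, two conv/pool stages, global-average head,
softmax cross-entropy; 800 Adam steps at \(3\times10^{-3}\)) standing in
for the full VGG16 of the deployed analysis, and
`visual_simulation_accuracy()` scores generated tiles against the labels
of their real counterparts.

## Reproducibility and numerical conventions

- Tiles are handled internally in \([-1,1]\); files map affinely onto
  8/16-bit PNG/TIFF. Generators end in tanh, so outputs always respect
  the range.
- One run seed fans out to per-purpose streams by fixed offsets; all
  randomness (geometry, augmentation, batch draws, interpolation
  \(\epsilon\), weight init) flows through R's RNG, so identical
  configurations reproduce identical loss logs and outputs on one
  device. Checkpoints store weights, Adam state, step counter, config
  hash and RNG state; save/load round-trips to bit-identical forwards.
- Geometric augmentation uses bilinear interpolation with reflected
  borders everywhere, so augmented tiles never acquire dark corners that
  would confound the hole-artifact analysis.
- Degenerate inputs: empty pools raise insufficient-data; shape
  mismatches raise invalid-argument; a NaN/Inf in any logged loss aborts
  with the step index.

## Desk-scale study conditions

CPU problem sizes used by the test suite and `scripts/acceptance.R`,
stated once as the package's chosen conditions: 64 px tiles; stage-1
translation with width-8 separable generators for 100 steps on the
400/80-tile regime; stage-2 fusion generator with feature width 32
(base width 16) for 300 steps on synthesized pairs; classifier fixtures
of 200 tiles split 150/50. The 512-channel, 256 px configuration is the
faithful default of every builder and is exercised structurally (and by
forward passes at reduced width) in the tests; training it is a
GPU-scale undertaking outside this package's scope.

## Known limitations

- The published clinical metric values (FID 175.969, IS 1.311, MS 0.717;
  93–97% reader and classifier accuracies) are not reproducible here:
  they require the private clinical images, GPU-scale training and human
  raters. The package reproduces the *method* and verifies it
  property-by-property at desk scale.
- The Mode Score identity above means MS adds no information beyond IS
  under the standard definition.
- Stage-2 training at desk scale learns global structure and palette
  but not the subtle class hue; classifier-based accuracy on virtual
  stains is therefore far below the clinical figure, and is reported
  honestly as computed.
- Single-device, single-threaded training only; no mixed precision, no
  whole-slide tiling.
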