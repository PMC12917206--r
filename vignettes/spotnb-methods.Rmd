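---
title: "Methods: distributional expression prediction from H&E tiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distributional expression prediction from H&E tiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotnb)
```

## The model

Spot-based spatial transcriptomics pairs each capture spot (55 µm for
10x Visium, 100 µm for the legacy array) with a gene-count vector and an
H&E image tile centred on the spot. `spotnb` models the count of gene
$g$ at a spot with tile $s$ as negative-binomial,

$$X_g \mid s \sim \mathrm{NB}(r_g(s),\, p_g(s)),$$

in the successes/probability parameterisation, with pmf
$\Pr(X = x) = \frac{\Gamma(x + r)}{\Gamma(r)\,x!}\, p^{r} (1-p)^{x}$,
mean $\mu = r(1-p)/p$ and standard deviation
$\sigma = \sqrt{r(1-p)}/p$. The parameters are affine functions of a
tile embedding $z = f(s)$:

$$r = \mathrm{softplus}(W_r z + b_r), \qquad
  p = \mathrm{sigmoid}(W_p z + b_p),$$

one $(r, p)$ output pair per gene, all genes sharing the embedding.
Training minimises the exact NB negative log-likelihood

$$\sum_{g}\sum_{i}\Big[\log\Gamma(r_{g,i}) + \log\Gamma(x_{g,i}+1)
  - \log\Gamma(r_{g,i}+x_{g,i}) - r_{g,i}\log p_{g,i}
  - x_{g,i}\log(1-p_{g,i})\Big]$$

with minibatch Adam (batch 64 by default). Counts enter raw: the
likelihood above is a model of the observed count, so no library-size
normalisation is applied before fitting.

**The $p$ activation.** Mapping $p$ through a softmax *across genes*
would force $\sum_g p_g = 1$, coupling genes that the likelihood treats
as independent; for a single gene it degenerates to the constant 1. The
default is therefore an elementwise logistic map, which preserves the
per-gene $(0,1)$ range. A literal softmax-across-genes mode
(`p_mode = "softmax"`) is retained for fidelity experiments.

**Numerical choices.** $r$ is clamped to $[10^{-6}, \infty)$ and $p$ to
$[10^{-6}, 1-10^{-6}]$ so the loss is finite for all inputs, including
all-zero genes (whose fitted mean then collapses towards the clamp, as
it should). Features are standardised with training statistics stored in
the model and re-applied at prediction time. Initialisation sets
$r \approx 1$ and solves $p$ from each gene's mean count via
$p = r/(r+\bar x)$, so the model starts at a sensible marginal fit.
Softplus and the log-likelihood use the stable `log1p` forms; gradients
are the analytic ones
($\partial\ell/\partial r = \psi(r) - \psi(r+x) - \log p$,
$\partial\ell/\partial p = -r/p + x/(1-p)$), verified against numerical
differentiation in the tests. Defaults: learning rate $10^{-3}$, 50
epochs; training is deterministic for a fixed seed.

## Feature extraction

The embedding $z$ is a swappable port with three implementations:

* **handcrafted** (default in tests): nine deterministic morphometrics —
  tissue-foreground fraction, per-channel means and variances, nucleus
  blob count (connected components of the foreground mask, minimum five
  pixels) and mean blob area. All nine are invariant to flips and
  90° rotations.
* **imported**: a CSV of per-spot embeddings computed elsewhere (e.g. a
  histology foundation model); the adapter aligns rows to spots and
  refuses silently missing spots.
* **builtin_cnn**: a small convolutional feature bank — tiles are
  block-averaged to 32×32, passed through a seeded random 5×5 filter
  bank with ReLU, and globally average-pooled to F features (64 by
  default). The filters are frozen; random convolutional features are a
  standard desk-scale stand-in for a pretrained backbone, and with
  `fine_tune_extractor = TRUE` a linear F×F feature adapter is trained
  jointly with the NB head by the same backpropagation, providing the
  trainable image-side capacity that fine-tuning a backbone would.

## Ensembles and uncertainty

`train_ensemble()` trains M replicates (default 30) differing only in
the seed; `pool_ensembles()` draws seeded random groups (default size
5). For a group, the pooled prediction is the arithmetic mean of the
member means (no ensemble-level $(r,p)$ is synthesised). By the law of
total variance,

$$\mathbb{V}[X_g \mid s] =
  \underbrace{\mathbb{V}_\Theta\!\big[\mu_g(s)\big]}_{\text{epistemic}}
  + \underbrace{\mathbb{E}_\Theta\!\big[\sigma_g^2(s)\big]}_{\text{aleatoric}},$$

`decompose_uncertainty()` reports both terms and their sum, which is
exact by construction. Epistemic uncertainty uses the population
(divide-by-M) variance, computed on deviations from the first member so
that identical members give exactly zero. The decomposition is checked
against a mixture Monte-Carlo sampler (draw a member uniformly, then a
count from its NB) in the tests.

## High/low classification

Expression is z-scored per gene across training spots
($z = (x-\mu)/\sigma$) and binarised: High iff $z > 0$, Low otherwise
(the tie $z = 0$ goes to Low, a fixed deterministic rule). Training
statistics are stored and reused at inference so test spots are
labelled on the training scale. Constant genes are rejected by name. A
per-gene logistic regression on the embedding minimises

$$L(\beta, b) = \mathrm{BCE} +
  \omega\big[(1-\alpha)\textstyle\sum_j \beta_j^2 +
  \alpha\sum_j |\beta_j|\big],$$

with the intercept unpenalised; $\omega = 0.1$ and $\alpha = 0.5$ by
default ($\alpha = 1$ is pure lasso, $\alpha = 0$ pure ridge). The
convex solve is delegated to glmnet's coordinate descent under the
exact reparameterisation $\lambda = \omega(2-\alpha)$,
$\alpha' = \alpha/(2-\alpha)$, which makes glmnet's penalised objective
identical to the one above (tolerance $10^{-10}$); at $\omega = 0$ an
unpenalised `glm` fit is used instead.

## Evaluation metrics

Per-gene Pearson correlation and ROC AUC (midrank ties; anti-ranked
scores give 0) are standard. Moran's I uses rook adjacency on the array
grid, row-standardised, by default; a k-nearest-neighbour option
(k = 6) suits hexagonal layouts. The weight matrix is a choice the
metric's definition leaves open, so it is explicit in the interface.

The **geometric spatial-pattern IoU** scores whether two per-spot
fields paint the same spatial pattern: (1) z-score each field; (2)
binarise at zero; (3) rasterise onto the array grid with unoccupied
cells set to 0; (4) smooth each binary raster with a separable 2-D
Gaussian, σ = 1 grid unit, kernel truncated at 4σ, zero padding at the
boundary; (5) re-binarise at 0.5; (6) intersection-over-union over the
occupied cells, with the convention that two empty patterns score 1.
The smoothing step makes the score tolerant to single-spot speckle
while the z-score step makes it invariant to positive affine transforms
of either field. Re-binarising before the IoU (rather than comparing
the real-valued smoothed fields) keeps the score a set overlap; the
0.5 threshold, the truncation and the padding are fixed here because
the metric's verbal definition leaves them open — the tests pin the
whole pipeline against an independent brute-force implementation.

## LIME over nuclei

`segment_tile()` finds nuclei either from an imported labelled mask or
by colour deconvolution to haematoxylin–eosin–DAB densities, Otsu
thresholding of the haematoxylin channel, and connected components
(minimum area 10 px). `lime_explain()` draws binary segment-inclusion
vectors (the first sample is always full inclusion, so the design
contains $f(x)$ itself), renders perturbed tiles with excluded segments
filled by the tile's mean colour (or mid-grey), and fits a weighted
linear surrogate with proximity kernel
$\exp(-D^2/w^2)$, $D$ = fraction of segments removed, $w = 0.25$.
Sparsity keeps the first `top_k` segments entering a weighted L1 path,
followed by a weighted least-squares refit; a singular design falls
back to ridge ($\lambda = 10^{-6}$) with a warning. With the kernel
held constant and all $2^K$ inclusion vectors enumerated, the surrogate
is exactly weighted least squares, which the tests verify against an
independent solver. Per-nucleus scores and areas come from
`aggregate_nucleus_scores()`.

## Preprocessing

Tiles are cropped per in-tissue spot with window
$[c - \lfloor T/2 \rfloor,\, c - \lfloor T/2 \rfloor + T)$ per axis
(T = 299 px by default), so odd tiles are exactly centred; spots whose
window leaves the image are dropped (logged) or mirror-padded.

Tissue coverage is the fraction of pixels whose HSV saturation exceeds
an Otsu threshold computed on the saturation channel, with a fixed 0.05
fallback when the histogram is degenerate (blank tiles). Tiles with
coverage below 0.70 are removed by default. This mask rule is a
deterministic restatement of standard background masking; it is a
package decision, documented because coverage thresholds only mean
something relative to a stated mask.

Stain normalisation maps a tile onto a template's stain statistics.
The template stores a two-stain colour basis (unit-norm rows), each
stain's 99th-percentile concentration, and the mean R, G, B
intensities. The default separation refines a Macenko initialisation
(SVD plane of the optical-density cloud, 1/99 angle percentiles) by
sparse dictionary learning (multiplicative-update NMF, L1 penalty 0.1
on concentrations); optical density is $-\log((I+1)/256)$.
Normalisation rescales each stain's concentrations to the template
percentiles, reconstructs with the template basis, and finishes with an
iterated per-channel multiplicative gain that aligns the mean channel
intensities with the template's to within 3 grey levels — the
contract the whole step is tested against. The gain is monotone, so
within-channel rank order of optical densities is preserved. Numerical
failure of the separation falls back to the gain-only method with a
warning; all-background tiles are returned unchanged.

## The synthetic-slide generator

`generate_slide()` renders elliptical purple "nuclei" on a pale pink
background over a square spot grid, then draws counts from the known
link: per spot a blob count $m$ is drawn (2–12 by default, iid across
spots; `"gradient"` and `"halves"` options modulate density across the
grid to create spatially autocorrelated fields), and
$\mu^*_g = \exp(a_g + b_g \tilde m)$ with $\tilde m$ the standardised
blob count, $a_g \sim U(0.5, 2)$, $b_g \sim U(0.6, 1.2)$, dispersion
$r_g \sim U(2, 10)$, counts $\sim \mathrm{NB}(\mu^*_g, r_g)$. The
generator stores $(a_g, b_g, r_g)$, every $\mu^*$, and the per-spot
morphology; `p = r/(r+\mu)` bridges to the head's parameterisation so
$\mu = r(1-p)/p$ holds exactly. Blobs are placed non-touching with
anti-aliased edges and luminance-only noise (σ = 1.5 grey levels,
equal across channels so the saturation-based mask is unaffected),
which keeps the planted blob count exactly recoverable by connected
components — the property that lets the feature extractor see the
generative signal.

What the generator emulates: tiles whose morphology drives expression
through a log-linear link, overdispersed counts, Visium-like geometry,
and batch-like stain shifts (`stain_shift`). What it does not: nuclear
texture and chromatin detail, overlapping or touching nuclei, stromal
and cytoplasmic structure, hexagonal spot packing, segmentation errors,
and spatial covariance beyond the coarse density patterns. Passing
tests on this generator therefore demonstrates that the estimation,
uncertainty, attribution and metric machinery is correct — not that any
particular accuracy will transfer to real H&E images.

## Problem sizes used by the tests and acceptance script

Chosen once as realistic desk-scale conditions: parameter recovery uses
a 45×45 grid (2025 spots), 8 genes, 45 px tiles, batch 64, 40 epochs at
Adam rate 0.05 — recovery is judged by per-gene correlation with the
generative means and dispersion ratios. The ensemble comparison uses
400 spots and 10 replicates trained for 15 epochs: the shortened budget
leaves genuine seed-to-seed variability, which is the phenomenon an
ensemble average is supposed to iron out; fully converged replicates on
clean synthetic data are near-identical and make the comparison
vacuous. The classification check plants a strong signal (slope 2,
dispersion 30–50) because it measures the classifier, not the
morphology-to-count noise floor. Monte-Carlo checks use $10^5$ draws
per cell and three-standard-error bands.

## Known limitations

* The NB head is linear in the embedding; non-linear structure must
  come from the extractor.
* The builtin extractor's filters are random, not learned; use imported
  embeddings when a pretrained backbone is available.
* Stain separation assumes two stains plus residual; it will not model
  DAB-heavy immunohistochemistry.
* Moran's I and the IoU rasterise on array coordinates as-is; hexagonal
  Visium offsets are not resampled (use the knn weights for Moran's I
  in that case).
* `binarize_expression` assumes raw counts by default; any positive
  affine transform gives identical labels, but non-monotone transforms
  do not.
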