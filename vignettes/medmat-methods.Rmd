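---
title: "Learning material categories and attributes from radiography-style images"
author: "medmat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning material categories and attributes from radiography-style images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Radiography images (X-rays, MRIs) carry rich local texture that hints at the
*material* present in a region — spongy bone, homogeneous background, brighter
tumor tissue — but almost no dataset annotates materials directly. `medmat`
implements a pipeline that bootstraps material supervision from whatever
annotation already exists:

1. **Patch dataset construction.** Normalized images are tiled on a grid and
   32×32 patches are categorized by simple rules: a patch whose average
   brightness $\bar{B}$ (the mean of its normalized values) falls below
   $\bar{B}_0$ is *null* (background); otherwise its brightness must lie in
   $[\bar{B}_{\min}, \bar{B}_{\max}]$, and its expert-mask coverage decides
   between the *expert* category (coverage $\ge 1-T$) and the *naive*
   category (coverage $\le T$). Coverage strictly inside $(T, 1-T)$ straddles
   the mask boundary and is rejected, since such ambiguous patches would
   confuse training. $T < 0.5$ is asserted at configuration load so the
   expert and naive rules can never both fire.
2. **Similarity learning.** A Siamese convolutional network scores patch
   pairs as same/different category (label $y=1$ means *different*),
   trained with cross-entropy
   $\sum -\left(y\ln\hat y + (1-y)\ln(1-\hat y)\right)$ under a
   best-validation-checkpoint regimen. Its binary decisions, averaged per
   comparison category, $p_k = \frac{1}{N_k}\sum_{n \mid c_n=k} s_n$, yield a
   perceptual distance matrix $D_{kk'} = \lVert p_k - p_{k'}\rVert_2$.
3. **Attribute discovery.** A $K\times M$ matrix $A$ of category-conditional
   attribute probabilities is fitted by box-constrained L-BFGS-B to
   $$\sum_{k,k'} \left(\lVert a_k - a_{k'}\rVert_2 - D_{kk'}\right)^2
     + \gamma \sum_{p\in P} \beta(p; \tfrac12,\tfrac12)
       \ln\frac{\beta(p;\tfrac12,\tfrac12)}{q(p; A)},$$
   where $q(p;A)$ is an equal-weight Gaussian KDE of $A$'s entries with
   bandwidth $h$. The arcsine Beta(0.5, 0.5) target encodes the prior that
   an attribute is usually clearly present or clearly absent.
4. **Multi-task classification.** A convolutional backbone with a $K$-way
   softmax category head and auxiliary attribute heads — one per backbone
   stage response, each a two-layer clipped-linear map
   $h(x)=\min(1,\max(0,x))$, merged by a combiner — is trained against the
   fixed $A^\*$ with a three-term loss: category negative log-likelihood,
   a $\gamma_1$-weighted KL term pulling the batch's attribute predictions
   toward the Beta target through the same KDE, and a $\gamma_2$-weighted
   squared error between $A$'s rows and per-category batch means of the
   predictions.
5. **Whole-image inference.** The classifier is applied over a sliding
   window (32 px window, 4 px stride by default), giving a category map and
   $M$ attribute maps per image.

# The synthetic study

Everything is testable without medical data through a deterministic scene
generator. The default study emulates a two-modality composite dataset:

* modality A: a dark background (base brightness 0.02) and a `bone_like`
  speckle texture (base 0.55, noise 0.12, blur radius 2 px);
* modality B: the same background, a `brain_like` speckle texture
  (base 0.63, noise 0.12, blur radius 2 px) and an expert-masked `lesion`
  region (base 0.70, blob pattern, blur 3 px).

`bone_like` and `brain_like` share the identical speckle process and differ
only by a brightness shift of 0.08 — about three patch-mean standard
deviations, so single patches are classifiable at ~95% while isolated pairs
still get confused: they are the deliberately confusable pair, standing in for
perceptually similar tissue categories, and — because the texture process is
identical — their decision error profiles are symmetric by construction, so
the learned distance between them shrinks for a structural reason rather
than by accident of which class errs more. The background and the brighter,
blobby lesion are
comparatively easy. Textures are value noise: white Gaussian noise
blurred to the target spatial scale, renormalized to the requested contrast
(`speckle`), left attenuated (`smooth`), or squared into bright bumps
(`blob`). Region means stay within 0.05 of the configured base brightness,
and every scene also emits its ground-truth region map so patch-rule
failures can be distinguished from generator failures.

What the generator does **not** emulate: acquisition physics (beam
hardening, bias fields, speckle statistics of real MRI), anatomical shape,
inter-patient variability, or annotation noise in expert masks. Passing
tests therefore demonstrate the pipeline's mechanics and its statistical
behavior under controlled texture similarity — not clinical performance.

## Study configuration

| parameter | default | why |
|---|---|---|
| images | 6 modality-A + 12 modality-B, 256×256 px | enough eligible grid points for ~2,000 patches with a 48 px pure-background border |
| $\bar{B}_0$ | 0.05 | separates the 0.02-brightness background |
| $[\bar{B}_{\min}, \bar{B}_{\max}]$ | [0.35, 0.95] | rejects patches mixing background and tissue, whose average brightness falls midway |
| $T$ | 0.05 | small positive tolerance keeps near-boundary lesion patches while avoiding ambiguous ones |
| grid spacing $p$ | 8 px | patch overlap without duplicate origins |
| split | 60 / 20 / 20 | per-category stratified train / validation / test |
| attributes $M$ | 4 | matches the four-category study |
| $\gamma$ (attribute objective) | 0.1 | balances the distance term (entries of a scalar-mode $D$ are small) against the KL pull; the KL grid is 101 points on [0.005, 0.995], $h = 0.1$ |
| $\gamma_1, \gamma_2$ (classifier) | $10^{-2}$, 1 | reference training weights of the method |
| batch, similarity lr | 50; $10^{-3}$ | reference training parameters of the method |
| classifier lr | $5\times10^{-4}$ in the study ($10^{-4}$ API default) | random-init adaptation, see below |

Both networks train for the method's reference regimen of 15 epochs. The similarity network
draws 750 reference samples (each compared against all $K$ categories) per
epoch and 300 validation samples for checkpoint selection. The distance
matrix is built by applying the saved best-validation-loss checkpoint to a
larger set of 2,500 validation comparison samples: each per-class decision
mean carries sampling error of order $1/\sqrt{N_k}$, and the scalar-mode
distances are differences of error rates divided by four, so a few hundred
decisions would drown them in noise. The classifier trains at an initial
learning rate of $5\times10^{-4}$ rather than the reference $10^{-4}$: that
rate is tied to a pretrained backbone being fine-tuned, while this
package's tested path trains from random initialization, where $10^{-4}$
cannot traverse the loss landscape in 15 epochs. The API defaults keep the
reference values.

# Design choices

**Backbones.** The networks are compact sequential conv stacks (3×3
convolutions, ReLU, 2×2 max pooling; "tiny" = 4 blocks of 8–32 channels,
~100k parameters) written directly in the package with Rcpp kernels for the
convolution and pooling passes. Deep residual backbones would add nothing at
32×32-patch, CPU-minutes scale; the architecture is configurable
(`backbone`, head widths) where a larger variant is wanted.

**Comparison head.** The two encoder embeddings are combined by absolute
elementwise difference before the fully connected layers, which makes the
similarity score exactly symmetric in its two inputs — swapping reference
and comparison cannot change a decision.

**Scalar vs. profile distance.** `trainDCNN`'s default distance matrix uses
the scalar reading of the decision aggregation: one $K$-vector $p$ pooled
over all reference categories, $D_{kk'} = |p_k - p_{k'}|$ (entries in
$[0,1]$). This discards reference-category information, and for a
*symmetric* confusable pair it is close to degenerate: mutual confusions and
same-class errors shift $p_A$ and $p_B$ almost identically, so their
difference — the distance — cancels to the order of error-rate differences
divided by four. The *profile* variant (`mode = "profile"`) keeps a
per-reference-category decision vector per class and takes L2 distances
between those profiles; a confusable pair's profiles lose contrast in
exactly the columns that involve the pair, so their distance shrinks
robustly rather than by cancellation. The synthetic study therefore builds
its distance matrix in profile mode; the scalar form remains the package
default.

**Attribute objective conventions.** The distance term sums over ordered
pairs $k \ne k'$ (each unordered pair twice — a constant factor that cannot
move the argmin). $a_k$ denotes *row* $k$ of $A$, consistent with the
classifier's $\gamma_2$ term comparing rows of $A$ with per-category
prediction means. The KL sum is a plain sum over the grid $P$ with no
$\Delta p$ factor; any such factor would be absorbed by rescaling $\gamma$.
Optimization runs on the raw entries with box constraints $[0,1]$ (L-BFGS-B)
from 5 random initializations drawn uniformly on $[0.1, 0.9]$ — away from
the endpoints, where the Beta target density diverges. The KDE inside the
objective is clamped to $10^{-12}$ before the logarithm; predicted
probabilities are clamped to $10^{-7}$ inside cross-entropy terms.

**Category head.** The softmax is applied before the negative
log-likelihood — the loss is only well-defined as a likelihood on a
normalized score vector. The two fully connected layers default to
narrow-then-wide order as configured (`catHidden`), 64→128 for the tiny
backbone, 512→2048 for the wide variant; pass them reversed to swap.

**Auxiliary heads.** Each backbone stage response (including the first
pooled response) is global-average-pooled and mapped by a two-layer
clipped-linear network (hidden width 64) to $M$ values; a combiner
concatenates the stage vectors and applies one more clipped-linear map.
Clipped-linear biases are initialized at 0.25 so units start inside the
active band $(0,1)$ rather than half-dead at the clamp.

**Scheduler and checkpoints.** The classifier's learning rate is divided by
exactly 10 after any epoch whose validation loss exceeded the previous
epoch's; both networks return the checkpoint with the lowest validation
loss, never simply the last epoch.

**Embedding diagnostic.** Category separation in feature space is scored by
embedding the vectors into two dimensions with classical metric MDS
(`cmdscale`, deterministic) and computing the mean silhouette width there.
The pipeline's contract is directional: on the trained study, the silhouette
of the $M$-dimensional attribute predictions exceeds that of the raw
1024-dimensional patch values.

**Determinism.** All randomness flows through seeds derived from one master
seed; training is single-threaded, so identical seeds give bit-identical
histories, checkpoints and matrices.

# Numerical and degenerate cases

* Constant-valued images normalize to all-zero with a warning (min–max
  degenerate).
* An absent mask counts as coverage 0, so maskless images feed the naive
  rule.
* A category with fewer than 2 patches cannot form comparison samples, and
  fewer than 3 cannot be stratified into splits; both are errors.
* Non-finite training losses abort with the epoch and batch in the message.
* `betaDensity` refuses the endpoints 0 and 1, where the arcsine density is
  unbounded.
* Empty cells of the pairwise accuracy matrix and zero-variance attributes
  in the correlation matrix are reported as missing (`NA`), never as 0.

# Known limitations

* The scalar distance matrix compresses all pairwise structure into one
  mean-decision scalar per category; with a well-trained network its
  off-diagonal entries are differences of small error rates and can be
  statistically delicate. The profile mode keeps more structure when that
  matters.
* Synthetic textures are stationary Gaussian fields; real tissue texture is
  not, and no claim about medical images follows from the study.
* The sliding-window map deliberately applies no smoothing or spatial
  post-processing, so maps inherit the patch classifier's local noise.
* Attribute heads can saturate (a clipped-linear unit stuck at 0 or 1 has
  zero gradient); the correlation matrix reports such dead attributes as
  missing rather than hiding them.

# A worked run

```{r}
library(medmat)
run <- runMaterialStudy(seed = 1, verbose = TRUE)
run$pairAccuracy            # held-out same/different decision accuracy
as.matrix(run$D)            # perceptual distances between the 4 categories
as.matrix(run$A)            # optimized category-attribute matrix
run$categoryEval$accuracy   # held-out patch category accuracy
run$silhouettes             # attribute vs raw-feature separation

img <- generateStudyImages(nA = 0, nB = 1, seed = 7)[[1]]
map <- slidingWindowMap(run$mac, img, stride = 8,
                        categories = studyCategories())
maskEnrichment(map, img@mask, "lesion")
```

The README shows the numbers this prints for one seed; the acceptance
script (`scripts/acceptance.R`) recomputes the same quantities from scratch
and writes them as JSON.
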