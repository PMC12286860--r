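---
title: "Content-loss neural code conversion: model, simulation design, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Content-loss neural code conversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncconvert)
```

## The problem

Fine-grained functional topography differs across individuals: the same
stimulus evokes different multivoxel patterns in different brains even after
anatomical alignment. Functional alignment methods learn a mapping between
two subjects' voxel spaces, but classically they need *paired* data — both
subjects viewing identical (shared) stimuli — which is often unavailable,
especially across datasets collected at different sites.

`ncconvert` implements a converter that removes this requirement. The idea:
although two subjects' voxel patterns are idiosyncratic, they represent the
same stimulus *content*, and that content can be expressed in a latent
feature space (hierarchical features of a deep network). If the target
subject has a pre-trained *feature decoder* — a regression model predicting
stimulus features from the target's voxel patterns — then a converter from
source to target space can be trained by requiring that the decoder, applied
to the *converted* source activity, reproduces the true features of the
stimuli the *source* saw. No target brain data for those stimuli is needed.

## The model

Let $x_i \in \mathbb{R}^m$ be the source subject's voxel pattern for
stimulus $i$, and let the target's frozen decoder for feature layer $l$ be
the affine map $d_{il} = W_l \, \Phi(x_i) + b_l$, where
$\Phi : \mathbb{R}^m \to \mathbb{R}^n$ is the converter. With
$v_{il}$ the true feature vector of stimulus $i$ at layer $l$, the
converter minimizes the content loss

$$\mathcal{L}(\Phi) = \sum_i^N \sum_l^L \eta_l\,
  \lVert v_{il} - (W_l \Phi(x_i) + b_l) \rVert^2,
  \qquad \eta_l = 1 / \lVert v_{il} \rVert^2 .$$

$\Phi$ is a multilayer perceptron with two hidden layers (each half the
input width) with instance normalization and ReLU; purely affine and
residual (three extra residual blocks) variants are provided. Training is
iterative with a stochastic layer-sampling schedule: at every iteration one
feature map (channel) per convolutional layer is drawn uniformly and all its
units are decoded, while fully connected layers contribute all their units;
the default schedule runs 1,024 iterations so that all units participate
over the course of training. The per-sample weight $\eta_l$ is computed on
the sampled units (a per-layer-average variant is available for ablation).

Two baselines that *do* require paired data are included for comparison:

* **brain loss** — multivariate ridge regression
  $\min_{M, c} \sum_i \lVert y_i - (M x_i + c)\rVert^2 +
  \lambda \lVert M \rVert_F^2$ against the target's measured patterns
  $y_i$, solved in closed form with the bias unpenalized; $\lambda$ by
  generalized cross-validation over $10^{-2} \dots 10^4$ when not given;
* **orthogonal Procrustes** — the best orthogonal map (reflections
  allowed), with optional isotropic scale and translation, from the SVD of
  the centered cross-covariance.

### Feature decoders

Decoders are per-layer ridge regressions from voxel patterns to feature
units. Voxels and features are z-scored with training statistics; per layer,
voxels are ranked by their maximum absolute Pearson correlation with any of
the layer's units and the top 500 (fewer if fewer exist) are retained; the
ridge solution is computed in closed form with the bias implicit in the
normalization. Voxel selection is per layer rather than per unit — one
selected set and one weight matrix per layer keeps memory linear in layer
size; this is a documented assumption. Decoding is affine in the voxel
pattern, which is what lets converter training differentiate through the
frozen decoder.

The canonical penalty is $\lambda = 100$, tied to training sets of several
thousand trials. The penalty acts relative to the data Gram matrix, whose
scale grows with the trial count, so the simulation-scale experiment
configuration defaults to $\lambda = 10$ at $N \approx 150$ trials (roughly
constant $\lambda/N$). Both are plain arguments.

### Evaluation

*Pattern* correlation compares two patterns across voxels (or units) for
one stimulus; *profile* correlation compares one voxel's (unit's) responses
across stimuli. For conversion accuracy both are normalized by noise
ceilings estimated from repeated measurements: the ceiling of a stimulus
(voxel) is the mean correlation between repetition pairs, and items whose
ceiling falls below the 99th percentile of a random-pair null are excluded.
The null pairs repetition responses to *mismatched* stimuli (for patterns)
or mismatched voxels (for profiles), 10,000 seeded draws — the precise
construction of "random pairs" is a documented choice. Ceiling
normalization is applied only to conversion metrics; decoding and
reconstruction analyses retain all voxels. Pattern ceilings pair single
repetitions rather than split-half averages (flag available).

Pairwise identification scores, for each test stimulus, whether the
candidate feature vector correlates more with the true stimulus's features
than with a false alternative, over all $S-1$ alternatives
($S(S{-}1)$ comparisons; chance 50%). Exact ties count 0.5, which is
unbiased under exchangeability; zero-variance candidates score 0.5 and are
flagged. Group summaries over subject pairs use a dyadic bootstrap: source
IDs and target IDs are resampled separately with replacement, crossed,
self-pairs dropped, and the observed pair values truncated/refilled to the
original sample size, 1,000 replicates for a percentile 95% CI — pair
values sharing a subject are dependent, so ordinary pair resampling would
understate the CI.

### Image reconstruction

Images are reconstructed from (decoded) features by optimizing a generator
latent $z$ under

$$z^* = \arg\min_z \; \mathcal{L}_{\mathrm{mse}}(z)
  + \lambda_{\mathrm{tex}} \mathcal{L}_{\mathrm{tex}}(z)
  + \lambda_{\mathrm{str}} \mathcal{L}_{\mathrm{str}}(z),$$

where $\mathcal{L}_{\mathrm{mse}} = \sum_l \gamma_l \lVert
\Psi_l(G(z)) - u_l \rVert^2$ with $\gamma_l = 1/\lVert u_l \rVert^2$, and
the texture and structure terms are built from per-channel spatial means
$\mu_k$, variances $\delta_k$ and cross-covariances of convolutional
feature maps:

$$\mathcal{L}_{\mathrm{tex}} = -\sum_l \alpha_l \frac{1}{K_l} \sum_k
  \frac{\mu_k(u_l)\mu_k(\hat u_l) + \epsilon}
       {\mu_k(u_l)^2 + \mu_k(\hat u_l)^2 + \epsilon}, \qquad
\mathcal{L}_{\mathrm{str}} = -\sum_l \beta_l \frac{1}{K_l} \sum_k
  \frac{\delta_k(u_l, \hat u_l) + \epsilon}
       {\delta_k(u_l) + \delta_k(\hat u_l) + \epsilon}.$$

These terms need spatial maps, so they act on convolutional layers only;
dense layers enter the feature MSE. The optimizer is gradient descent with
momentum (200 iterations), with all gradients computed analytically and
chained through the extractor's backward pass. The generator defaults to
direct pixel parameterization (`identity_pixels`): the latent is the image,
clipped to $[0,1]$. A deep generative prior is deliberately out of scope —
the identity generator preserves the full loss structure with no pretrained
dependency; any `pixel_generator()` (e.g. the seeded `toy_decoder`) can be
substituted.

## The simulated world

No real fMRI data or pretrained network weights are used anywhere. Instead:

* **Content space.** A small fixed-weight (seeded) convolutional extractor
  — three strided 3×3 stages (8, 16, 16 channels) plus a 64-unit dense
  layer on 32×32×3 input by default — supplies the hierarchical features.
  Features are pre-rectification values, and the extractor is exactly
  differentiable, which the converter and reconstruction modules rely on.
  At least three hierarchy levels are kept so multi-layer content losses
  are meaningful. A second, differently parameterized extractor (patch
  embedding + dense) provides an alternative feature family for
  cross-decoder generalization tests. For the published architectures the
  package ships shape arithmetic only (`layer_unit_count()`), validated
  against the standard layer dimensions; the AlexNet table uses the Caffe
  227-pixel crop geometry that yields its standard 55×55 first-layer map.
* **Stimuli.** Procedural colored geometric composites organized by
  category (shape, palette, position jittered within category), with an
  optional category-disjoint train/test split and a category-disjoint
  source/target split of the training set for the no-shared-stimuli
  condition. A random texture field (weight 0.25) is blended into every
  image: purely geometric stimuli span a feature manifold of effective
  rank ≈ 30, which leaves most of voxel space unconstrained and makes the
  decoder ill-conditioned off the training manifold; the texture field
  emulates the broadband local variability of natural images and roughly
  doubles the usable rank. This is a property of the *stimulus
  distribution*, not of the method.
* **Subjects.** Each virtual subject reads out the middle convolutional
  layer's flattened features through its own sparse Gaussian matrix
  (5% density by default), so all subjects share the content space but
  none share a topography. Reading out the *middle* layer makes lower and
  higher layers only partially linearly decodable, so layer-wise accuracy
  profiles are non-degenerate. Voxel signals are standardized to unit
  variance over the training stimuli, so `noise_sd` is a direct
  noise-to-signal ratio and the expected profile noise ceiling is
  $1/(1 + \mathrm{noise\_sd}^2)$ — the suite verifies this analytic value.
  Repetition noise is i.i.d. Gaussian: the method operates on trial-level
  response amplitudes, so hemodynamics, temporal autocorrelation and
  session drift are deliberately not modeled.
* **Sites.** Different sites are different worlds (different stimuli)
  sharing the extractor; subjects are tagged by `dataset_id` and no
  stimulus crosses sites, so inter-site pairs genuinely share nothing.

What passing tests therefore do and do not show: they demonstrate that the
algorithms are implemented correctly and that the method's qualitative
claims (content ≈ brain loss accuracy, no-shared-stimuli robustness,
cross-decoder generalizability, data-efficiency of converter training) hold
in a controlled linear-readout world at desk scale. They do not certify
performance on real cortical data, where encodings are nonlinear,
noise is structured, and feature spaces are vastly larger.

## Numerical choices

* **Conditioning.** The content optimum inverts the stacked decoder maps;
  directions weakly represented in the decoder training data are amplified.
  Three design choices keep this benign, mirroring the regime the method
  operates in with real data: rich stimuli (texture field), more training
  trials than voxels, and a non-vanishing decoder penalty. The MLP's
  stochastic training adds implicit regularization — it approaches the
  constrained optimum without exploding along weak directions, and in
  pilots it *outperforms* the exact closed-form content optimum on
  ill-conditioned problems.
* **Optimizers.** Converter: Adam (default learning rate $10^{-3}$;
  the simulation-scale experiment configs use $10^{-2}$, which converges
  within 512–1,024 iterations at 96–140 voxels), full-batch, one gradient
  step per sampled-unit iteration (the per-iteration step count is an open
  choice; one step is the default and is documented). Training consumes
  trial-level source responses by default (repetition averaging is a
  flag). Reconstruction: SGD with momentum 0.9 and learning rate 0.1,
  stable across both toy extractors (0.5 diverges at 16 px); the returned
  image is the best iterate, so the final loss never exceeds the
  initialization.
* **Degenerate inputs.** Constant voxels get unit sd, correlation 0, and
  are never selected; constant feature units get zero weights and their
  mean as prediction; correlations with zero-variance arguments are
  recorded as missing (`NA`) and propagate as missing — never as zeros —
  into all means; $\epsilon = 10^{-6}$ keeps the similarity ratios finite
  for all-zero maps; instance normalization uses per-sample statistics, so
  batch composition cannot change a conversion.
* **Ties and exclusions.** Identification ties count 0.5; noise-ceiling
  exclusion applies only to conversion metrics; Procrustes allows
  reflections (the reflection-constrained variant never has lower
  residual); mismatched Procrustes spaces can be zero-padded but are
  rejected by default.
* **Problem sizes.** The test suite and experiments run 16×16 worlds with
  a (4, 8, 8 / 16)-channel extractor (128-unit encoding layer), 150
  training / 40 test stimuli, 96-voxel subjects (140 for exact-recovery
  checks, where the voxel count must reach the encoding dimension), 2–4
  test repetitions, and 256–1,024 converter iterations — minutes on one
  CPU. The training-size ladder uses 10/20/60/150 of 150 training samples:
  ~7% of the data is the smallest rung that is degraded yet reliably above
  chance; at 8 samples the MLP drops toward chance.

## Known limitations

* Linear voxel encodings only; no nonlinear receptive-field structure.
* The toy extractors share no weights with any published network; all
  feature-space claims are internal to the simulation.
* The brain-loss penalty selection uses generalized cross-validation as a
  stand-in for an external calibration procedure.
* Inter-site evaluation is limited to decoding/identification metrics, as
  no measured target responses exist for the source's stimuli — matching
  the real inter-site situation.
* The dyadic bootstrap's truncate/refill rule is one of several reasonable
  readings of resampling "data points of the original sample size"; the
  implementation is documented and oracle-tested against its own
  specification.
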