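# ncconvert

Functional alignment of fMRI activity patterns between individuals —
without shared stimuli.

## The problem

Multivoxel response patterns are idiosyncratic: the same image evokes
different fine-grained patterns in different brains, and classical
functional alignment (neural code converters, hyperalignment) needs both
subjects to have seen identical stimuli so that paired patterns can be
regressed onto each other. Such shared stimuli are usually unavailable,
especially across datasets from different sites.

`ncconvert` implements a **content-loss neural code converter**: a mapping
Φ from a source subject's voxel space (m voxels) into a target subject's
voxel space (n voxels) trained so that the target's *pre-trained feature
decoders*, applied to the converted pattern, reproduce the true
hierarchical features of the stimulus the source saw:

    L(Φ) = Σ_i Σ_l η_l ‖ v_il − (W_l Φ(x_i) + b_l) ‖²,   η_l = 1/‖v_il‖²

where `x_i` is the source pattern for stimulus `i`, `(W_l, b_l)` is the
target's frozen ridge decoder for feature layer `l`, and `v_il` the true
feature vector. Training needs the source's own responses and stimulus
features only — no paired brain data. Φ is an MLP (two hidden layers of
m/2 units, instance normalization + ReLU; affine and residual variants),
trained with a stochastic schedule that decodes one random feature map per
convolutional layer (all dense units) per iteration.

The package also provides, end to end and fully simulated (no fMRI data,
no pretrained network weights):

* a differentiable toy hierarchical feature extractor (+ a second,
  patch-embedding extractor for cross-decoder tests) and shape arithmetic
  for standard architectures (`layer_unit_count()`);
* virtual subjects: procedural stimulus worlds, sparse Gaussian voxel
  encodings over a shared content space, repetition noise at controlled
  SNR, category-disjoint splits (`make_stimulus_world()`,
  `make_virtual_subject()`, `simulate_session()`);
* per-layer ridge feature decoding with correlation-based voxel selection
  (`fit_feature_decoder()`, `decode_features()`);
* brain-loss ridge and orthogonal Procrustes baselines (paired data);
* noise-ceiling-normalized pattern/profile conversion metrics, pairwise
  identification, pair enumeration, dyadic bootstrap CIs;
* feature-inversion image reconstruction with texture/structure similarity
  losses built from per-channel spatial statistics
  (`reconstruct_image()`);
* an experiment workbench (`run_conversion_experiment()` and friends) and
  a CLI (`inst/cli/ncc.R`).

## Worked example

Two simulated subjects from one site, converters trained in both
directions, conversion accuracy against the measured target activity
(normalized by noise ceilings) and identification from decoded features:

```r
library(ncconvert)

cfg <- experiment_config(datasets = c(siteA = 2L), n_train = 150, n_test = 40,
                         image_size = 16, iterations = 512, seed = 1)
metrics <- run_conversion_experiment(cfg, scope = "within_dataset", max_pairs = 2)
aggregate(value ~ condition + metric,
          data = metrics[metrics$metric %in%
                           c("conversion_pattern", "identification"), ],
          FUN = mean)
#>      condition             metric     value
#> 1   brain_loss conversion_pattern 0.8938469
#> 2 content_loss conversion_pattern 0.7815665
#> 3   brain_loss     identification 0.5926282
#> 4 content_loss     identification 0.6012821
```

The content-loss converter — trained with **no access to the target's
brain data** — reaches a normalized pattern correlation close to the
brain-loss baseline that *was* trained on paired responses, and slightly
higher identification accuracy of the features decoded from its output;
the same qualitative picture the method is built around. `metrics` holds
the per-pair, per-layer rows; `summarize_pairs()` adds dyadic bootstrap
CIs; `run_training_size_ladder()` and
`run_cross_decoder_generalization()` reproduce the data-efficiency and
generalizability analyses.

See the vignette (`vignettes/content-loss-conversion.Rmd`) for the model,
the simulation's design and its limits, and all numerical choices.

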