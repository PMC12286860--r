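Package: ncconvert
Title: Content-Loss Neural Code Conversion for fMRI Activity Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Functional alignment of brain activity patterns between individuals
    without shared stimuli. Implements a content-loss neural code converter that
    maps a source subject's multivoxel patterns into a target subject's voxel
    space by minimizing the discrepancy between stimulus features decoded from
    the converted activity (through the target's pre-trained ridge feature
    decoders) and the true stimulus features, together with brain-loss ridge and
    orthogonal Procrustes baselines, noise-ceiling-normalized conversion
    metrics, pairwise identification analysis, dyadic bootstrap inference, and
    feature-inversion image reconstruction with texture and structure
    similarity losses. A virtual-subject simulation framework (a differentiable
    toy hierarchical feature extractor plus random linear voxel encodings)
    exercises the full pipeline end-to-end without any fMRI data or pretrained
    network weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
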