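Package: arenaneuro
Title: Encoding, Decoding and Manifold Analysis of Freely Moving Neural Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for analysing neural population recordings from
    freely moving animals in a three-dimensional arena. Provides a synthetic
    session generator with planted, recoverable ground truth (spatial fields,
    reference-frame tuning, behavioral-syllable gains, context interactions,
    anticipatory ramps); pose cleaning and kinematic feature extraction; ridge
    encoding models with blocked, embargoed temporal cross-validation and
    shuffle-based unique-variance decomposition; allocentric versus egocentric
    reference-frame comparison; unsupervised behavioral syllable segmentation
    (pairwise-distance features, identity-filtered PCA, Morlet wavelets,
    density watershed); population decoding with permutation nulls and
    temporal generalization; and population-manifold statistics (context
    ratio, anticipatory drift, transition velocity) with circular-shift nulls.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    class,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
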