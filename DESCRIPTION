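Package: cftpet
Title: Computer-Aided Classification of Parkinsonian Disorders from
    Dopamine-Transporter PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end framework for differential diagnosis of
    parkinsonian disorders (Parkinson's disease, multiple system atrophy,
    progressive supranuclear palsy) from dopamine-transporter PET imaging
    with anatomical MRI assistance. Provides a synthetic phantom generator
    for paired MRI/PET volumes with group-specific striatal uptake and
    bilateral asymmetry, ROI segmentation with atlas and learned backends,
    rigid multimodal registration by mutual information, equal-volume
    tripartition of caudate and putamen by balanced k-means, computation of
    striatal-to-occipital ratios and asymmetry indexes, linear
    squared-hinge support-vector classification with leave-one-out
    cross-validation and stage-stratified training strategies, random-forest
    region-contribution analysis with McNemar comparison, and
    confusion-matrix diagnostics (sensitivity, specificity, predictive
    values, rank-based AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml,
    nnet,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    pROC,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'evaluation.R'
    'classification.R'
    'phantom.R'
    'features.R'
    'importance.R'
    'io.R'
    'pipeline.R'
    'registration.R'
    'segmentation.R'
    'subregions.R'
    'utils.R'
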