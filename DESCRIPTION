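Package: octasm
Title: 3D Active Shape Model Synthesis of Macular OCT Retinal Layer Boundaries
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Statistical shape modelling of macular optical coherence
    tomography (OCT) retinal layer boundaries for synthetic data generation
    and diagnostic-model augmentation. Builds 3D point distribution models
    (Procrustes alignment plus PCA over 18,200 landmark points) from dense
    boundary stacks, synthesizes new anatomically valid boundary stacks from
    constrained mode weights, derives per-layer retinal thickness maps, and
    validates synthetic cohorts with histogram similarity metrics
    (correlation, chi-square, intersection, Bhattacharyya/Hellinger),
    pairwise peak cross-correlation / mean absolute error / Kolmogorov-
    Smirnov analyses, and an RBF-SVM classification experiment with nested
    stratified cross-validation comparing shape-model augmentation against
    SMOTE. Includes a seeded generator of artificial cohorts emulating
    healthy-control, multiple sclerosis and neuromyelitis optica thickness
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'augmentation.R'
    'cli.R'
    'fixtures.R'
    'histMetrics.R'
    'io.R'
    'landmarking.R'
    'octasm-package.R'
    'pairwiseMetrics.R'
    'shapeModel.R'
    'thickness.R'
    'utils.R'
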