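Package: oliveGrade
Title: Grading Olive Batches as Tree- or Ground-Picked from RGB Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies batches of olives arriving at an oil mill as picked
    from the tree or collected from the ground, using a single RGB photograph
    per batch. Texture is captured by a Roberts-operator gradient image and
    oxidation browning by red-green and red-blue channel-difference images;
    the three 256-bin gray-level histograms are concatenated into a
    768-component feature vector, standardized, filtered by one-way ANOVA
    F-statistics, and reduced by principal component analysis before
    classification with Fisher discriminant analysis or a single-hidden-neuron
    sigmoid perceptron trained by scaled conjugate gradient. Evaluation
    follows stratified 2-fold cross-validation repeated three times, reporting
    correct classification percentages. A synthetic batch-image generator
    emulating the two classes makes the whole pipeline testable without real
    imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    png,
    tiff,
    jpeg,
    jsonlite,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
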