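Package: mwistroke
Title: Synthetic Microwave-Scattering Data and Stroke Classification for
    Microwave Brain Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fast physics-based generation of labelled microwave scattering
    datasets for brain-stroke classification. Builds layered multi-tissue
    tetrahedral head phantoms, assembles the distorted-Born linearized
    scattering operator mapping per-tetrahedron dielectric-contrast
    perturbations to differential antenna-array scattering parameters at
    1 GHz, inserts random ischemic and haemorrhagic stroke scenarios with
    contrast-domain noise, emulates non-nominal coupling media with
    calibration to the nominal system, morphs tissue boundaries and
    dielectric heterogeneity to produce head-model families, and trains and
    evaluates SVM, multilayer-perceptron and k-nearest-neighbour classifiers
    with nine-class and macro-class confusion-matrix reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    e1071,
    class,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
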