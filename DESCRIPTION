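Package: sausi
Title: Quantification of Social Aversion from Dyadic Pose Tracking and Ethograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying rodent social aversion in a two-chamber
    selective-access assay from two-animal keypoint trajectories and scored
    behavioral event logs. Computes the full ethogram metric set (sniffing,
    social freezing, reactivity, tunnel hesitancy, chamber preference and
    related measures), a composite sign-aligned z-score index of social
    aversion, housing-condition decoding by penalized logistic regression
    with feature-importance reporting, an unsupervised behavior map (posture
    angles, PCA, 2-D embedding, density watershed regions) with region
    occupancy statistics, and threat-imminence profiles of behavior against
    nose-to-nose distance. Includes a seeded two-animal session simulator
    that generates trajectories with matched ground-truth event logs so the
    whole pipeline is testable without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    rhdf5,
    uwot
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'artifacts.R'
    'aversion.R'
    'utils-geometry.R'
    'metrics.R'
    'continuum.R'
    'decoder.R'
    'io.R'
    'mapping.R'
    'methods-accessors.R'
    'pipeline.R'
    'sausi-package.R'
    'simulate.R'
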