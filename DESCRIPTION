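Package: headreach
Title: Kinematic Analysis of Occiput-Reaching Motion in Hemiplegia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates and analyses three-dimensional marker trajectories of
    the seated occiput-reaching task used to characterise upper-limb motor
    function in mild post-stroke hemiplegia. Provides a minimum-jerk motion
    generator with side-dependent kinematics, marker-based segmentation of
    outward and return phases, Euler joint-angle and angular-velocity feature
    extraction, multivariate covariate-adjusted side comparison, binomial
    logistic discrimination with ROC/Youden cutoffs and DeLong AUC tests,
    exact binomial sample-size search, and unsupervised random-forest
    proximity clustering of motion patterns with elbow-method cluster-count
    selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    cluster,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
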