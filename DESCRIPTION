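Package: pupiladapt
Title: Pupillometry and Behaviour During Force-Field Reach Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for studies that track pupil
    diameter while humans adapt their reaching movements to velocity-dependent
    curl force fields.  Provides a synthetic-cohort generator (perturbation
    schedules with channel and light-reflex trials, a two-state motor learner,
    and a generative tonic/phasic pupil model with known ground truth), the
    standard pupillometry preprocessing chain (blink interpolation, Gaussian
    smoothing, Savitzky-Golay differentiation, saccade detection, light-reflex
    normalization), per-trial feature extraction (kinematic errors, channel
    learning index, baseline pupil, dilation velocity), two-state model
    fitting with bootstrap washout prediction, frame-wise running t-tests with
    Holm-Bonferroni and Benjamini-Hochberg correction, cluster-mass sign-flip
    permutation tests, and experiment-level analyses (change-point response
    modelling, set-break contrasts, recall-based median splits).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    stats,
    generics,
    lme4,
    lmerTest,
    signal,
    pracma,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
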