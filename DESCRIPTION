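Package: seegplan
Title: Spatial-Prior-Constrained Trajectory Planning and Vessel Risk Scoring
    for SEEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for computer-assisted planning of stereoelectroencephalography
    (SEEG) depth-electrode trajectories. Implements a vessel-proximity risk
    score for straight stereotactic trajectories (128-node sampling with 3 mm
    safety and 10 mm risk margins), per-electrode safety metrics (intracranial
    length, drilling angle to the outer skull table, gray:white matter sampling
    ratio, minimum vessel distance), construction of spatial-prior ellipsoids
    from historical implantations (grouping, lesional and outlier exclusion,
    PCA ellipsoid fitting), a prior-constrained candidate planner with hard
    feasibility constraints and inter-electrode spacing guarantees, the
    evaluation statistics used to validate such planners (Fisher exact 2x2,
    Bonferroni adjustment, Krippendorff's alpha, paired t-test, random-intercept
    moment estimator), and seeded synthetic head phantoms so the full pipeline
    runs without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    RNifti,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
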