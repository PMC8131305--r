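Package: stapetrack
Title: Automated Detection of Electrically Evoked Stapedius Reflexes in
    Surgical Microscope Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects electrically evoked stapedius reflexes (eSR) in
    grayscale video of the middle ear recorded through a surgical
    microscope during cochlear implantation. The pipeline stabilizes the
    scene against a promontory reference patch by normalized
    cross-correlation, seeds sub-pixel markers on the stapedius tendon
    from maximally stable extremal regions (MSER), tracks them with a
    pyramidal Kanade-Lucas-Tomasi tracker, denoises the tendon
    displacement signal with a Savitzky-Golay filter, and classifies each
    electrical stimulus by comparing the post-stimulus displacement peak
    against a robust pre-stimulus noise floor. Includes reflex-threshold
    (eSRT) estimation over stimulation-level sweeps, a ground-truthed
    synthetic scene generator for validation, audio sync-tone alignment
    of stimuli, and the cohort statistics layer (pairwise rater
    chi-square tests with Bonferroni correction, intensity-amplitude
    Pearson correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    tiff,
    png,
    tools,
    utils,
    yaml,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
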