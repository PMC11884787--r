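Package: moviemap
Title: Movie-Evoked Retinotopic Map Analysis via Homotopy, ICA and Shared
    Response Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for studying the organization of visual cortex
    from movie-watching fMRI without a retinotopy task. Provides
    cross-hemisphere homotopic correlation contrasts with bootstrap inference
    and multidimensional scaling of area similarity, spatial independent
    component analysis with gradient-profile validation of candidate
    retinotopic maps and a rolled-component null, and shared response model
    (SRM) fitting with frozen-model projection for cross-participant map
    prediction against flipped-time and anatomical-average baselines. A
    synthetic cortical sheet generator supplies two-hemisphere retinotopic
    ground truth (spatial-frequency and meridian maps, traced gradient lines)
    and movie-like recordings with shared low-rank stimulus drive, noise and a
    motion confound, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    cluster,
    digest
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    withr
Config/testthat/edition: 3
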