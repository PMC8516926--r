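Package: arousalwaves
Title: Phasic Arousal Bursts, Cortical Travelling Waves and the BOLD
    Energy Landscape
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline linking phasic bursts in subcortical
    arousal nuclei (locus coeruleus, basal nucleus of Meynert) to
    cortical travelling waves, time-resolved network integration and a
    mean-squared-displacement (MSD) energy landscape of parcellated BOLD
    dynamics.  Includes second-derivative phasic event detection with a
    sustained-elevation criterion, event-locked time-to-peak wave mapping
    and velocity estimation, multiplication-of-temporal-derivatives
    connectivity, signed Louvain modularity with consensus clustering,
    participation coefficients, Gaussian-KDE energy landscapes with
    non-negative decomposition of the joint landscape, block-resampled
    null models, finite-impulse-response event-locked responses, and a
    synthetic cohort generator with full ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    pracma,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    RNifti
Config/testthat/edition: 3
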