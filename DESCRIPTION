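Package: massprint
Title: MALDI-TOF Proteomic Fingerprinting for Metazoan Species Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end workflow for identifying metazoan specimens from
    MALDI-TOF mass-spectrum fingerprints (2-20 kDa). Provides deterministic
    spectrum preprocessing (trimming, square-root transform, Savitzky-Golay
    smoothing, SNIP baseline removal, total-ion-current normalisation),
    SNR/half-window peak picking with strict cross-spectrum binning iterated
    to convergence, arc-length quality screening, random-forest
    identification with an empirical post-hoc acceptance test on out-of-bag
    assignment probabilities, higher-taxon (class/phylum) fallback models,
    congeneric-affinity analysis, Gini-importance peak ranking,
    bootstrap-supported hierarchical clustering, data-processing
    hyperparameter optimisation with a binomial GAM driver analysis,
    reference-library sizing (specimens-per-species saturation) curves, and
    a synthetic fingerprint simulator for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    randomForest,
    mgcv,
    ape,
    stats,
    utils
Suggests:
    mzR,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
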