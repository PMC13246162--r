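Package: condsieve
Title: Size Exclusion and Client Recruitment in Biomolecular Condensates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying how the conformational entropy of
    intrinsically disordered regions (IDRs) excludes neutral particles from
    biomolecular condensates, and how favourable binding overcomes that
    barrier to recruit clients. Provides a closed-form theory engine
    (semidilute blob scaling of the correlation length, a unified insertion
    free-energy expression, partition coefficients, and a recruitment free
    energy), a coarse-grained sticker-spacer Langevin dynamics simulator with
    FENE/harmonic bonds, WCA repulsion and short-range sticker attraction, a
    hard-sphere Widom insertion estimator with pressure-volume correction,
    coexistence-trajectory analysis (density profiles, measured partition
    coefficients, dissociation constants), and parameter-fitting utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
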