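Package: hopchem
Title: Chemometric Quantitation and Chemotaxonomic Classification of Wild Hops
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for UPLC-DAD phytochemical profiling of wild
    hops (Humulus lupulus) germplasm: seeded simulation of multi-channel
    diode-array chromatograms, peak detection and baseline-aware trapezoidal
    integration, linear calibration and ICE-3 standard based quantitation of
    prenylchalcones, alpha/beta bitter acids and leaf flavonol glycosides,
    per-accession trait statistics (totals, cohumulone proportion, alpha
    ratio, malonyl-flavonol proportion), subspecies chemotype classification
    (cone xanthogalenol/4'-O-methylxanthohumol marker rule and the leaf
    malonyl-ester rule) with concordance analysis, and theoretical
    ESI+/ESI- ion series prediction for flavonol glycoside annotation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    pracma,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
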