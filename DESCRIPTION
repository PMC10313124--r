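Package: microgamma
Title: Microdosimetric Gamma Model of Radiation-Induced DNA Damage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Implements the Microdosimetric Gamma Model (MGM): closed-form
    predictions of the number of DNA damage sites induced per ionizing track
    and of their complexity distribution, parameterized by the frequency-mean
    lineal energy (yF). Includes a reader/writer for a minimal dialect of the
    Standard DNA Damage (SDD) text format, damage-complexity scoring and
    per-track yield analysis with track bootstrapping, yF/zF microdosimetric
    conversions, calibration of all model functions from per-track damage
    summaries, a spatial damage-realization generator for spherical nuclei,
    and a sigmoid repair model propagated to cell survival and RBE.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    IRanges,
    S4Vectors,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
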