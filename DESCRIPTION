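Package: pccdose
Title: Cytogenetic Biodosimetry with Dicentric and G2-PCC Aberration Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for cytogenetic radiation biodosimetry based on
    unstable chromosome aberrations (dicentrics, centric and acentric rings,
    and acentric fragments) scored in metaphase spreads or calyculin
    A-induced G2-phase prematurely condensed chromosomes (G2-PCC). Provides
    per-cell score-sheet data structures and readers, per-dose yield and
    variance-to-mean dispersion statistics with the Papworth U test,
    linear-quadratic dose-response calibration by Poisson maximum
    likelihood, absorbed-dose estimation with exact (Garwood) Poisson
    confidence limits propagated through the inverse calibration curve,
    triage-mode scoring truncation, multinomial comparison of aberration
    spectra between chromosome preparations, and a seedable score-sheet
    simulator. Ships the per-dose scoring data of an X-ray dose-response
    study (0-20 Gy) as plain-text fixtures so every analysis step can be
    exercised at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
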