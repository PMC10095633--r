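Package: lipaff
Title: Intrinsic Ligand-Protein Affinities in Media Containing Lipid
    Bilayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Equilibrium framework for the distribution of a ligand among
    the aqueous medium, a lipid bilayer, and a protein with a single
    binding site.  Computes exact ligand distributions from mass balance
    (analytical quadratic solution in the dilute regime and an exact
    local-concentration formulation for concentrated media), relates
    binding constants and partition coefficients through thermodynamic
    cycle closure, predicts and inverts the bias between apparent and
    intrinsic binding affinities caused by ligand sequestration in (or
    exclusion from) the lipid phase, fits titration data with the full
    model and with the commonly used approximate models, and provides a
    seeded synthetic-titration generator and simulation scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
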