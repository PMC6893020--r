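Package: allerquant
Title: Quantitative Analysis of Allergen Stability and Endosomal Processing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying how hydrophobic ligand binding alters the
    stability and endosomal processing of lipid-binding allergens such as the
    cockroach allergen Bla g 1. Implements stable-isotope (natural abundance
    vs uniform 15N) MALDI peak-pair matching and ratio time-courses for
    protease digestion experiments, in-silico fragment enumeration with
    label-dependent monoisotopic or average peptide masses, mapping of
    digestion fragments onto T-cell epitope intervals, two-state Boltzmann
    fits of thermal melt curves with a 25%-denaturation melting temperature,
    concentration-normalized cathepsin proteolysis rates from SDS-PAGE
    densitometry, and lipid:protein binding stoichiometry from linear 31P NMR
    standard curves. A synthetic-data module generates every input with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    dplyr,
    jsonlite,
    minpack.lm,
    S4Vectors,
    stats,
    tibble,
    utils,
    withr
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
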