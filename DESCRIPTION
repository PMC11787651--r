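Package: histoneDIA
Title: Histone PTM Quantification from DIA (SWATH) Mass Spectrometry
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A desk-scale toolkit for quantifying histone post-translational
    modifications from data-independent acquisition (SWATH) runs of
    propionylated histone digests. Builds in-silico target databases
    (derivatized tryptic digestion, PTM form enumeration, isobaric grouping),
    designs fixed- and variable-width precursor isolation window schemes,
    converts mzML/mzXML runs to the plain-text ms1/ms2 spectral formats,
    extracts isotope-cluster ion chromatograms, integrates peaks with
    retention-time-driven identity assignment, splits co-eluting positional
    isomers with linear equations on discriminating fragment-ion signals,
    and reports replicate QC (peptide ratios, CVs, points across the peak).
    Includes a DIA run simulator with known ground truth so every pipeline
    stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    mzR,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
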