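Package: fpopquant
Title: Quantitation of Covalent-Labeling / FPOP Footprinting Mass Spectrometry Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computes the extent of modification (EOM) for hydroxyl radical
    protein footprinting (FPOP/HRPF) and other covalent-labeling mass
    spectrometry experiments from search-engine PSM tables. Reads Proteome
    Discoverer, FragPipe and generic exports, parses and classifies localized
    modifications against an extensible catalog, applies fidelity filters
    (search-node duplicate removal, missing-unmodified-area exclusion,
    replicate-support threshold, both-conditions protein restriction), and
    reports control-subtracted, replicate-averaged peptide- and residue-level
    EOM together with average peptide oxidation events (APO), condition
    comparisons, bar/grouped-bar/Venn graphics, and a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    readxl,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
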