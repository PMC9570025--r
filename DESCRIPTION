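Package: venomdimorph
Title: Sex-Specific Venom Peptide Identification from Proteo-Transcriptomic Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies sexually dimorphic venom peptides in scorpions by
    integrating three evidence layers: maturation of venom precursor proteins
    under a processing grammar (signal-peptide removal, mono-/di-/tribasic
    cleavage sites, quadruplet motifs, C-terminal Gly amidation, allelic
    expansion), monoisotopic [M+H]+ prediction with post-translational
    modification corrections (C-terminal amidation, disulfide bridges),
    reproducibility-filtered matching against replicate MALDI-TOF peak lists,
    PSM and annotation quality filtering, and a three-way expression contrast
    (male telson, female telson, negative control), yielding up- or
    down-in-males calls per precursor. Ships a curated reference set of twelve
    Euscorpius italicus venom precursors and a synthetic-data generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
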