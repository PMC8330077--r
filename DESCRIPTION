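Package: methatlas
Title: CpG Observed/Expected Profiling, LUMA Simulation and Ancestral
    Methylation-Machinery Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for building a DNA-methylation atlas of a transcriptome
    and its methylation machinery. Computes per-sequence CpG
    observed/expected (o/e) ratios, estimates their distribution by kernel
    density with bootstrap confidence intervals, detects modes and
    classifies gene-body methylation types; simulates
    methylation-sensitive restriction digestion (HpaII/MspI/EcoRI) of
    genomes with known CCGG methylation states and estimates percent
    methylation by the LUminometric Methylation Assay (LUMA) peak-ratio
    formula; quantifies per-CpG methylation from bisulfite read sets;
    reconstructs ancestral presence/absence of DNA-methylation and NuRD
    gene families by Dollo parsimony on (possibly polytomous) species
    trees; and categorizes expression fold changes between developmental
    stages. Seeded synthetic-data generators produce every input the
    pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
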