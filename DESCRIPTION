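Package: phageMosaic
Title: Comparative Genomics of Temperate Phage Genomes and Their Mobile Elements
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of closely related bacteriophage
    genomes: fragment-based average nucleotide identity, single-linkage
    protein phamily clustering under a dual identity/E-value threshold,
    detection and classification of intervening mobile elements (group I
    introns by splice restoration, protein inteins, transposons with
    target-site duplications, free-standing homing endonucleases),
    discovery of attP/attB integration cores with arm-type repeat scanning,
    and icosahedral capsid stoichiometry from triangulation numbers.
    Includes a deterministic synthetic-genome generator that plants every
    element class with a machine-readable truth log, so detection can be
    validated end-to-end against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
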