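Package: operonDMS
Title: Deep Mutational Scanning Analysis of Single-Codon Saturation
    Libraries in Operonic Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of site-saturation (NNK) deep
    mutational scanning libraries of an operonic gene, modelled on a
    toxin-antitoxin antitoxin screen: simulation of NNK libraries with
    known survival effects, paired-end amplicon read processing
    (demultiplexing, quality filtering, pair merging, local alignment,
    single-codon variant calling, Poisson sequencing-error read
    thresholds), enrichment scoring (survival score, ES, fitness,
    phenotype classes, per-position summaries), codon-optimality
    features (relative codon usage, relative tRNA abundance, relative
    GC, base changes, relative ribosome stalling, codon adaptation
    index), anti-Shine-Dalgarno hybridization window scans and
    ribosome-binding-site strength, and Mann-Whitney feature-phenotype
    association reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
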