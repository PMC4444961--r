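Package: socmir
Title: Phylogenetic Profiling of microRNA Presence and Absence Across
    Insect Genomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative phylogenetic profiling of mature
    microRNAs across genome panels. Builds a deduplicated query catalog
    from miRBase-style mature FASTA files, scores each miRNA as present
    or absent in each genome by strand-aware exact sequence matching,
    assembles and orders the resulting binary profile matrix along a
    species phylogeny, reconstructs gain and loss histories under Fitch,
    Dollo, and weighted parsimony, and screens for candidates whose
    distribution tracks a convergent trait (such as eusociality in the
    aculeate Hymenoptera) or is universal to a named clade. Includes a
    generator for fully synthetic genome panels with known gain/loss
    ground truth and a packaged worked-example profile of hymenopteran
    eusociality-associated miRNAs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    grDevices,
    graphics,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
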