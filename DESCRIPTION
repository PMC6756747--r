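Package: peptimine
Title: Motif-Based Neuropeptide Mining and Reduced-Database Spectral Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mines protein databases for putative neuropeptide precursors using
    structural hallmarks of mature neuropeptides (C-terminal amidation signals,
    N-terminal glutamine or early prolines), cleaves candidate peptides in
    silico, expands them into post-translationally modified variants
    (C-terminal amidation of glycine-extended peptides, N-terminal
    pyroglutamate, methionine oxidation), and matches singly charged MALDI
    tandem mass spectra against the resulting reduced peptide database with
    precursor and fragment mass tolerances. Includes a bilaterian dibasic
    cleavage-site engine for comparison, shuffled-sequence decoy database
    construction, a brute-force no-enzyme search-space counter, a census of
    neuropeptide hallmark motifs over curated peptide lists, and a seeded
    synthetic-fixture generator (precursor architectures and b/y fragment
    spectra) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
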