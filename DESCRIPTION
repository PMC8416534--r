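Package: pepscout
Title: Selection of Function-Specific Tryptic Peptides for Targeted
    Metaproteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Designs function-based targeted proteomic assays for complex
    microbial communities. Given a set of homologous protein sequences for
    one enzymatic function (a UniProt-style reference set, a custom
    metagenome-derived set, or both), pepscout digests the proteins in
    silico with trypsin, indexes every peptide against the taxa and
    proteins that encode it, screens candidates for chemical-modification
    proneness, LC-MS/MS detectability and BLASTP-based functional
    specificity, and shortlists peptides that greedily maximize genus- and
    species-level coverage. A synthetic-fixture module generates homolog
    families and BLAST results with known ground truth so the whole
    pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    xml2,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
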