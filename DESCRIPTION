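Package: ersitemap
Title: Integrative Mapping of Estrogen Receptor Alpha and Beta Binding Sites
Version: 0.1.0
Authors@R:
    person("ersitemap", "authors", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of estrogen receptor (ER) alpha and beta
    ChIP-Seq binding-site maps in hormone-responsive breast cancer cells:
    peak extension and merging into binding regions, receptor-subtype
    partitioning (heterodimer/homodimer), prevalent-site extraction, a
    six-class co-binding taxonomy across wild-type and ERbeta-expressing
    cells, estrogen response element (ERE) and hemi-ERE matrix scanning
    with MatInspector-style core/matrix similarity, transcription factor
    binding site over-representation Z-scores against a genomic
    background, differential-expression regulation groups from Illumina
    DiffScores, primary target gene linking within 10 kb of the
    transcription unit, a matched bootstrap null for pre-miRNA proximity,
    and a mitochondrial tag-density filter. Ships a synthetic-data
    generator so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
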