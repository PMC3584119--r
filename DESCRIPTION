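Package: mitosig
Title: Comparative Mitogenomics: Annotation, Alignment, Phylogenetic Signal and
    Clade Signatures for Processionary Moths
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for comparative analysis of lepidopteran
    mitogenome segments: rule-based annotation of protein-coding genes
    (including truncated stop codons), tRNA cloverleaf detection, rRNA
    boundary assignment and intergenic-spacer extraction; codon-aware and
    structure-guided multiple alignment with named concatenations and
    partition schemes; quartet likelihood mapping of phylogenetic signal;
    p-distance matrices with within- and among-clade summaries; detection of
    clade-diagnostic spacer and tRNA-loop signatures on a reference tree; and
    unordered-parsimony ancestral reconstruction of categorical life-history
    traits.  A synthetic-data generator with full ground truth makes every
    stage testable without sequence downloads.
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
    tools,
    utils,
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Collate:
    'templates.R'
    'model.R'
    'simulate.R'
    'annotate.R'
    'align.R'
    'likelihood.R'
    'quartet.R'
    'pdist.R'
    'parsimony.R'
    'signatures.R'
    'pipeline.R'
    'data.R'
    'mitosig-package.R'
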