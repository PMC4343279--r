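Package: meshora
Title: MeSH Term Over-Representation Analysis with Annotation Stores,
    Ortholog Transfer and FDR Control
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A self-contained toolkit for over-representation analysis (ORA)
    of gene lists against Medical Subject Headings (MeSH) annotations. It
    provides an in-memory and on-disk gene-to-term annotation store with a
    SELECT-style retrieval interface and poly-hierarchy queries, builders
    that derive gene-to-MeSH links from literature links (gene2pubmed-style
    joins) or project them across organisms by reciprocal-best-hit sequence
    comparison, an exact hypergeometric enrichment engine, and three
    false-discovery-rate correction methods (Benjamini-Hochberg, q-value
    with spline pi0 estimation, and local FDR via a Grenander density
    estimate). Synthetic fixture generators allow every component to be
    exercised and benchmarked without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Annotation, GeneSetEnrichment, MultipleComparison, Software
RoxygenNote: 7.3.3
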