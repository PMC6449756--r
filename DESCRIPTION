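Package: phylosplit
Title: Phylogenetic Detection of Split Genes in Draft Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects pairs of annotated genes that are in fact
    non-overlapping (or marginally overlapping) fragments of a single
    gene, a frequent artifact of fragmented genome assemblies and their
    annotations. Within each gene family, candidate pairs from a target
    genome are screened by an aligned-overlap filter and then tested with
    two complementary phylogenetic tests: collapsing weakly supported
    branches of the family tree and checking whether the fragments become
    sister leaves, and a likelihood ratio test of the one-gene
    (concatenated) hypothesis against the two-paralog hypothesis whose
    null distribution is obtained by non-parametric bootstrap resampling
    of alignment columns. Predictions are combined by intersection and
    multi-way calls are classified as ambiguous or compatible multi-piece
    splits. Includes a synthetic-data generator that evolves protein
    families along a species tree and plants true splits and
    paralog-derived negative pairs for calibration and benchmarking.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    phangorn,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
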