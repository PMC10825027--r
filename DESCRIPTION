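Package: mhcbench
Title: Benchmarking Framework for Peptide-MHC Binding Predictors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for evaluating peptide-MHC binding predictors with an
    emphasis on alleles missing from a predictor's training data: population
    coverage of training-allele sets under Hardy-Weinberg genotype sampling,
    decoy spike-in benchmarking with fractional rank statistics corrected for
    binding-motif information content, AUPRC/PPV summaries with binding-core
    weighting, percentile bootstrap confidence intervals, HLA sequence-space
    mapping via PAM100 distances and classical multidimensional scaling, and
    residue-substitution (occlusion) sensitivity scanning.  A fully seeded
    synthetic world - clustered allele catalogs, Dirichlet population
    frequencies, and a deterministic pocket-keyed position-weight-matrix
    predictor - makes every stage testable end-to-end without external tools
    or datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
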