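Package: phybench
Title: Benchmarking Phylogenetic Tree Inference on Simulated Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A self-contained toolkit for benchmarking phylogenetic tree
    inference. Simulates DNA multiple sequence alignments along reference
    trees under the general time-reversible model with discrete Gamma rate
    heterogeneity and an optional Zipfian insertion/deletion process whose
    parameters can be calibrated against target alignment statistics
    (sites, site patterns, gap fraction). Ships built-in inferrers (BIONJ,
    Fitch parsimony with random stepwise addition, NNI hill-climbing
    maximum likelihood) and an adapter contract for external tools, scores
    inferred trees against reference trees with Robinson-Foulds,
    normalized tree and quartet distances and log-likelihood differences,
    runs the approximately unbiased test via multiscale RELL bootstrap to
    flag statistically plausible trees, computes a ground-truth difficulty
    score from replicate searches, and aggregates results into
    difficulty buckets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    phangorn (>= 2.8),
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
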