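Package: spikegene
Title: Bayesian Spike-and-Slab Gene-Based Association for Rare and Common Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical Bayesian mixture model for identifying genes that
    contain rare and common variants associated with a binary phenotype.
    Genotypes are coded additively and standardized by allele frequency so
    that rare-variant effects are expressed on a common liability scale;
    per-gene collinear SNPs are pruned by a prefix-rank scheme; gene- and
    SNP-level inclusion is estimated with a spike-and-slab
    Metropolis-Hastings-within-Gibbs sampler using Polya-Gamma data
    augmentation for the logistic likelihood. Includes highest posterior
    density intervals, effective-size and Raftery-Lewis convergence
    diagnostics, and a synthetic mini-exome generator for validation at
    desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, grDevices, graphics, tools, jsonlite
Suggests: testthat (>= 3.0.0), vcfR, coda, optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
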