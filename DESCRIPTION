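Package: femnet
Title: Functional Epigenetic Module Discovery on Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects interactome hotspots of coordinated differential DNA
    methylation associated with a binary phenotype and filters them to
    functionally deregulated modules by requiring concordant, anti-correlated
    differential mRNA expression (the EpiMod/FEM two-step analysis).
    Provides supervised per-CpG logistic regression likelihood-ratio
    statistics with Storey q-value false discovery rates, closest-to-TSS
    promoter CpG selection, statistic-weighted network construction, a
    seeded spin-glass (constant Potts) module search with statistic
    permutation and degree-preserving rewiring null models, Fisher exact
    gene-set enrichment, a synthetic-data generator with planted hotspots
    and full ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
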