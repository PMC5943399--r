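Package: bloodbiome
Title: Microbial Diversity Profiling from Host-Unmapped RNA-Seq Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects and quantifies microbial transcripts in whole-blood
    RNA-seq by filtering host-unmapped reads (quality, complexity and
    residual-host screens with fixed-depth subsampling), assigning the
    surviving reads to taxa through a k-mer marker-gene index with
    lowest-common-ancestor fallback, and summarising the resulting
    abundance tables as alpha (inverse Simpson), beta (Bray-Curtis) and
    gamma (group richness) diversity. A reference-free companion distance
    computes the earth mover's distance between per-sample k-mer mass
    distributions over a de Bruijn graph ground metric. A statistics layer
    provides covariate-adjusted group contrasts on normalised alpha,
    Nagelkerke pseudo-R2 effect sizes from logistic regression, PERMANOVA,
    exact 2xK presence/absence tests, and cell-proportion associations.
    A synthetic-data module generates taxonomies, marker genes, reads,
    design tables and cell proportions with known truth so the whole
    pipeline is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    igraph,
    glmnet,
    Rsamtools,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
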