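Package: clonemap
Title: Bayesian Assignment of Single-Cell Clusters to Tumor Clones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns clusters of single tumor cells (for example B-cell-receptor
    clonotype clusters) to evolutionary tumor clones by matching allele-specific
    scRNA-seq transcript counts at mutated positions against binary clone
    genotypes. A Gibbs sampler over a beta-binomial graphical model jointly
    corrects the input clone genotypes and the input cell clustering while
    estimating cluster-to-clone and cell-to-clone posterior probabilities,
    the genotype error rate, and allelic success probabilities. Includes a
    synthetic-data generator with a matched exact-enumeration oracle,
    confidence metrics (normalized entropy, Gini index), agreement metrics
    (adjusted Rand index), and cluster-validity indices (Dunn, RMSSTD,
    Calinski-Harabasz, connectivity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    vegan,
    optparse,
    yaml
Config/testthat/edition: 3
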