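Package: mrtriad
Title: Two-Sample Mendelian Randomization with Literature Triangulation
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A self-contained toolkit for two-sample Mendelian randomization
    (2SMR) from GWAS summary statistics. Provides instrument selection
    (genome-wide significance filtering, MHC exclusion, greedy LD clumping,
    proxy-SNP substitution), allele harmonization with three palindromic-SNP
    strategies, causal-effect estimation (Wald ratio, inverse-variance
    weighted, MR-Egger, weighted/simple median, weighted/simple mode),
    sensitivity analyses (Cochran's Q, Egger intercept, Steiger
    directionality filtering, leave-one-out, single-SNP), phenome-wide
    scanning with Bonferroni control and Miami-plot export, and offline
    triangulation of causal estimates against literature-derived semantic
    triples. A simulation module generates paired exposure/outcome summary
    statistics, LD references and triple tables with known ground truth so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
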