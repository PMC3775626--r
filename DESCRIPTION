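Package: bwpd
Title: Balance-Weighted Phylogenetic Diversity and Alpha-Diversity Benchmarking
Version: 0.1.0
Authors@R: person("Parity", "Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Abundance-weighted phylogenetic alpha-diversity measures for
    microbial community profiles, centred on the one-parameter BWPD family
    that interpolates between classical (unrooted) Faith phylogenetic
    diversity and a fully balance-weighted extension. Also provides rooted
    abundance-weighted PD, phylogenetic quadratic entropy, phylogenetic
    entropy, Hill-number phylogenetic diversity, the discrete Shannon,
    Simpson, Chao1 and ACE measures, rarefaction machinery including a
    closed-form expectation of phylogenetic quadratic entropy under
    subsampling, a comparative framework that ranks measures by their
    ability to distinguish community states, a deterministic two-state
    community simulator, and a small command-line surface. Trees are read
    from Newick, count tables from TSV or BIOM-JSON v1.0.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    biomformat,
    vegan,
    phangorn,
    withr,
    boot,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
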