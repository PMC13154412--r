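Package: pepcoev
Title: Evolution-Guided Design of Fixed-Length MHC Class II Binding-Core Peptides
Version: 0.1.0
Authors@R:
    person("pepcoev", "maintainers", email = "pepcoev@example.org", role = c("aut", "cre"))
Description: Extracts first-order (per-site frequency and Kullback-Leibler
    conservation) and second-order (joint-frequency and coupling) evolutionary
    statistics from aligned, gap-free peptide sets grouped by HLA allotype, and
    generates artificial binding-core peptide sets that reproduce those
    statistics.  Three design routes are provided: independent per-position
    frequency sampling (FS), Monte Carlo simulated annealing on a
    coupling-matrix objective (MC1/MC2, with a compiled inner loop), and a
    small generative attention network trained with frequency and
    joint-frequency matching losses (L1/L2).  A mixture-of-profiles synthetic
    data module with closed-form target statistics supports testing and
    benchmarking, and an evaluation module compares designed sets against
    native sets via conservation profiles, coupling matrices, and Pearson
    correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
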