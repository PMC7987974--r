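Package: agaclust
Title: Simulation and Quantification of Aminoglycoside-Induced Translation Error Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying clusters of amino-acid misincorporations induced
    by aminoglycoside antibiotics (AGAs) in bacterial proteins. Implements a
    two-state (drug-bound/unbound) Markov model of ribosome elongation with
    stochastic AGA binding and retention that generates peptide-level
    mass-spectrometry-like intensity data, together with the error-frequency
    statistics used to quantify mistranslation from such data: per-substitution
    error frequencies from intensity ratios, cluster frequencies, error
    amplification over the stochastic expectation, three estimators of the
    conditional next-error frequency, distance-dependence profiles with
    exponential retention fitting, and drug-group classification. Also provides
    genetic-code utilities (near-cognate misreading enumeration,
    mismatch-position classification, in-silico tryptic digestion,
    cluster-candidate prediction) and the secondary normalizations used for
    proteotoxicity readouts (aggregation enrichment, thermostability curves,
    presence filtering, downshifted-normal imputation, interval scaling).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
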