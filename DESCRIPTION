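Package: pairkin
Title: Pairwise Relationship Inference from SNP Genotypes with Simulated
    Identity-by-Descent Ground Truth
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates pairs of relatives (full siblings through third
    cousins) by gene dropping on a sex-averaged genetic map, tracking true
    identity-by-descent (IBD) segments, and infers pairwise relationships
    from SNP genotypes with five statistical approaches: likelihood ratios
    with and without genetic linkage (a hidden Markov model over pairwise
    IBD states), maximum-likelihood estimation of the Cotterman kappa
    coefficients, the KING-robust method-of-moments kinship estimator, plain
    half-identical segment detection, and windowed kinship segment calling.
    Includes genotype-error injection, classification of pairs into
    relationship classes, classification-rate matrices, and an
    error-sensitivity experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite, vcfR
Suggests: testthat (>= 3.0.0), Matrix, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
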