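Package: triosvm
Title: Gene-Level Rare-Variant Association Tests in Parent-Child Trios
    with a Gaussian Support Vector Machine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Aggregates rare-variant transmission distortion across a gene
    in parent-child trios and tests for association with a dichotomous
    trait. Each child is encoded by the per-site difference between the
    observed and the Mendelian-expected number of rare alleles received
    from the parents, conditioning on parental genotypes as in family-based
    association tests so that population stratification does not contribute
    information. Affected and unaffected children are contrasted with a
    soft-margin Gaussian-kernel support vector machine trained in its dual
    form, and the area under the ROC curve of the cross-validated composite
    scores is tested against 0.5 with a one-sided asymptotic Gaussian test
    using the DeLong variance estimator. Includes a linkage-format (PED/MAP)
    reader, a configurable trio simulator with Mendelian transmission, a
    liability model with mixed-direction rare-variant effects, ascertainment
    and bootstrap resampling, and harnesses for type-I-error and power
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    pROC,
    e1071,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
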