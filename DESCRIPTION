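Package: lumipred
Title: Bioluminescent Protein Classification from PSSM Evolutionary Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for predicting bioluminescent proteins (luciferases,
    photoproteins) from evolutionary sequence profiles. Parses PSI-BLAST
    ASCII position-specific scoring matrices (PSSMs), transforms them into
    fixed-length descriptors -- the auto-covariance encoding (PSSM-AC),
    which captures local sequence-order correlation, and the order-free
    composition encoding (PSSM-400) -- and fits a radial-basis-function
    support vector machine with grid-searched cost and kernel width under
    stratified 10-fold cross-validation. Includes the maximum-lag selection
    sweep, sensitivity/specificity/accuracy and ROC/AUC evaluation for both
    cross-validated and independent-test protocols, and a seeded synthetic
    profile generator with class-dependent autocorrelation so the whole
    pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    withr,
    stats,
    utils,
    graphics
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
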