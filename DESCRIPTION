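Package: fuzzygrade
Title: Fuzzy-Logic Molecular Grading of Tumor Expression Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fuzzy-logic feature selection and classification for molecular
    grading of tumor gene-expression profiles. Expression values are min-max
    standardized and fuzzified with binomial or Gaussian membership functions;
    probes are ranked by a membership-margin criterion (MEMBAS); tumors are
    classified with the LAMDA fuzzy classifier (marginal and global adequacy
    degrees aggregated with mixed fuzzy connectives) into grade 1-like and
    grade 3-like classes with an equivocal score zone; minimal gene signatures
    are sized by incremental leave-one-out cross-validation. Includes a
    synthetic-cohort generator with known ground truth, cross-platform probe
    adaptation, and readers/writers for the tabular formats involved.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
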