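Package: refstab
Title: Reference-Gene Selection and Validation for qRT-PCR Normalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects and validates reference (housekeeping) genes for
    qRT-PCR normalization. Candidate isogenes are pre-screened from
    expression matrices by a weighted rank score of within-family
    coefficients of variation; single genes and all 2-4 gene combinations
    are ranked by the mean standard deviation of pairwise delta-Ct values;
    target genes are quantified by the delta-delta-Ct method against a
    chosen reference set; and reference choices are validated by
    residual-variance concordance of fold changes against an independent
    platform. Includes a synthetic-data generator with known ground-truth
    stability structure and a single-pass geNorm M-value comparator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
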