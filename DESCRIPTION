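Package: psvtyper
Title: Paralog-Specific-Variant Typing of CYP2A7/CYP2A6 Hybrid Alleles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers hybrid alleles between highly homologous gene paralogs
    (modelled on the CYP2A7/CYP2A6 locus) from long reads and short-read
    depth. Long reads are assigned to a paralog of origin at each
    paralog-specific variant (PSV), switch positions of CYP2A7::CYP2A6
    hybrid alleles are located by penalized changepoint segmentation of the
    per-read PSV votes, and read-level allele candidates are integrated
    with integer copy-number segments from depth to produce a diplotype and
    a deletion/retained functional classification. Includes an in-silico
    PCR screen for junction-spanning amplicons, a synthetic-locus generator
    with truth labels for end-to-end validation, and a downstream
    mutation-analysis stage (tumor mutation burden, Welch's t-test,
    non-negative least-squares refitting of single-base-substitution
    signatures with a minor-signature merge rule).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
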