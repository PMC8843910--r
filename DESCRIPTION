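Package: clonecomp
Title: Clonal Composition Estimation from Allele-Specific Copy Number Segments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the clonal composition (CC) number of a tumor from
    segment-level B-allele frequency (BAF) and log2 intensity ratio (log2R)
    summaries of SNP-array data. A mixture model links the aberrant-cell
    fraction and the copy state of an aberrant clone to the expected folded
    BAF and log2R of a segment; segments consistent with loss-of-heterozygosity
    states carrying zero minor alleles are fitted, clustered by aberrant-cell
    percentage, and counted to give the CC number, classifying tumors as
    mono-CC (homogeneous) or poly-CC (heterogeneous). Includes a seeded
    synthetic-cohort generator with known clone structure and group-dependent
    recurrence times, and the downstream cohort statistics (two-sided Fisher
    exact test, Mann-Whitney U, Kaplan-Meier estimation with median survival,
    and the log-rank test) implemented from first principles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
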