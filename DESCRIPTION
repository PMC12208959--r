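Package: sncflow
Title: Blood Small Non-Coding RNA Fragment Classification and Cohort Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies short RNA-sequencing reads from blood biofluids into
    isomiRs, tRNA-derived fragments (tRFs), rRNA-derived fragments (rRFs),
    Y RNA-derived fragments (yRFs), and unannotated "not-itr" groups; labels
    every molecule with a reversible base-32 "license plate" identifier; and
    runs the downstream cohort statistics used in biomarker screening:
    negative-binomial differential abundance with median-of-ratios
    normalization, presence/absence enrichment via two-sided Fisher tests,
    Cox proportional-hazards and Kaplan-Meier survival screening,
    longitudinal sign-concordance analysis, and exact-match ribosomal-DNA
    taxonomic attribution. Includes a synthetic-data generator (reference
    bundle, count matrices, clinical metadata, FASTQ reads with UMIs) with
    planted ground truth so every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
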