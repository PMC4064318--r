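Package: hlatyper
Title: Two-Digit HLA Typing, Zygosity and Expression from RNA-Seq Reads
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Determines an individual's two-digit HLA class I (A, B, C) and
    class II (DQA1, DQB1, DRB1) type directly from bulk RNA-Seq reads, with a
    confidence p-value for every call, a zygosity decision per locus, and
    locus-level expression in RPKM units. Reads are aligned ungapped and
    end-to-end against exon-derived HLA allele sub-transcripts with a fixed
    mismatch budget; allele groups are called in two iterations by read-count
    outlier statistics. Also ships the companion allele-diversity analytics
    (per-position Shannon variability, intra-/inter-group Hamming distance
    summaries, unique k-mer fractions) and a seeded simulator of HLA-like
    allele databases and diploid read sets with known truth, so the whole
    pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
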