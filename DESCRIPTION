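Package: iesret
Title: Genome-Wide Quantification of Programmed DNA Elimination via IES Retention Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify programmed DNA elimination in ciliates from
    deep-sequencing data. Reads aligned to a somatic (MAC) reference and to a
    germline-like MAC+IES reference are classified at the boundaries of
    internal eliminated sequences (IESs) into IES-containing and
    junction-containing reads, yielding per-IES retention scores. Significantly
    retained IESs are called against a control sample with an exact binomial
    framework (Clopper-Pearson control bound, one-sided binomial test,
    Benjamini-Hochberg adjustment). Includes cohort analyses (size-group
    retention bias, knockdown set overlaps, sequence-feature association,
    replicate concordance), coverage-based germline sequence-complexity
    accounting, and a deterministic paired-end read simulator with
    maternal-MAC contamination for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
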