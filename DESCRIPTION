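Package: scattervc
Title: Scatter-Gather Parallel Variant Calling with Overlap-Padded Genome Partitioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scatter-gather pipeline for parallel small-variant calling.
    The reference genome is partitioned into overlap-padded pieces, sorted
    alignment files are split per piece with coordinates remapped to
    piece-relative space, variant-calling jobs run concurrently per piece,
    and the per-piece VCFs are lifted back to absolute coordinates,
    deduplicated by core-region ownership, and merged into one sorted VCF.
    Includes a deterministic built-in pileup SNV caller, templated
    invocation of external callers, callset-concordance metrics (missing
    rate, difference rate, score correlation), and a synthetic-data module
    that generates references, planted diploid SNVs, error-bearing reads
    and truth VCFs so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    parallel,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
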