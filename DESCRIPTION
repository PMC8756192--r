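Package: shardcall
Title: Scatter-Gather Somatic Variant Calling with Exact Parallel Equivalence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A single-machine, multi-process somatic variant calling pipeline
    built on scatter-gather genome partitioning. Balanced chromosomal regions
    are derived from randomly sampled tumor alignments; reads of the tumor and
    matched normal sample are shuffled to regions with boundary-spanning pairs
    duplicated into all overlapped regions; each region is coordinate-sorted
    and duplicate-marked deterministically; per-region base quality score
    recalibration (BQSR) covariate tables are built with single-counting of
    boundary reads and merged exactly into one genome-wide table; a
    position-local tumor/normal pileup caller emits somatic SNVs per region and
    shard VCFs are merged in genome order. The design makes the partitioned run
    provably identical to the unpartitioned run for any region count and worker
    count. Includes a deterministic synthetic-data generator (reference,
    germline and somatic truth variants, miscalibrated paired reads, PCR
    duplicates) so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    parallel,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
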