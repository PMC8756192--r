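---
title: "Scatter-gather somatic calling: model, design and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scatter-gather somatic calling: model, design and verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Somatic variant calling compares sequencing reads of a tumor sample with
reads of a matched normal sample from the same individual to find mutations
private to the tumor. At whole-genome scale the preprocessing steps —
coordinate sorting, PCR-duplicate marking, base quality score recalibration
(BQSR) — and the calling itself dominate wall-clock time, but all of them
are *local* in the genome except one: BQSR, whose covariate statistics must
be aggregated genome-wide before they are applied, because covariate counts
collected from a small region are too sparse to estimate error rates
reliably and region-local recalibration perturbs downstream calls.

`shardcall` implements this workload as a scatter-gather pipeline on a
single machine: the genome is split into `N` regions balanced by tumor read
count, each region is processed independently (and in parallel over a
process pool), and the only cross-region synchronization point is an exact,
associative merge of integer covariate tables. The engineering goal is a
provable property rather than a benchmark: *the partitioned run is
byte-identical to the unpartitioned run for every choice of `N` and worker
count.* This is the desk-scale, exact analogue of the near-identity that
production scatter-gather pipelines report between their parallel and
sequential outputs.

## Pipeline structure

Three jobs, with artifacts persisted between them:

1. **Partition.** Alignment start positions of a reservoir sample of tumor
   reads (60 per requested region by default) are sorted, and region
   boundaries are placed at every `ceiling(k/N)`-th sampled position —
   sample quantiles of the read-start distribution. Boundaries are snapped
   so that no region crosses a contig; a contig with no sampled read
   becomes one whole-contig region. The realized region count can therefore
   differ slightly from `N`. Quantile cuts are the simplest estimator that
   yields regions with roughly equal read counts under arbitrary coverage
   skew.
2. **Prepare.** Reads of both samples are shuffled to regions. A read is
   copied into *every* region overlapped by its own alignment interval or
   its mate's (boundary duplication); exactly one copy — in the region
   containing the read's own start — is marked *primary* (`XP:i:1`).
   Duplicating by interval overlap of both mates is deliberately stronger
   than duplicating only boundary-crossing pairs: it guarantees each
   region's pileup sees every read overlapping every one of its positions,
   which is what makes N-invariance exact rather than approximate. Each
   region is then coordinate-sorted (spilling sorted runs to disk above a
   record threshold and merging them with one-record buffers),
   duplicate-marked, and counted into a partial BQSR table using primary
   copies only, so no base is counted twice. Partial tables are tree-merged.
3. **Call.** Each region shard is recalibrated with the *merged* table and
   scored by the built-in tumor/normal pileup caller; per-region VCF shards
   are concatenated in genome order.

## Why the output is exactly partition-invariant

Each ingredient is order- and partition-free by construction:

* **Sorting** uses the total key (contig, position, strand, qname,
  first-in-pair); a region's sorted shard is the restriction of the
  globally sorted order.
* **Duplicate marking** decides groups by (library, unclipped 5′ end pair),
  the representative by quality sum then lexicographic qname — never by
  arrival order. Duplicate-group members share unclipped ends, so the whole
  group is co-duplicated into the same regions and every copy receives the
  same flag.
* **BQSR tables** hold integer counts; keywise addition is associative and
  commutative, so any merge tree gives the same genome-wide table, and the
  primary-copy rule makes per-region counts a partition of the single-pass
  counts.
* **The caller** is position-local: each site is scored only from its own
  pileup column, whose content (and float summation order, fixed by the
  sorted read order) is identical in any region that contains the site.

Haplotype-assembly callers are *not* position-local; they are reachable
through the per-region adapter contract (region interval + two region SAM
paths in, VCF shard out) but then the equivalence guarantee weakens to the
near-identity those tools exhibit, which is exactly why the built-in caller
exists as the testable reference.

## The recalibration model

Covariates are GATK's standard four: read group, reported quality (clamped
to [2, 60]), signed machine cycle (1-based, negated on reverse strand,
binned to decades above cycle 30 to bound table size), and
machine-orientation dinucleotide (previous base, current base; `NN` when
undefined). Counting walks aligned, non-clipped bases, skips `N`s, known
germline sites (SNV positions; ±5 bp around known indels), duplicate,
secondary/supplementary and mapq-0 reads.

The empirical quality is a Laplace-smoothed frequency,

\[ Q = -10\,\log_{10}\frac{e + 1}{n + 2}, \quad \text{capped at } 60, \]

not a hierarchical-shrinkage estimate: the pipeline's contribution is the
exact genome-wide *merge*, which is estimator-independent, and the closed
form keeps every acceptance check exact. Application replaces each base's
quality by the rounded empirical quality of its full key when the key holds
at least 100 observations, else falls back to the (read group, reported
quality) aggregate, then the read-group aggregate, then leaves the reported
quality unchanged — a direct embodiment of the requirement that
recalibration accuracy needs volume of observations.

## The built-in caller

For a tumor column with alt count \(a\), depth \(d\) and per-allele error
rates \(\epsilon\) from mean phred scores, with
\(P(\text{alt read}\mid f) = f(1-\epsilon) + (1-f)\epsilon/3\) and
\(P(\text{ref read}\mid f) = (1-f)(1-\epsilon) + f\epsilon/3\):

* `TLOD` is the log10 likelihood ratio of \(f = \hat f = a/d\) against
  \(f = 0\) over the tumor column;
* `NLOD` is the log10 ratio of the normal column under \(f = 0\) against a
  germline het (\(f = 0.5\)) — large when the normal is confidently
  reference.

A site is emitted iff `TLOD >= 6.3`, `NLOD >= 2.2`, tumor depth `>= 8` and
normal alt fraction `<= 0.03` (all configurable; pileups use mapq `>= 20`,
base quality `>= 13`, duplicates excluded). These defaults are package
choices in the spirit of widely used tumor/normal callers, not fitted
values. SNVs only; indels and assembly are out of scope by design.

## What the simulator emulates — and what it does not

The generator produces the study conditions used by every end-to-end test:
a three-contig ~60 kb genome (30/20/10 kb, uniform base composition),
germline hets at 1e-3 per bp (planted per *fragment* at probability 0.5 in
both samples), 30 somatic SNVs with allele fractions drawn from
{0.1, 0.2, 0.35, 0.5, 0.8} (tumor fragments only), 60× tumor / 30× normal
proper pairs of 100 bp reads with 300 ± 30 bp fragments, 5% PCR-duplicate
pair clones (same molecule, independent sequencing errors), and a
systematic miscalibration: every base reports Q40 while the true error
rate is 1e-3 up to machine cycle 70 and 1e-2 beyond, doubled in the `CG`
dinucleotide context. An optional coverage-skew factor doubles the sampling
weight of the first half of each contig, and pairs can be forced to
straddle contig midpoints. Reads are emitted pre-aligned with exact
coordinates and ungapped `100M` cigars — the aligned-input mode of the
pipeline — plus optional FASTQ export for the chunker.

Passing tests on this material therefore demonstrates the *architectural*
claims (equivalence, exact merge, conservation, balance, calibration
recovery, truth recovery at planted fractions) but says nothing about
alignment artifacts, indels, structural variation, realistic error
spectra, optical duplicates, or contamination — none of which the
simulator models.

## Numerical and design choices

* Internal coordinates are 0-based half-open everywhere; SAM/VCF text stays
  1-based, converted only at the I/O boundary.
* Reads travel as one `data.table` row per SAM record; optional tags are
  carried verbatim so shard round-trips are byte-stable.
* Quality-sum scoring for duplicate representatives counts bases with
  phred ≥ 15; ties break on qname so arrival order never matters.
* `round()` (banker's rounding) maps empirical qualities to integers; the
  choice is irrelevant to equivalence, it only has to be fixed.
* Pileup allele means are computed as sum/count with summation in sorted
  read order, fixing the floating-point result across partitionings.
* Mean phred per allele stands in for per-base qualities in the likelihood;
  with homogeneous qualities (the common case after recalibration of a
  constant-Q run) it is exactly the per-base model.
* Degenerate inputs: empty regions produce empty shards and empty tables
  (the merge identity); contigs without samples become whole-contig
  regions; a reference `N` or read `N` base contributes nothing to BQSR
  counts; a locus with reference `N` can still be called against the
  majority allele definition.
* Test problem sizes: unit tests run a 16 kb genome at 30×/15×; end-to-end
  properties run the full default conditions with
  `N ∈ {1, 4, 16} × workers ∈ {1, 4}`, twenty random splits for the merge
  oracle, twenty 500-read duplicate instances, and three seeded replicates
  for caller truth recovery, pooled. These sizes were chosen so the whole
  suite exercises every boundary case the architecture creates (multiple
  contigs, dozens of boundary-straddling pairs per cut) while staying
  desk-scale.

## Known limitations

* The FASTQ entry path requires an external aligner adapter and is not
  exercised by the test suite; aligned SAM input is the reference path.
* BAM/CRAM are not read natively; convert with `samtools view -h`.
* Optical-duplicate detection (tile/x/y) is not implemented; all
  duplicates are treated as PCR-type.
* The caller has no panel-of-normals, contamination model, or indel
  support; `FilterMutectCalls`-style post-filtering is out of scope.
* Restartability is manifest-based (checksums of persisted artifacts);
  there is no lineage recomputation — a failed stage is simply rerun.
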