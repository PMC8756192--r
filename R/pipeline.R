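# Three-job orchestration over a pluggable executor (serial or forked
# process pool): job 1 samples tumor alignments and fixes the region
# specification; job 2 shuffles both samples to regions, sorts, marks
# duplicates and merges per-region recalibration tables into one genome-wide
# table; job 3 applies the merged table and calls somatic variants per
# region, merging shard VCFs in genome order. Inter-stage artifacts are
# persisted with checksum manifests so completed stages rerun as no-ops.

#' Pipeline configuration
#'
#' @param tumor,normal aligned SAM paths (plain or gzip).
#' @param genome_fa reference FASTA path.
#' @param known_vcf known-variants VCF path (germline sites masked in BQSR).
#' @param out_dir working/output directory.
#' @param n_regions requested region count (default 1,800; the realized
#'   count may differ slightly where contigs force boundaries).
#' @param sample_per_region sampled tumor reads per requested region; the
#'   partitioner draws `sample_per_region * n_regions` reads.
#' @param chunk_mb FASTQ chunk size in MB (FASTQ-adapter mode only).
#' @param seed RNG seed for the position sampler.
#' @param workers process count for per-region stages (forked on unix).
#' @param caller `"builtin"` or `"adapter:<command template>"` with
#'   placeholders `{tumor}`, `{normal}`, `{contig}`, `{start}`, `{end}`,
#'   `{out}`.
#' @param params caller parameters, see [caller_params()].
#' @param spill_threshold max records sorted in memory per region.
#' @param min_obs minimum covariate observations used in recalibration.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(tumor, normal, genome_fa, known_vcf, out_dir,
                            n_regions = 1800L, sample_per_region = 60L,
                            chunk_mb = 60L, seed = 1L, workers = 1L,
                            caller = "builtin", params = caller_params(),
                            spill_threshold = 1e6L, min_obs = 100L) {
  if (n_regions < 1L) stop("n_regions must be >= 1")
  if (workers < 1L) stop("workers must be >= 1")
  for (p in c(tumor, normal, genome_fa, known_vcf))
    if (!file.exists(p)) stop("input file does not exist: ", p)
  cfg <- as.list(environment())
  cfg$params <- params
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a flat YAML file
#'
#' Keys match the arguments of [pipeline_config()]; caller thresholds may be
#' given under a `params:` mapping.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pars <- do.call(caller_params, y$params %||% list())
  y$params <- NULL
  do.call(pipeline_config, c(y, list(params = pars)))
}

manifest_path <- function(cfg, stage) file.path(cfg$out_dir, paste0(stage, ".manifest"))

stage_complete <- function(cfg, stage) {
  mf <- manifest_path(cfg, stage)
  if (!file.exists(mf)) return(FALSE)
  m <- utils::read.delim(mf, stringsAsFactors = FALSE)
  all(file.exists(m$path)) && all(tools::md5sum(m$path) == m$md5)
}

write_manifest <- function(cfg, stage, paths) {
  m <- data.frame(path = paths, md5 = unname(tools::md5sum(paths)))
  utils::write.table(m, manifest_path(cfg, stage), sep = "\t",
                     row.names = FALSE, quote = FALSE)
}

# run f over items with the configured executor; results in item order
region_apply <- function(cfg, items, f) {
  if (cfg$workers > 1L && .Platform$OS.type == "unix") {
    res <- parallel::mclapply(items, f, mc.cores = cfg$workers,
                              mc.preschedule = TRUE)
    err <- vapply(res, inherits, logical(1), "try-error")
    if (any(err)) stop("worker failure in regions: ",
                       paste(items[err], collapse = ", "))
    res
  } else lapply(items, f)
}

shard_path <- function(cfg, kind, region)
  file.path(cfg$out_dir, kind, sprintf("region_%04d.sam", region))

#' Job 1: determine chromosomal regions from sampled tumor alignments
#'
#' Loads the tumor alignment, reservoir-samples
#' `sample_per_region * n_regions` alignment starts, computes the quantile
#' region boundaries and persists them as `regions.bed`. Rerunning a
#' completed job is a no-op.
#'
#' @param cfg a [pipeline_config()].
#' @return the `region_spec`.
#' @export
run_job1 <- function(cfg) {
  genome <- read_fasta_genome(cfg$genome_fa)
  bed <- file.path(cfg$out_dir, "regions.bed")
  if (stage_complete(cfg, "job1_partition"))
    return(read_region_bed(bed, genome))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  tumor <- read_sam(cfg$tumor, genome)
  k <- cfg$sample_per_region * cfg$n_regions
  samples <- sample_positions(tumor, k, genome, cfg$seed)
  spec <- compute_regions(samples, genome, cfg$n_regions)
  write_region_bed(spec, bed)
  write_manifest(cfg, "job1_partition", bed)
  spec
}

#' Job 2: shuffle, sort, mark duplicates, build and merge BQSR tables
#'
#' Reads of both samples are grouped into region shards (boundary pairs
#' duplicated), then per region — in parallel over `workers` — sorted,
#' duplicate-marked and counted into a partial recalibration table
#' (primary-region reads only). Partial tables are tree-merged into the
#' genome-wide table persisted as `recal_merged.tsv`.
#'
#' @param cfg a [pipeline_config()].
#' @param spec the `region_spec` from [run_job1()].
#' @return the merged [recal_table()].
#' @export
run_job2 <- function(cfg, spec) {
  genome <- read_fasta_genome(cfg$genome_fa)
  report <- file.path(cfg$out_dir, "recal_merged.tsv")
  if (stage_complete(cfg, "job2_prepare"))
    return(read_recal_report(report))
  tumor <- read_sam(cfg$tumor, genome)
  normal <- read_sam(cfg$normal, genome)
  if (!nrow(normal)) stop("normal sample has no reads")
  if (!nrow(tumor)) stop("tumor sample has no reads")
  shards <- shuffle_tables(tumor, normal, spec, genome)
  known <- read_vcf(cfg$known_vcf, genome)
  mask <- known_sites_mask(known, genome)
  meta <- list(genome_id = basename(cfg$genome_fa), known_id = basename(cfg$known_vcf))
  dir.create(file.path(cfg$out_dir, "sorted"), recursive = TRUE, showWarnings = FALSE)
  regions <- seq_len(n_regions_of(spec)) - 1L
  tables <- region_apply(cfg, regions, function(r) {
    reads <- sort_region(shards[[r + 1L]], genome, cfg$spill_threshold,
                         scratch = file.path(cfg$out_dir, "scratch", paste0("region_", r)))
    reads <- mark_duplicates(reads, genome)
    write_sam(reads, genome, shard_path(cfg, "sorted", r), sort_order = "coordinate")
    build_recal_table(reads, genome, mask, metadata = meta)
  })
  merged <- tree_merge_tables(tables)
  write_recal_report(merged, report)
  write_manifest(cfg, "job2_prepare",
                 c(report, vapply(regions, function(r) shard_path(cfg, "sorted", r),
                                  character(1))))
  merged
}

#' Tree-reduce a list of recalibration tables
#'
#' Pairwise balanced reduction; since the merge is associative and
#' commutative over integer counts, any tree shape yields the identical
#' genome-wide table.
#'
#' @param tables list of [recal_table()]s.
#' @return merged table.
#' @export
tree_merge_tables <- function(tables) {
  if (!length(tables)) return(recal_table())
  while (length(tables) > 1L) {
    nxt <- list()
    for (i in seq(1L, length(tables), by = 2L)) {
      nxt[[length(nxt) + 1L]] <-
        if (i + 1L <= length(tables))
          merge_recal_tables(tables[[i]], tables[[i + 1L]])
        else tables[[i]]
    }
    tables <- nxt
  }
  tables[[1]]
}

#' Job 3: apply BQSR and call somatic variants per region
#'
#' Each region shard is recalibrated with the merged genome-wide table,
#' split by sample, piled up and scored by the built-in caller (or handed
#' to an adapter command), then shard VCFs are merged in genome order into
#' `somatic.vcf`.
#'
#' @param cfg a [pipeline_config()].
#' @param spec the `region_spec`.
#' @param table merged [recal_table()] from [run_job2()] (error if missing).
#' @return path of the final VCF, invisibly; the merged variant table is
#'   attached as attribute `variants`.
#' @export
run_job3 <- function(cfg, spec, table) {
  if (is.null(table)) stop("merged recalibration table is required")
  genome <- read_fasta_genome(cfg$genome_fa)
  out_vcf <- file.path(cfg$out_dir, "somatic.vcf")
  regions <- seq_len(n_regions_of(spec)) - 1L
  shards <- region_apply(cfg, regions, function(r) {
    reads <- read_sam(shard_path(cfg, "sorted", r), genome)
    reads <- apply_bqsr(reads, table, min_obs = cfg$min_obs)
    reg <- as.list(spec$regions[r + 1L])
    if (cfg$caller == "builtin") {
      smp <- sam_tag_get(reads$tags, "XS")
      call_region(reads[smp == "tumor"], reads[smp == "normal"],
                  genome, reg, cfg$params)
    } else {
      run_caller_adapter(cfg, reads, genome, reg, r)
    }
  })
  merged <- merge_shard_vcfs(shards, spec)
  write_vcf(merged, genome, out_vcf, info_defs = VCF_INFO_DEFS)
  write_manifest(cfg, "job3_call", out_vcf)
  structure(invisible(out_vcf), variants = merged)
}

# external caller contract: region interval + two region SAM paths in,
# VCF shard out; the command template is filled and run with system().
run_caller_adapter <- function(cfg, reads, genome, reg, r) {
  tmpl <- sub("^adapter:", "", cfg$caller)
  smp <- sam_tag_get(reads$tags, "XS")
  tpath <- file.path(cfg$out_dir, sprintf("adapter_t_%04d.sam", r))
  npath <- file.path(cfg$out_dir, sprintf("adapter_n_%04d.sam", r))
  opath <- file.path(cfg$out_dir, sprintf("adapter_out_%04d.vcf", r))
  write_sam(reads[smp == "tumor"], genome, tpath, sort_order = "coordinate")
  write_sam(reads[smp == "normal"], genome, npath, sort_order = "coordinate")
  cmd <- tmpl
  for (kv in list(c("{tumor}", tpath), c("{normal}", npath),
                  c("{contig}", reg$contig), c("{start}", reg$start),
                  c("{end}", reg$end), c("{out}", opath)))
    cmd <- gsub(kv[1], kv[2], cmd, fixed = TRUE)
  status <- system(cmd)
  if (status != 0L) stop("caller adapter failed for region ", r)
  read_vcf(opath, genome)
}

#' Run the full pipeline
#'
#' [run_job1()], [run_job2()], [run_job3()] in sequence.
#'
#' @param cfg a [pipeline_config()].
#' @return list with `spec`, `table`, `vcf` (path) and `variants`.
#' @export
run_pipeline <- function(cfg) {
  spec <- run_job1(cfg)
  table <- run_job2(cfg, spec)
  vcf <- run_job3(cfg, spec, table)
  list(spec = spec, table = table, vcf = as.character(vcf),
       variants = attr(vcf, "variants"))
}

#' Concordance between two variant sets
#'
#' Records match on (contig, pos, ref, alt). Counts are also accumulated
#' cumulatively over tumor allele fraction bins (width `vaf_bin`, VAF read
#' from the a-side `TAF`/`AF` info key when present).
#'
#' @param a,b variant tables (see [read_vcf()]) on the same genome.
#' @param vaf_bin bin width over \[0, 1\].
#' @return list with `corresponding`, `only_a`, `only_b` counts and a
#'   data.table `by_vaf` with cumulative counts per VAF bin.
#' @export
vcf_concordance <- function(a, b, vaf_bin = 0.05) {
  key <- function(v) paste(v$contig, v$pos, v$ref, v$alt, sep = "|")
  ka <- key(a); kb <- key(b)
  corr <- sum(ka %in% kb)
  vaf <- function(info) {
    m <- regexpr("(TAF|AF)=[0-9.eE+-]+", info)
    out <- rep(NA_real_, length(info))
    hit <- m > 0
    out[hit] <- as.numeric(sub("^(TAF|AF)=", "", regmatches(info, m)))
    out
  }
  av <- vaf(a$info)
  bins <- seq(0, 1, by = vaf_bin)
  bin_of <- pmin(findInterval(av, bins, rightmost.closed = TRUE), length(bins) - 1L)
  by_vaf <- data.table::data.table(
    vaf_max = bins[-1],
    corresponding = vapply(seq_along(bins[-1]), function(i)
      sum(ka %in% kb & !is.na(bin_of) & bin_of <= i), integer(1)),
    only_a = vapply(seq_along(bins[-1]), function(i)
      sum(!(ka %in% kb) & !is.na(bin_of) & bin_of <= i), integer(1)))
  list(corresponding = corr, only_a = length(ka) - corr,
       only_b = sum(!(kb %in% ka)), by_vaf = by_vaf)
}
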