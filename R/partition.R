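# Scatter phase: derive N load-balanced regions from sampled tumor alignment
# starts, then assign reads of both samples to every region their own or
# their mate's alignment interval overlaps (boundary duplication), with the
# region containing the read's own start marked primary.

new_region_spec <- function(regions, genome) {
  regions <- data.table::as.data.table(regions)
  ord <- match(regions$contig, genome$names)
  if (anyNA(ord)) stop("region spec names contig absent from genome")
  o <- order(ord, regions$start)
  regions <- regions[o]
  ord <- ord[o]
  if (!"region" %in% names(regions)) regions[, "region" := seq_len(.N) - 1L]
  if (!identical(regions$region, seq_len(nrow(regions)) - 1L))
    stop("region ordinals must be 0..R-1 in (contig, start) order")
  if (any(regions$start >= regions$end)) stop("empty or inverted region interval")
  if (any(regions$end > genome$lengths[ord])) stop("region exceeds contig bounds")
  # disjoint + covering: per contig, intervals must tile [0, length)
  for (ctg in genome$names) {
    r <- regions[regions$contig == ctg]
    if (!nrow(r)) stop("contig ", ctg, " not covered by any region")
    if (r$start[1] != 0L || r$end[nrow(r)] != genome$lengths[[ctg]] ||
        (nrow(r) > 1L && any(r$start[-1] != r$end[-nrow(r)])))
      stop("regions do not tile contig ", ctg)
  }
  offsets <- cumsum(c(0, genome$lengths[-length(genome$lengths)]))
  names(offsets) <- genome$names
  spec <- list(regions = regions,
               gstart = offsets[regions$contig] + regions$start,
               offsets = offsets,
               genome_names = genome$names,
               genome_lengths = genome$lengths)
  class(spec) <- "region_spec"
  spec
}

#' @export
print.region_spec <- function(x, ...) {
  cat("region_spec:", nrow(x$regions), "regions over",
      length(unique(x$regions$contig)), "contigs\n")
  invisible(x)
}

n_regions_of <- function(spec) nrow(spec$regions)

#' Reservoir-sample alignment start positions
#'
#' Draws a uniform random sample of `k` alignment-start positions from the
#' mapped reads of a sample (Algorithm R), as the input for region boundary
#' estimation. Deterministic given `seed`.
#'
#' @param reads read table (see [read_sam()]); unmapped records are ignored.
#' @param k requested sample size; the default partitioning uses 60 per
#'   requested region. If fewer mapped reads exist, all are returned.
#' @param genome a [reference_genome()].
#' @param seed integer RNG seed.
#' @return a `sample_positions` object: data.table (ord, pos) plus the seed.
#' @export
sample_positions <- function(reads, k, genome, seed) {
  if (k < 1L) stop("k must be >= 1")
  mapped <- reads[read_is_mapped(reads)]
  n <- nrow(mapped)
  if (!n) stop("no mapped reads to sample from")
  idx <- with_seed(seed, {
    if (n <= k) seq_len(n) else {
      res <- seq_len(k)
      j <- as.integer(floor(stats::runif(n - k) * ((k + 1L):n))) + 1L
      for (i in seq_len(n - k)) if (j[i] <= k) res[j[i]] <- k + i
      res
    }
  })
  pos <- data.table::data.table(
    ord = contig_ordinal(genome, mapped$rname[idx]),
    pos = mapped$pos[idx])
  data.table::setorderv(pos, c("ord", "pos"))
  structure(list(positions = pos, seed = seed, requested = k),
            class = "sample_positions")
}

#' Compute balanced genomic regions from sampled positions
#'
#' Region boundaries are placed at sample quantiles: with `k` sorted sampled
#' start positions and `n_regions` requested regions, a boundary opens a new
#' region at every `ceiling(k / n_regions)`-th sampled position. Boundaries
#' are then snapped so that no region crosses a contig; contigs without any
#' sampled read become one whole-contig region, so the realized region count
#' can differ slightly from `n_regions`.
#'
#' @param samples a [sample_positions()] object.
#' @param genome a [reference_genome()].
#' @param n_regions requested number of regions (default 1,800 at the
#'   pipeline level).
#' @return a `region_spec`: ordered, disjoint intervals covering the genome.
#' @export
compute_regions <- function(samples, genome, n_regions) {
  if (n_regions < 1L) stop("n_regions must be >= 1")
  if (n_regions > sum(genome$lengths)) stop("n_regions exceeds genome length")
  pos <- samples$positions
  k <- nrow(pos)
  step <- ceiling(k / n_regions)
  cuts <- data.table::data.table(ord = integer(), cut = integer())
  if (n_regions > 1L && k > 1L) {
    ranks <- seq(step + 1L, k, by = step)
    cuts <- unique(data.table::data.table(ord = pos$ord[ranks], cut = pos$pos[ranks]))
  }
  rows <- list()
  for (i in seq_along(genome$names)) {
    len <- genome$lengths[[i]]
    b <- sort(unique(cuts$cut[cuts$ord == i - 1L]))
    b <- b[b > 0L & b < len]
    starts <- c(0L, b)
    ends <- c(b, len)
    rows[[i]] <- data.table::data.table(contig = genome$names[i],
                                        start = starts, end = ends)
  }
  new_region_spec(data.table::rbindlist(rows), genome)
}

# 1-based region index range overlapped by a half-open global interval
region_range <- function(spec, gfrom, gto_excl) {
  from <- findInterval(gfrom, spec$gstart)
  to <- findInterval(gto_excl - 1L, spec$gstart)
  list(from = from, to = to)
}

#' Assign one read (and its mate's interval) to regions
#'
#' A read belongs to every region overlapped by its own alignment interval
#' plus every region overlapped by its mate's interval, so that pairs stay
#' intact per region and every region sees every read overlapping any of its
#' positions. Exactly one region — the one containing the read's own
#' alignment start — is primary; single-counting rules (BQSR) use it.
#'
#' @param read single-row read table (mapped).
#' @param mate_interval `NULL`, or `list(contig =, start =, end =)` for the
#'   mate's alignment interval (0-based half-open).
#' @param spec a `region_spec`.
#' @param genome a [reference_genome()].
#' @return list with `regions` (0-based region ordinals, sorted) and
#'   `primary` (single ordinal).
#' @export
assign_to_regions <- function(read, mate_interval = NULL, spec, genome) {
  if (nrow(read) != 1L) stop("assign_to_regions expects a single read")
  if (!read_is_mapped(read)) stop("read is unmapped")
  ord <- contig_ordinal(genome, read$rname)
  if (read$pos < 0L || read$pos >= genome$lengths[[ord + 1L]])
    stop("read start outside genome")
  g1 <- spec$offsets[[read$rname]] + read$pos
  rr <- region_range(spec, g1, g1 + ref_widths(read$cigar))
  regs <- rr$from:rr$to
  if (!is.null(mate_interval)) {
    gm <- spec$offsets[[mate_interval$contig]] + mate_interval$start
    mr <- region_range(spec, gm, gm + (mate_interval$end - mate_interval$start))
    regs <- union(regs, mr$from:mr$to)
  }
  list(regions = sort(regs) - 1L, primary = rr$from - 1L)
}

# Vectorized assignment for a combined read table. Returns data.table
# (row, region, primary) with one entry per (read, region) membership.
assign_table <- function(reads, spec, genome) {
  n <- nrow(reads)
  g1 <- spec$offsets[reads$rname] + reads$pos
  w <- ref_widths(reads$cigar)
  own <- region_range(spec, g1, g1 + w)
  primary <- own$from
  # mate interval via self-join on (sample qname): mate is the other record
  key <- reads$qname
  idx <- seq_len(n)
  ord2 <- order(key, idx)
  mate_of <- rep(NA_integer_, n)
  k2 <- key[ord2]
  same_next <- c(k2[-length(k2)] == k2[-1], FALSE)
  a <- ord2[which(same_next)]
  b <- ord2[which(same_next) + 1L]
  mate_of[a] <- b
  mate_of[b] <- a
  from <- own$from; to <- own$to
  has_mate <- !is.na(mate_of)
  mfrom <- rep(NA_integer_, n); mto <- rep(NA_integer_, n)
  mfrom[has_mate] <- own$from[mate_of[has_mate]]
  mto[has_mate] <- own$to[mate_of[has_mate]]
  expand_ranges <- function(row, from, to) {
    span <- to - from
    simple <- span == 0L
    out <- data.table::data.table(row = row[simple], region = from[simple])
    if (any(!simple)) {
      r2 <- row[!simple]; f2 <- from[!simple]; t2 <- to[!simple]
      out <- rbind(out, data.table::data.table(
        row = rep(r2, t2 - f2 + 1L),
        region = unlist(Map(seq.int, f2, t2))))
    }
    out
  }
  memb <- rbind(expand_ranges(idx, from, to),
                expand_ranges(idx[has_mate], mfrom[has_mate], mto[has_mate]))
  memb <- unique(memb)
  memb[, "primary" := as.integer(memb$region == primary[memb$row])]
  data.table::setorderv(memb, c("region", "row"))
  memb[, "region" := memb$region - 1L]
  memb[]
}

#' Shuffle tumor and normal reads into per-region SAM shards
#'
#' Mapped reads of both samples are grouped by region per the boundary
#' duplication rule (see [assign_to_regions()]); unmapped reads are dropped
#' with a logged count. Each shard record carries an `XS:Z:` sample-of-origin
#' tag and an `XP:i:` primary marker (1 in exactly one region per read).
#'
#' @param tumor,normal read tables aligned to `genome`.
#' @param spec a `region_spec`.
#' @param genome a [reference_genome()].
#' @param out_dir output directory for `region_%04d.sam` shard files.
#' @return manifest data.table (region, path, n_reads, n_primary).
#' @export
shuffle_by_region <- function(tumor, normal, spec, genome, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  shards <- shuffle_tables(tumor, normal, spec, genome)
  manifest <- data.table::data.table(
    region = seq_along(shards) - 1L,
    path = file.path(out_dir, sprintf("region_%04d.sam", seq_along(shards) - 1L)),
    n_reads = vapply(shards, nrow, integer(1)),
    n_primary = vapply(shards, function(s)
      sum(sam_tag_get(s$tags, "XP") == "1"), integer(1)))
  for (r in manifest$region)
    write_sam(shards[[r + 1L]], genome, manifest$path[r + 1L])
  manifest[]
}

# in-memory shuffle: list of per-region read tables with XS (sample) and
# XP (primary-copy) tags set; the workhorse behind shuffle_by_region and
# the pipeline's prepare job
shuffle_tables <- function(tumor, normal, spec, genome) {
  all <- rbind(cbind(tumor, sample = "tumor"), cbind(normal, sample = "normal"))
  n_unmapped <- sum(!read_is_mapped(all))
  if (n_unmapped) message("dropping ", n_unmapped, " unmapped reads before partitioning")
  all <- all[read_is_mapped(all)]
  # qnames are disambiguated by sample for the mate join
  all2 <- data.table::copy(all)
  all2[, "qname" := paste0(all$sample, "/", all$qname)]
  memb <- assign_table(all2, spec, genome)
  lapply(seq_len(n_regions_of(spec)) - 1L, function(r) {
    rows <- memb[memb$region == r]
    shard <- all[rows$row]
    shard[, "tags" := sam_tag_set(sam_tag_set(shard$tags, "XS", "Z", shard$sample),
                                  "XP", "i", rows$primary)]
    shard[, "sample" := NULL]
    shard
  })
}
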