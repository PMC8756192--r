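# Base quality score recalibration with exactly mergeable covariate tables.
# Per-region tables count only reads whose primary region is the region at
# hand (boundary copies carry XP:i:0 and are skipped), so the keywise sum
# over any partition of the genome equals the single-pass whole-genome table
# with integer exactness.

#' Build a recalibration covariate table from one region's reads
#'
#' Counts aligned, non-clipped bases of usable reads against the reference:
#' `observations += 1` per base, `errors += 1` on mismatch. Skipped entirely:
#' duplicate-flagged, secondary/supplementary, mapq-0, and non-primary
#' (boundary-copy, `XP:i:0`) reads; skipped per base: `N` read or reference
#' bases and known-site positions. Covariates are (read group, reported
#' quality clamped to \[2, 60\], signed machine-cycle bin, machine-orientation
#' dinucleotide).
#'
#' @param reads sorted, duplicate-flagged read table of one region.
#' @param genome a [reference_genome()].
#' @param known_mask per-contig logical mask from [known_sites_mask()], or
#'   `NULL` for no masking.
#' @param metadata table metadata (genome/known identifiers).
#' @return a [recal_table()].
#' @export
build_recal_table <- function(reads, genome, known_mask = NULL,
                              metadata = list(genome_id = "", known_id = "")) {
  use <- read_is_mapped(reads) & !read_is_dup(reads) &
    !read_is_secondary(reads) & reads$mapq > 0L
  xp <- sam_tag_get(reads$tags, "XP")
  use <- use & xp != "0"
  r <- reads[use]
  if (!nrow(r)) return(recal_table(metadata = metadata))
  bases <- expand_aligned_bases(r, genome)
  keep <- bases$qcode != 4L & bases$rcode != 4L
  if (!is.null(known_mask)) {
    masked <- logical(nrow(bases))
    for (k in unique(bases$ord)) {
      sel <- bases$ord == k
      masked[sel] <- known_mask[[k + 1L]][bases$refpos[sel] + 1L]
    }
    keep <- keep & !masked
  }
  bases <- bases[keep]
  rg <- read_group_of(r)
  rgs <- sort(unique(rg))
  rgi <- match(rg, rgs)[bases$row] - 1L
  qc <- pmin(pmax(bases$qual, 2L), 60L)
  cyc <- bin_cycle(bases$cycle)
  # composite integer key: fast exact counting via tabulate
  key <- (((rgi * 64L + qc) * 256L) + cyc + 128L) * 25L + bases$dinuc + 1L
  nbins <- ((length(rgs) * 64L + 61L) * 256L + 256L) * 25L
  obs <- tabulate(key, nbins)
  errs <- tabulate(key[bases$qcode != bases$rcode], nbins)
  nz <- which(obs > 0L)
  k0 <- nz - 1L
  din <- k0 %% 25L
  rest <- k0 %/% 25L
  cycv <- rest %% 256L - 128L
  rest <- rest %/% 256L
  counts <- data.table::data.table(
    read_group = rgs[rest %/% 64L + 1L],
    reported_q = rest %% 64L,
    cycle = cycv,
    dinuc_context = dinuc_label(din),
    observations = obs[nz],
    errors = errs[nz])
  recal_table(counts, metadata = metadata)
}

#' Merge two recalibration tables
#'
#' Keywise integer sum of observations and errors. Associative and
#' commutative with the empty table as identity, so partial tables from any
#' partition of the genome can be reduced in any tree shape/order and yield
#' the identical genome-wide table.
#'
#' @param a,b [recal_table()]s with identical metadata.
#' @return merged [recal_table()].
#' @export
merge_recal_tables <- function(a, b) {
  if (!identical(attr(a, "metadata"), attr(b, "metadata")))
    stop("cannot merge recalibration tables with different metadata")
  both <- rbind(data.table::as.data.table(a), data.table::as.data.table(b))
  merged <- both[, list(observations = sum(observations), errors = sum(errors)),
                 by = c("read_group", "reported_q", "cycle", "dinuc_context")]
  recal_table(merged, metadata = attr(a, "metadata"))
}

#' Empirical phred quality from mismatch counts
#'
#' Laplace-smoothed frequency estimate on the phred scale:
#' `Q = -10 log10((errors + 1) / (observations + 2))`, capped at 60.
#'
#' @param observations,errors non-negative integer vectors with
#'   `errors <= observations`.
#' @return numeric phred qualities.
#' @export
empirical_quality <- function(observations, errors) {
  if (any(observations < 0) || any(errors < 0)) stop("negative counts")
  if (any(errors > observations)) stop("errors exceed observations")
  pmin(-10 * log10((errors + 1) / (observations + 2)), 60)
}

#' Apply a merged recalibration table to read qualities
#'
#' Every base's quality is replaced by the rounded empirical quality of its
#' covariate key, provided the key has at least `min_obs` observations;
#' otherwise the (read group, reported quality) aggregate is tried, then the
#' read-group aggregate, and finally the reported quality is left unchanged.
#' Sequences are untouched; the operation is deterministic.
#'
#' @param reads read table (any region shard; qualities of all records are
#'   recalibrated, duplicates included).
#' @param table the merged genome-wide [recal_table()].
#' @param min_obs minimum observations for a key (or aggregate) to be used.
#' @return a copy of `reads` with recalibrated quality strings.
#' @export
apply_bqsr <- function(reads, table, min_obs = 100L) {
  if (!nrow(reads)) return(reads)
  tab <- data.table::as.data.table(table)
  full <- tab[tab$observations >= min_obs]
  full[, "newq" := as.integer(round(empirical_quality(full$observations, full$errors)))]
  agg2 <- tab[, list(observations = sum(observations), errors = sum(errors)),
              by = c("read_group", "reported_q")]
  agg2 <- agg2[agg2$observations >= min_obs]
  agg2[, "newq" := as.integer(round(empirical_quality(agg2$observations, agg2$errors)))]
  agg1 <- tab[, list(observations = sum(observations), errors = sum(errors)),
              by = "read_group"]
  agg1 <- agg1[agg1$observations >= min_obs]
  agg1[, "newq" := as.integer(round(empirical_quality(agg1$observations, agg1$errors)))]

  len <- nchar(reads$seq)
  n <- nrow(reads)
  row <- rep(seq_len(n), len)
  qidx <- sequence(len)
  codes <- seq_codes(reads$seq)
  seq_off <- cumsum(c(0L, len[-n]))
  cov <- base_covariates(reads, row, qidx, codes, seq_off)
  rgs <- sort(unique(c(tab$read_group, read_group_of(reads))))
  rgi_read <- match(read_group_of(reads), rgs)
  # composite integer keys for fast hashed lookup
  key_of <- function(rgi, q, cyc, din) (((rgi * 64L + q) * 256L) + cyc + 128L) * 25L + din
  key2_of <- function(rgi, q) rgi * 64L + q
  q0 <- phred_ints_concat(reads$qual)
  qc <- pmin(pmax(q0, 2L), 60L)
  bkey <- key_of(rgi_read[row], qc, bin_cycle(cov$cycle), cov$dinuc)
  m1 <- full$newq[match(bkey, key_of(match(full$read_group, rgs), full$reported_q,
                                     full$cycle, dinuc_code(full$dinuc_context)))]
  m2 <- agg2$newq[match(key2_of(rgi_read[row], qc),
                        key2_of(match(agg2$read_group, rgs), agg2$reported_q))]
  m3 <- agg1$newq[match(rgi_read[row], match(agg1$read_group, rgs))]
  newq <- m1
  newq[is.na(newq)] <- m2[is.na(newq)]
  newq[is.na(newq)] <- m3[is.na(newq)]
  newq[is.na(newq)] <- q0[is.na(newq)]
  big <- rawToChar(as.raw(pmin(pmax(newq, 0L), 93L) + 33L))
  out <- data.table::copy(reads)
  out[, "qual" := substring(big, seq_off + 1L, seq_off + len)]
  out[]
}
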