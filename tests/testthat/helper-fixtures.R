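# Shared fixtures: hand-built read tables, a scaled-down simulation for
# unit tests, and an independent brute-force duplicate-marking oracle.

# single-read constructor with sensible defaults
mk_read <- function(qname = "r1", flag = 0L, rname = "chr1", pos = 0L,
                    mapq = 60L, cigar = "100M", rnext = "*", pnext = NA_integer_,
                    tlen = 0L, seq = NULL, qual = NULL, tags = "RG:Z:tumor\tLB:Z:libA") {
  len <- if (grepl("^[0-9]+M$", cigar)) as.integer(sub("M$", "", cigar)) else 100L
  if (is.null(seq)) seq <- strrep("A", len)
  if (is.null(qual)) qual <- strrep("I", nchar(seq))
  data.table::data.table(qname = qname, flag = flag, rname = rname, pos = pos,
                         mapq = mapq, cigar = cigar, rnext = rnext,
                         pnext = pnext, tlen = tlen, seq = seq, qual = qual,
                         tags = tags)
}

# deterministic toy genome (uniform bases)
toy_genome <- function(lengths = c(chr1 = 3000L, chr2 = 2000L), seed = 42L) {
  seqs <- shardcall:::with_seed(seed, vapply(lengths, function(n)
    paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    character(1)))
  names(seqs) <- names(lengths)
  reference_genome(seqs)
}

# scaled-down simulation shared by unit tests (memoized per session)
.small_sim_cache <- new.env(parent = emptyenv())
small_sim <- function(seed = 5L) {
  key <- paste0("s", seed)
  if (!is.null(.small_sim_cache[[key]])) return(.small_sim_cache[[key]])
  p <- sim_params(contig_lengths = c(chr1 = 8000L, chr2 = 5000L, chr3 = 3000L),
                  tumor_depth = 30, normal_depth = 15, n_somatic = 10L,
                  seed = seed)
  g <- simulate_reference(p)
  sim <- simulate_reads(p, g)
  out <- c(sim, list(genome = g, params = p))
  .small_sim_cache[[key]] <- out
  out
}

# Brute-force duplicate-marking oracle: O(n^2) pairwise grouping computed
# from first principles (its own clip arithmetic and scoring), independent
# of the implementation under test.
oracle_mark_duplicates <- function(reads, genome) {
  n <- nrow(reads)
  flags <- reads$flag
  mapped <- bitwAnd(flags, 4L) == 0L
  second <- bitwAnd(flags, 256L + 2048L) != 0L
  elig <- which(mapped & !second)
  parse1 <- function(cig) {
    lens <- as.integer(regmatches(cig, gregexpr("[0-9]+", cig))[[1]])
    ops <- regmatches(cig, gregexpr("[A-Z=]", cig))[[1]]
    list(lens = lens, ops = ops)
  }
  end5 <- function(i) {
    cg <- parse1(reads$cigar[i])
    rev <- bitwAnd(flags[i], 16L) != 0L
    if (!rev) {
      clip <- 0L
      for (j in seq_along(cg$ops)) {
        if (cg$ops[j] %in% c("S", "H")) clip <- clip + cg$lens[j] else break
      }
      p <- reads$pos[i] - clip
    } else {
      span <- sum(cg$lens[cg$ops %in% c("M", "D", "N", "=", "X")])
      clip <- 0L
      for (j in rev(seq_along(cg$ops))) {
        if (cg$ops[j] %in% c("S", "H")) clip <- clip + cg$lens[j] else break
      }
      p <- reads$pos[i] + span - 1L + clip
    }
    lb <- sub(".*LB:Z:([^\t]*).*", "\\1", reads$tags[i])
    c(lb, reads$rname[i], p, as.integer(rev))
  }
  score1 <- function(i) {
    q <- as.integer(charToRaw(reads$qual[i])) - 33L
    sum(q[q >= 15L])
  }
  ends <- lapply(seq_len(n), function(i) if (i %in% elig) end5(i) else NULL)
  mate <- rep(NA_integer_, n)
  for (i in elig) for (j in elig) {
    if (i != j && reads$qname[i] == reads$qname[j] &&
        bitwAnd(flags[i], 1L) != 0L && bitwAnd(flags[j], 1L) != 0L) mate[i] <- j
  }
  paired <- !is.na(mate)
  pair_key <- function(i) {
    k1 <- paste(ends[[i]], collapse = "|")
    k2 <- paste(ends[[mate[i]]], collapse = "|")
    paste(sort(c(k1, k2)), collapse = "||")
  }
  dup <- logical(n)
  firsts <- elig[paired[elig] & elig < mate[elig]]
  if (length(firsts)) {
    keys <- vapply(firsts, pair_key, character(1))
    for (k in unique(keys)) {
      grp <- firsts[keys == k]
      sc <- vapply(grp, function(i) score1(i) + score1(mate[i]), numeric(1))
      qn <- reads$qname[grp]
      best <- grp[order(-sc, qn)][1]
      for (i in setdiff(grp, best)) { dup[i] <- TRUE; dup[mate[i]] <- TRUE }
    }
  }
  pair_end_set <- unique(unlist(lapply(firsts, function(i)
    c(paste(ends[[i]], collapse = "|"), paste(ends[[mate[i]]], collapse = "|")))))
  singles <- elig[!paired[elig]]
  if (length(singles)) {
    keys <- vapply(singles, function(i) paste(ends[[i]], collapse = "|"), character(1))
    clash <- keys %in% pair_end_set
    dup[singles[clash]] <- TRUE
    rest <- singles[!clash]
    for (k in unique(keys[!clash])) {
      grp <- rest[keys[!clash] == k]
      sc <- vapply(grp, score1, numeric(1))
      best <- grp[order(-sc, reads$qname[grp])][1]
      dup[setdiff(grp, best)] <- TRUE
    }
  }
  dup
}

# hand-constructed soft-clipped duplicate fixture: three pairs sharing
# unclipped ends (two via clipping), one distinct pair, one orphan read
softclip_fixture <- function() {
  g <- toy_genome()
  r <- rbind(
    mk_read("p1", 99L, "chr1", 100L, cigar = "100M", rnext = "=", pnext = 300L,
            qual = strrep("I", 100)),
    mk_read("p1", 147L, "chr1", 300L, cigar = "100M", rnext = "=", pnext = 100L,
            qual = strrep("I", 100)),
    mk_read("p2", 99L, "chr1", 105L, cigar = "5S95M", rnext = "=", pnext = 300L,
            qual = strrep("5", 100)),                      # unclipped start 100
    mk_read("p2", 147L, "chr1", 300L, cigar = "95M5S", rnext = "=", pnext = 105L,
            qual = strrep("5", 100)),                      # unclipped end 399
    mk_read("p3", 99L, "chr1", 102L, cigar = "2S98M", rnext = "=", pnext = 300L,
            qual = strrep("7", 100)),                      # unclipped start 100
    mk_read("p3", 147L, "chr1", 300L, cigar = "98M2S", rnext = "=", pnext = 102L,
            qual = strrep("7", 100)),                      # unclipped end 399
    mk_read("q1", 99L, "chr1", 500L, cigar = "100M", rnext = "=", pnext = 700L),
    mk_read("q1", 147L, "chr1", 700L, cigar = "100M", rnext = "=", pnext = 500L),
    mk_read("s1", 16L, "chr1", 300L, cigar = "95M5S"))     # unclipped end 399
  list(genome = g, reads = sort_region(r, g))
}

write_test_fastq <- function(n_pairs, dir, seed = 1L) {
  shardcall:::with_seed(seed, {
    qn <- sprintf("read_%05d", seq_len(n_pairs))
    mkrec <- function(q, mate) {
      sq <- vapply(seq_along(q), function(i)
        paste0(sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = ""),
        character(1))
      paste0("@", q, "/", mate, "\n", sq, "\n+\n", strrep("I", 50))
    }
    r1 <- file.path(dir, "r1.fastq.gz"); r2 <- file.path(dir, "r2.fastq.gz")
    g1 <- gzfile(r1, "wt"); writeLines(mkrec(qn, 1L), g1); close(g1)
    g2 <- gzfile(r2, "wt"); writeLines(mkrec(qn, 2L), g2); close(g2)
    list(r1 = r1, r2 = r2)
  })
}

read_gz_lines <- function(p) { con <- gzfile(p, "rt"); on.exit(close(con)); readLines(con) }
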