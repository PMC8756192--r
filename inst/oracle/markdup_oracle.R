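# Brute-force duplicate-marking oracle: O(n^2) pairwise grouping computed
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
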