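# Per-region preparation: coordinate sorting with bounded memory (spill to
# disk + k-way merge) and order-independent duplicate marking. Marking
# decisions depend only on (library, unclipped ends, base-quality score,
# qname) so that copies of a read duplicated into adjacent regions receive
# identical flags — a prerequisite for exact equivalence with the
# unpartitioned run.

#' Unclipped 5' alignment start of reads
#'
#' The alignment start adjusted outward by clip lengths, as used for
#' duplicate grouping: forward-strand reads extend left by leading soft/hard
#' clips; reverse-strand reads use the last aligned base extended right by
#' trailing clips.
#'
#' @param reads mapped read table with valid cigars.
#' @return integer vector of 0-based unclipped 5' positions.
#' @export
unclipped_start <- function(reads) {
  if (any(reads$cigar == "*")) stop("cigar absent for a mapped read")
  isrev <- read_is_reverse(reads)
  out <- integer(nrow(reads))
  simple <- grepl("^[0-9]+M$", reads$cigar)
  slen <- as.integer(sub("M$", "", reads$cigar[simple]))
  out[simple] <- reads$pos[simple] + ifelse(isrev[simple], slen - 1L, 0L)
  if (all(simple)) return(out)
  lead_clip <- function(cig) {
    i <- 1L
    s <- 0L
    while (i <= length(cig$op) && cig$op[i] %in% c("S", "H")) {
      s <- s + cig$len[i]; i <- i + 1L
    }
    s
  }
  trail_clip <- function(cig) lead_clip(list(op = rev(cig$op), len = rev(cig$len)))
  cx <- which(!simple)
  cigs <- parse_cigar(reads$cigar[cx])
  crev <- isrev[cx]
  fwd <- which(!crev)
  if (length(fwd))
    out[cx[fwd]] <- reads$pos[cx[fwd]] - vapply(cigs[fwd], lead_clip, integer(1))
  rv <- which(crev)
  if (length(rv))
    out[cx[rv]] <- reads$pos[cx[rv]] + ref_widths(reads$cigar[cx[rv]]) - 1L +
      vapply(cigs[rv], trail_clip, integer(1))
  out
}

sort_key_order <- function(reads, genome) {
  ord <- ifelse(read_is_mapped(reads), match(reads$rname, genome$names), .Machine$integer.max)
  order(ord, reads$pos, read_is_reverse(reads), reads$qname,
        bitwAnd(reads$flag, FLAG_FIRST) == 0L, method = "radix")
}

#' Coordinate-sort the reads of one region
#'
#' Total, stable order: (contig ordinal, position, strand, qname,
#' first-in-pair). When the input exceeds `spill_threshold` records it is
#' sorted as runs of at most that many records, each spilled to `scratch` as
#' a SAM file, and the runs are merged with one-record read buffers.
#'
#' @param reads read table of one region.
#' @param genome a [reference_genome()].
#' @param spill_threshold maximum records held in memory while sorting.
#' @param scratch directory for spill files (created if needed).
#' @return the sorted read table (same multiset of records).
#' @export
sort_region <- function(reads, genome, spill_threshold = 1e6L, scratch = tempfile("sort_")) {
  n <- nrow(reads)
  if (n <= spill_threshold) return(reads[sort_key_order(reads, genome)])
  dir.create(scratch, recursive = TRUE, showWarnings = FALSE)
  n_runs <- ceiling(n / spill_threshold)
  paths <- character(n_runs)
  for (i in seq_len(n_runs)) {
    run <- reads[((i - 1L) * spill_threshold + 1L):min(i * spill_threshold, n)]
    paths[i] <- file.path(scratch, sprintf("spill_%d.sam", i))
    write_sam(run[sort_key_order(run, genome)], genome, paths[i],
              sort_order = "coordinate")
  }
  merged <- merge_sorted_runs(paths, genome)
  unlink(scratch, recursive = TRUE)
  merged
}

# streaming k-way merge of sorted SAM run files (one buffered record each)
merge_sorted_runs <- function(paths, genome) {
  cons <- lapply(paths, file, open = "rt")
  on.exit(lapply(cons, close))
  next_rec <- function(con) {
    repeat {
      l <- readLines(con, n = 1L)
      if (!length(l)) return(NULL)
      if (!startsWith(l, "@")) return(l)
    }
  }
  line_key <- function(l, genome) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    list(ord = match(f[3], genome$names) %||% NA_integer_,
         pos = as.integer(f[4]),
         rev = bitwAnd(flag, FLAG_REVERSE) != 0L,
         qname = f[1],
         second = bitwAnd(flag, FLAG_FIRST) == 0L)
  }
  key_less <- function(a, b) {
    if (a$ord != b$ord) return(a$ord < b$ord)
    if (a$pos != b$pos) return(a$pos < b$pos)
    if (a$rev != b$rev) return(!a$rev)
    if (a$qname != b$qname) return(a$qname < b$qname)
    a$second < b$second
  }
  buf <- lapply(cons, next_rec)
  keys <- lapply(buf, function(l) if (is.null(l)) NULL else line_key(l, genome))
  out <- character(0)
  chunks <- list()
  repeat {
    live <- which(!vapply(buf, is.null, logical(1)))
    if (!length(live)) break
    best <- live[1]
    for (i in live[-1]) if (key_less(keys[[i]], keys[[best]])) best <- i
    out[length(out) + 1L] <- buf[[best]]
    if (length(out) >= 10000L) { chunks[[length(chunks) + 1L]] <- out; out <- character(0) }
    nxt <- next_rec(cons[[best]])
    buf[best] <- list(nxt)
    keys[best] <- list(if (is.null(nxt)) NULL else line_key(nxt, genome))
  }
  chunks[[length(chunks) + 1L]] <- out
  lines <- unlist(chunks)
  tmp <- tempfile(fileext = ".sam")
  writeLines(c(sam_header(genome, "coordinate"), lines), tmp)
  on.exit(unlink(tmp), add = TRUE)
  read_sam(tmp, genome)
}

#' Mark PCR duplicates in a coordinate-sorted region
#'
#' Reads (pairs) sharing a library and identical unclipped 5' end
#' coordinates form a duplicate group. The representative — left unmarked —
#' is the read/pair with the highest sum of base qualities of at least 15,
#' ties broken by lexicographically smallest qname; all other members get
#' the duplicate flag. Paired groups take precedence: an unpaired read whose
#' end matches a paired group's end is marked. Secondary and supplementary
#' alignments are excluded from grouping. Decisions never depend on input
#' order.
#'
#' @param reads coordinate-sorted read table (error if unsorted).
#' @param genome a [reference_genome()].
#' @return the read table with duplicate flag bits set/cleared.
#' @export
mark_duplicates <- function(reads, genome) {
  if (!nrow(reads)) return(reads)
  ordc <- match(reads$rname, genome$names)
  mp <- read_is_mapped(reads)
  if (sum(mp) > 1L) {
    om <- ordc[mp]; pm <- reads$pos[mp]; nm <- length(om)
    ok <- om[-1] > om[-nm] | (om[-1] == om[-nm] & pm[-1] >= pm[-nm])
    if (!all(ok)) stop("mark_duplicates requires coordinate-sorted input")
  }
  out <- data.table::copy(reads)
  out[, "flag" := bitwAnd(out$flag, bitwNot(FLAG_DUP))]
  elig <- which(mp & !read_is_secondary(out))
  if (!length(elig)) return(out[])
  e <- out[elig]
  lib <- library_of(e)
  ustart <- unclipped_start(e)
  strand <- as.integer(read_is_reverse(e))
  endkey <- paste(lib, ordc[elig], ustart, strand, sep = "|")
  q <- lapply(phred_ints(e$qual), function(p) sum(p[p >= 15L]))
  score <- as.numeric(unlist(q))
  # pair up mates present in this table
  idx <- seq_len(nrow(e))
  o2 <- order(e$qname, idx)
  k2 <- e$qname[o2]
  same <- c(k2[-length(k2)] == k2[-1], FALSE)
  mate_of <- rep(NA_integer_, nrow(e))
  a <- o2[which(same)]; b <- o2[which(same) + 1L]
  paired_flag <- bitwAnd(e$flag, FLAG_PAIRED) != 0L
  okpair <- paired_flag[a] & paired_flag[b]
  a <- a[okpair]; b <- b[okpair]
  mate_of[a] <- b; mate_of[b] <- a
  is_paired <- !is.na(mate_of)

  dup <- logical(nrow(e))
  paired_ends <- character(0)
  if (any(is_paired)) {
    first_of_pair <- which(is_paired & idx < mate_of)
    pk <- vapply(first_of_pair, function(i) {
      ka <- endkey[i]; kb <- endkey[mate_of[i]]
      if (ka <= kb) paste(ka, kb, sep = "||") else paste(kb, ka, sep = "||")
    }, character(1))
    pscore <- score[first_of_pair] + score[mate_of[first_of_pair]]
    pqname <- e$qname[first_of_pair]
    pg <- data.table::data.table(grpkey = pk, score = pscore, qname = pqname,
                                 i1 = first_of_pair, i2 = mate_of[first_of_pair])
    data.table::setorderv(pg, c("grpkey", "score", "qname"), order = c(1L, -1L, 1L))
    keep <- !duplicated(pg$grpkey)
    dup[pg$i1[!keep]] <- TRUE
    dup[pg$i2[!keep]] <- TRUE
    paired_ends <- unique(c(endkey[pg$i1], endkey[pg$i2]))
  }
  singles <- which(!is_paired)
  if (length(singles)) {
    sk <- endkey[singles]
    clash <- sk %in% paired_ends
    dup[singles[clash]] <- TRUE
    rest <- singles[!clash]
    if (length(rest)) {
      sg <- data.table::data.table(grpkey = endkey[rest], score = score[rest],
                                   qname = e$qname[rest], i = rest)
      data.table::setorderv(sg, c("grpkey", "score", "qname"), order = c(1L, -1L, 1L))
      keep <- !duplicated(sg$grpkey)
      dup[sg$i[!keep]] <- TRUE
    }
  }
  flag_new <- e$flag
  flag_new[dup] <- bitwOr(flag_new[dup], FLAG_DUP)
  out[elig, "flag" := flag_new]
  out[]
}
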