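# Per-base expansion of aligned reads: the vectorized core shared by BQSR
# counting, quality application and pileup. Each aligned (M/=/X) base
# becomes one row carrying its reference position, read/reference base
# (integer codes A=0 C=1 G=2 T=3 N=4), quality, signed machine cycle, and
# machine-orientation dinucleotide code (prev*5 + cur, 24 = "NN"). Row
# order is (read, query index), i.e. sorted-read order, which fixes
# floating-point summation order downstream.

CODE_OF <- local({
  v <- rep(4L, 256)
  v[utf8ToInt("ACGT") + 1L] <- 0:3
  v
})
COMP_CODE <- c(3L, 2L, 1L, 0L, 4L)
CODE_CHAR <- c("A", "C", "G", "T", "N")
DINUC_NN <- 24L
DINUC_LABEL <- paste0(rep(CODE_CHAR, each = 5), rep(CODE_CHAR, 5))

dinuc_label <- function(code) DINUC_LABEL[code + 1L]

dinuc_code <- function(label) {
  out <- match(label, DINUC_LABEL) - 1L
  if (anyNA(out)) stop("unknown dinucleotide context: ", label[is.na(out)][1])
  out
}

seq_codes <- function(seqs) CODE_OF[as.integer(charToRaw(paste0(seqs, collapse = ""))) + 1L]

# aligned-base coordinates: list(row, qidx, refpos) in read order
aligned_base_coords <- function(reads) {
  n <- nrow(reads)
  simple <- grepl("^[0-9]+M$", reads$cigar)
  if (all(simple)) {
    len <- nchar(reads$seq)
    return(list(row = rep(seq_len(n), len),
                qidx = sequence(len),
                refpos = sequence(len, from = reads$pos + 1L) - 1L))
  }
  rows <- vector("list", n)
  cigs <- parse_cigar(reads$cigar)
  for (i in seq_len(n)) {
    cig <- cigs[[i]]
    q <- 0L; r <- reads$pos[i]
    qidx <- integer(0); refpos <- integer(0)
    for (j in seq_along(cig$op)) {
      op <- cig$op[j]; L <- cig$len[j]
      if (op %in% c("M", "=", "X")) {
        qidx <- c(qidx, (q + 1L):(q + L))
        refpos <- c(refpos, r:(r + L - 1L))
        q <- q + L; r <- r + L
      } else if (op %in% c("I", "S")) q <- q + L
      else if (op %in% c("D", "N")) r <- r + L
    }
    rows[[i]] <- list(qidx = qidx, refpos = refpos)
  }
  list(row = rep(seq_len(n), vapply(rows, function(x) length(x$qidx), integer(1))),
       qidx = unlist(lapply(rows, `[[`, "qidx")),
       refpos = unlist(lapply(rows, `[[`, "refpos")))
}

bin_cycle <- function(cycle) {
  a <- abs(cycle)
  big <- a > 30L
  a[big] <- 10L * ((a[big] + 9L) %/% 10L)
  a[cycle < 0L] <- -a[cycle < 0L]
  a
}

# machine-cycle and dinucleotide covariates for arbitrary (row, qidx) bases;
# codes = integer base codes of the concatenated read sequences
base_covariates <- function(reads, row, qidx, codes, seq_off) {
  len <- nchar(reads$seq)
  rev <- read_is_reverse(reads)
  rrow <- rev[row]
  lrow <- len[row]
  mc <- qidx
  mc[rrow] <- lrow[rrow] - qidx[rrow] + 1L
  cur <- codes[seq_off[row] + qidx]
  cur_m <- cur
  cur_m[rrow] <- COMP_CODE[cur[rrow] + 1L]
  has_prev <- qidx > 1L
  has_prev[rrow] <- qidx[rrow] < lrow[rrow]
  pix <- qidx - 1L
  pix[rrow] <- qidx[rrow] + 1L
  prev_m <- rep(4L, length(qidx))
  w <- which(has_prev)
  pv <- codes[seq_off[row[w]] + pix[w]]
  rw <- rrow[w]
  pv[rw] <- COMP_CODE[pv[rw] + 1L]
  prev_m[w] <- pv
  dinuc <- prev_m * 5L + cur_m
  dinuc[prev_m == 4L | cur_m == 4L] <- DINUC_NN
  cycle <- mc
  cycle[rrow] <- -mc[rrow]
  list(cycle = cycle, dinuc = dinuc, cur = cur)
}

# full expansion of aligned bases against the reference; integer base codes.
# Cycle/dinucleotide covariates are skipped when not needed (pileup).
expand_aligned_bases <- function(reads, genome, covariates = TRUE) {
  if (!nrow(reads)) {
    return(data.table::data.table(
      row = integer(), ord = integer(), refpos = integer(), qcode = integer(),
      rcode = integer(), qual = integer(), cycle = integer(), dinuc = integer()))
  }
  co <- aligned_base_coords(reads)
  codes <- seq_codes(reads$seq)
  seq_off <- cumsum(c(0L, nchar(reads$seq)[-nrow(reads)]))
  qual_all <- phred_ints_concat(reads$qual)
  ordc <- match(reads$rname, genome$names)
  ord_row <- ordc[co$row]
  qix <- seq_off[co$row] + co$qidx
  l <- list(
    row = co$row,
    ord = ord_row - 1L,
    refpos = co$refpos,
    qcode = codes[qix],
    rcode = genome$gcodes[genome$goffset[ord_row] + co$refpos + 1L],
    qual = qual_all[qix])
  if (covariates) {
    cov <- base_covariates(reads, co$row, co$qidx, codes, seq_off)
    l$cycle <- cov$cycle
    l$dinuc <- cov$dinuc
  }
  data.table::setDT(l)
  l
}
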