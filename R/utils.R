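# Internal helpers: SAM flag bits, phred strings, cigar arithmetic, seeded RNG.

FLAG_PAIRED      <- 1L
FLAG_PROPER      <- 2L
FLAG_UNMAPPED    <- 4L
FLAG_MUNMAPPED   <- 8L
FLAG_REVERSE     <- 16L
FLAG_MREVERSE    <- 32L
FLAG_FIRST       <- 64L
FLAG_SECOND      <- 128L
FLAG_SECONDARY   <- 256L
FLAG_QCFAIL      <- 512L
FLAG_DUP         <- 1024L
FLAG_SUPPL       <- 2048L

flag_set <- function(flag, bit) bitwAnd(flag, bit) != 0L

#' Convert a phred quality string to integer scores
#'
#' @param qual character vector of SAM/FASTQ quality strings (phred+33).
#' @return for length-1 input an integer vector of per-base scores; for longer
#'   input a list of integer vectors.
#' @keywords internal
phred_ints <- function(qual) {
  if (length(qual) == 1L) return(as.integer(charToRaw(qual)) - 33L)
  lapply(qual, function(q) as.integer(charToRaw(q)) - 33L)
}

# concatenated per-base scores for a vector of quality strings (fast path)
phred_ints_concat <- function(qual) {
  as.integer(charToRaw(paste0(qual, collapse = ""))) - 33L
}

phred_string <- function(q) {
  rawToChar(as.raw(pmin(pmax(q, 0L), 93L) + 33L))
}

# parse cigar strings -> list of list(len = int vec, op = chr vec)
parse_cigar <- function(cigar) {
  lens <- regmatches(cigar, gregexpr("[0-9]+", cigar))
  ops  <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))
  Map(function(l, o) list(len = as.integer(l), op = o), lens, ops)
}

CIGAR_QUERY <- c("M", "I", "S", "=", "X")
CIGAR_REF   <- c("M", "D", "N", "=", "X")

cigar_query_length <- function(cig) {
  sum(cig$len[cig$op %in% CIGAR_QUERY])
}

cigar_ref_length <- function(cig) {
  sum(cig$len[cig$op %in% CIGAR_REF])
}

# reference span of each read: vectorized, with fast path for ungapped "<n>M"
ref_widths <- function(cigar) {
  w <- integer(length(cigar))
  simple <- grepl("^[0-9]+M$", cigar)
  w[simple] <- as.integer(sub("M$", "", cigar[simple]))
  if (any(!simple)) {
    w[!simple] <- vapply(parse_cigar(cigar[!simple]), cigar_ref_length, integer(1))
  }
  w
}

# run code with a temporary RNG seed, restoring global state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# retrieve one tag value from the packed optional-tag strings ("" if absent)
sam_tag_get <- function(tags, tag) {
  pat <- paste0("(?:^|\t)", tag, ":[AifZH]:([^\t]*)")
  m <- regexpr(pat, tags, perl = TRUE)
  out <- rep("", length(tags))
  hit <- m > 0
  if (any(hit)) out[hit] <- sub(pat, "\\1", regmatches(tags, m), perl = TRUE)
  out
}

sam_tag_set <- function(tags, tag, type, value) {
  entry <- paste0(tag, ":", type, ":", value)
  ifelse(tags == "", entry, paste(tags, entry, sep = "\t"))
}
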