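# SAM text I/O. Reads are carried through the pipeline as a data.table with
# one row per record; positions are converted to 0-based at this boundary and
# back to 1-based on write. Optional tags (field 12+) are kept verbatim in a
# single packed column so round-trips are byte-stable.

SAM_COLS <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
              "rnext", "pnext", "tlen", "seq", "qual", "tags")

#' Read aligned reads from a SAM file
#'
#' Plain or gzipped SAM text. The header's `@SQ` lines must name a subset of
#' the genome's contigs in genome order. SAM `POS`/`PNEXT` (1-based) are
#' converted to 0-based internal coordinates; `PNEXT = 0` becomes `NA`.
#'
#' @param path SAM file (`.sam` or `.sam.gz`) or an open connection.
#' @param genome a [reference_genome()]; contig names of mapped records are
#'   checked against it.
#' @return a `data.table` with columns qname, flag, rname, pos (0-based),
#'   mapq, cigar, rnext, pnext (0-based or NA), tlen, seq, qual, tags
#'   (packed optional fields, `""` if none), in file order.
#' @export
read_sam <- function(path, genome) {
  con <- if (inherits(path, "connection")) path else {
    if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  }
  if (!inherits(path, "connection")) on.exit(close(con))
  lines <- readLines(con)
  is_hdr <- startsWith(lines, "@")
  header <- lines[is_hdr]
  body <- lines[!is_hdr]
  body_lineno <- which(!is_hdr)

  sq <- header[startsWith(header, "@SQ")]
  sq_names <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  if (length(sq_names)) {
    ord <- match(sq_names, genome$names)
    if (anyNA(ord)) stop("SAM header names contig absent from genome: ",
                         sq_names[is.na(ord)][1])
    if (is.unsorted(ord, strictly = TRUE))
      stop("SAM header contig order disagrees with genome contig order")
  }

  if (!length(body)) return(empty_reads())
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 11L)) {
    i <- which(nf < 11L)[1]
    stop("malformed SAM record at line ", body_lineno[i], ": fewer than 11 fields")
  }
  # column extraction grouped by field count (vectorized per group)
  cols <- vector("list", 11L)
  for (k in seq_len(11L)) cols[[k]] <- character(length(parts))
  tags <- character(length(parts))
  for (k in sort(unique(nf))) {
    rows <- which(nf == k)
    m <- matrix(unlist(parts[rows], use.names = FALSE), nrow = k)
    for (j in seq_len(11L)) cols[[j]][rows] <- m[j, ]
    if (k > 11L)
      tags[rows] <- do.call(paste, c(lapply(12:k, function(j) m[j, ]), sep = "\t"))
  }
  reads <- data.table::data.table(
    qname = cols[[1]],
    flag  = as.integer(cols[[2]]),
    rname = cols[[3]],
    pos   = as.integer(cols[[4]]) - 1L,
    mapq  = as.integer(cols[[5]]),
    cigar = cols[[6]],
    rnext = cols[[7]],
    pnext = as.integer(cols[[8]]) - 1L,
    tlen  = as.integer(cols[[9]]),
    seq   = cols[[10]],
    qual  = cols[[11]],
    tags  = tags
  )
  reads[pnext < 0L, "pnext" := NA_integer_]

  mapped <- !bitwAnd(reads$flag, FLAG_UNMAPPED)
  bad_len <- reads$seq != "*" & nchar(reads$seq) != nchar(reads$qual)
  if (any(bad_len))
    stop("malformed SAM record at line ", body_lineno[which(bad_len)[1]],
         ": SEQ length differs from QUAL length")
  if (any(mapped)) {
    ord <- match(reads$rname[mapped], genome$names)
    if (anyNA(ord))
      stop("SAM record at line ", body_lineno[mapped][is.na(ord)][1],
           " maps to unknown contig ", reads$rname[mapped][is.na(ord)][1])
    cg <- reads$cigar[mapped]
    qlen <- integer(length(cg))
    simple <- grepl("^[0-9]+M$", cg)
    qlen[simple] <- as.integer(sub("M$", "", cg[simple]))
    if (any(!simple))
      qlen[!simple] <- vapply(parse_cigar(cg[!simple]), cigar_query_length, integer(1))
    mismatch <- qlen != nchar(reads$seq[mapped]) & cg != "*"
    if (any(mismatch))
      stop("malformed SAM record at line ", body_lineno[mapped][which(mismatch)[1]],
           ": cigar query length differs from SEQ length")
    over <- reads$pos[mapped] < 0L |
      reads$pos[mapped] + ref_widths(reads$cigar[mapped]) > genome$lengths[ord]
    if (any(over))
      stop("SAM record at line ", body_lineno[mapped][which(over)[1]],
           " extends beyond contig bounds")
  }
  reads[]
}

empty_reads <- function() {
  data.table::data.table(
    qname = character(), flag = integer(), rname = character(),
    pos = integer(), mapq = integer(), cigar = character(),
    rnext = character(), pnext = integer(), tlen = integer(),
    seq = character(), qual = character(), tags = character())
}

sam_header <- function(genome, sort_order = "unknown", read_groups = NULL) {
  h <- c(paste0("@HD\tVN:1.6\tSO:", sort_order),
         paste0("@SQ\tSN:", genome$names, "\tLN:", genome$lengths))
  if (length(read_groups))
    h <- c(h, paste0("@RG\tID:", read_groups$id, "\tSM:", read_groups$sm,
                     "\tLB:", read_groups$lb, "\tPL:ILLUMINA"))
  h
}

#' Write aligned reads to a SAM file
#'
#' Inverse of [read_sam()]: `read_sam(write_sam(x))` reproduces `x`
#' field-for-field. Positions are converted back to 1-based SAM text.
#'
#' @param reads read table as produced by [read_sam()] or the simulator.
#' @param genome a [reference_genome()] used for the `@SQ` header lines.
#' @param path output path (`.gz` suffix gzips).
#' @param sort_order value for the `@HD SO:` field.
#' @param read_groups optional data.frame with columns id, sm, lb for `@RG`
#'   header lines.
#' @return number of records written, invisibly.
#' @export
write_sam <- function(reads, genome, path, sort_order = "unknown",
                      read_groups = NULL) {
  mapped <- !bitwAnd(reads$flag, FLAG_UNMAPPED)
  if (any(mapped) && anyNA(match(reads$rname[mapped], genome$names)))
    stop("reads reference contigs absent from genome")
  body <- sam_format_body(reads)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(c(sam_header(genome, sort_order, read_groups), body), con)
  invisible(length(body))
}

sam_format_body <- function(reads) {
  if (!nrow(reads)) return(character())
  pnext1 <- ifelse(is.na(reads$pnext), 0L, reads$pnext + 1L)
  line <- paste(reads$qname, reads$flag, reads$rname, reads$pos + 1L,
                reads$mapq, reads$cigar, reads$rnext, pnext1, reads$tlen,
                reads$seq, reads$qual, sep = "\t")
  ifelse(reads$tags == "", line, paste(line, reads$tags, sep = "\t"))
}

# flag predicates used across modules
read_is_mapped    <- function(reads) bitwAnd(reads$flag, FLAG_UNMAPPED) == 0L
read_is_reverse   <- function(reads) bitwAnd(reads$flag, FLAG_REVERSE) != 0L
read_is_dup       <- function(reads) bitwAnd(reads$flag, FLAG_DUP) != 0L
read_is_secondary <- function(reads)
  bitwAnd(reads$flag, FLAG_SECONDARY + FLAG_SUPPL) != 0L
read_group_of     <- function(reads) sam_tag_get(reads$tags, "RG")
library_of       <- function(reads) {
  lb <- sam_tag_get(reads$tags, "LB")
  ifelse(lb == "", read_group_of(reads), lb)
}
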