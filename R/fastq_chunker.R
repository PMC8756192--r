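# Pair-preserving splitting of paired gzipped FASTQ into chunks for
# downstream parallel alignment. Chunk size is measured on uncompressed
# text, which is what governs downstream task granularity.

#' Split paired FASTQ files into pair-preserving chunks
#'
#' Both inputs are streamed in lockstep; a chunk is closed once its
#' uncompressed size reaches `chunk_bytes`, never between the two mates of
#' a pair, so concatenating the chunks in chunk order reproduces the input
#' pair sequence exactly.
#'
#' @param fastq_1,fastq_2 paths of the mate-1/mate-2 FASTQ files (gzipped
#'   or plain); must hold equal record counts in matching order.
#' @param chunk_bytes target uncompressed chunk size; default 60 MB.
#' @param out_dir output directory; chunks are written gzipped as
#'   `chunk_<id>_1.fastq.gz` / `chunk_<id>_2.fastq.gz`.
#' @return manifest data.table (chunk_id, file_1, file_2, pair_count,
#'   byte_size); also written as `chunks.tsv` in `out_dir`.
#' @export
split_fastq_pairs <- function(fastq_1, fastq_2, chunk_bytes = 60 * 2^20,
                              out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  open_in <- function(p) if (grepl("\\.gz$", p)) gzfile(p, "rt") else file(p, "rt")
  c1 <- open_in(fastq_1); c2 <- open_in(fastq_2)
  on.exit({ close(c1); close(c2) })
  manifest <- list()
  chunk_id <- 0L
  buf1 <- list(); buf2 <- list()
  pairs <- 0L; bytes <- 0
  flush <- function() {
    f1 <- file.path(out_dir, sprintf("chunk_%04d_1.fastq.gz", chunk_id))
    f2 <- file.path(out_dir, sprintf("chunk_%04d_2.fastq.gz", chunk_id))
    g1 <- gzfile(f1, "wt"); writeLines(unlist(buf1), g1); close(g1)
    g2 <- gzfile(f2, "wt"); writeLines(unlist(buf2), g2); close(g2)
    manifest[[length(manifest) + 1L]] <<- data.table::data.table(
      chunk_id = chunk_id, file_1 = f1, file_2 = f2,
      pair_count = pairs, byte_size = bytes)
    chunk_id <<- chunk_id + 1L
    buf1 <<- list(); buf2 <<- list(); pairs <<- 0L; bytes <<- 0
  }
  block_recs <- 1000L
  repeat {
    l1 <- readLines(c1, n = 4L * block_recs)
    l2 <- readLines(c2, n = 4L * block_recs)
    if (!length(l1) && !length(l2)) break
    n1 <- length(l1) %/% 4L; n2 <- length(l2) %/% 4L
    if (length(l1) %% 4L || length(l2) %% 4L)
      stop("malformed FASTQ: truncated 4-line record")
    if (n1 != n2) stop("unequal record counts in FASTQ pair")
    hdr <- seq(1L, length(l1), by = 4L)
    if (any(!startsWith(l1[hdr], "@")) || any(!startsWith(l2[hdr], "@")) ||
        any(!startsWith(l1[hdr + 2L], "+")) || any(!startsWith(l2[hdr + 2L], "+")))
      stop("malformed FASTQ record")
    rec_bytes <- (nchar(l1[hdr]) + nchar(l1[hdr + 1L]) + nchar(l1[hdr + 2L]) +
                    nchar(l1[hdr + 3L]) + nchar(l2[hdr]) + nchar(l2[hdr + 1L]) +
                    nchar(l2[hdr + 2L]) + nchar(l2[hdr + 3L]) + 8L)
    done <- 0L
    while (done < n1) {
      room <- cumsum(rec_bytes[(done + 1L):n1]) + bytes
      take <- which(room >= chunk_bytes)
      take <- if (length(take)) take[1] else n1 - done
      sel <- (done * 4L + 1L):((done + take) * 4L)
      buf1[[length(buf1) + 1L]] <- l1[sel]
      buf2[[length(buf2) + 1L]] <- l2[sel]
      pairs <- pairs + take
      bytes <- bytes + sum(rec_bytes[(done + 1L):(done + take)])
      done <- done + take
      if (bytes >= chunk_bytes) flush()
    }
  }
  if (pairs > 0L) flush()
  if (!length(manifest)) stop("empty FASTQ input")
  m <- data.table::rbindlist(manifest)
  data.table::fwrite(m, file.path(out_dir, "chunks.tsv"), sep = "\t")
  m[]
}

#' Decompress a gzipped FASTQ and count records
#'
#' @param path gzipped (or plain) FASTQ file.
#' @return list with `records` (lines / 4) and `bytes` (uncompressed,
#'   including newlines).
#' @export
decompress_and_count <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4L != 0L)
    stop("FASTQ line count is not a multiple of 4")
  list(records = length(lines) %/% 4L,
       bytes = sum(nchar(lines, type = "bytes")) + length(lines))
}
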