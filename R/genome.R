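#' Reference genome container
#'
#' Builds the in-memory reference genome used throughout the pipeline: an
#' ordered set of contigs whose order defines contig ordinals (0-based), as in
#' the `@SQ` lines of a SAM header. Sequences are cached as raw byte vectors
#' for fast per-base comparison during recalibration and pileup.
#'
#' @param sequences named character vector of upper-case A/C/G/T/N sequences;
#'   names are contig names and the element order fixes contig ordinals.
#' @return an object of class `ref_genome` with elements `names`, `lengths`,
#'   `seq` (character) and `raw` (list of raw vectors).
#' @export
reference_genome <- function(sequences) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("contig sequences must have unique names")
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) stop("contig ", names(sequences)[bad][1], " contains non-ACGTN characters")
  g <- list(
    names   = names(sequences),
    lengths = nchar(sequences),
    seq     = unname(sequences),
    raw     = lapply(unname(sequences), charToRaw)
  )
  g$codes <- lapply(g$raw, function(r) CODE_OF[as.integer(r) + 1L])
  g$gcodes <- unlist(g$codes, use.names = FALSE)
  g$goffset <- cumsum(c(0L, unname(g$lengths[-length(g$lengths)])))
  names(g$lengths) <- g$names
  class(g) <- "ref_genome"
  g
}

#' @export
print.ref_genome <- function(x, ...) {
  cat("ref_genome:", length(x$names), "contigs,",
      format(sum(x$lengths), big.mark = ","), "bp\n")
  for (i in seq_along(x$names))
    cat(sprintf("  [%d] %s  %d bp\n", i - 1L, x$names[i], x$lengths[i]))
  invisible(x)
}

contig_ordinal <- function(genome, name) {
  ord <- match(name, genome$names) - 1L
  if (anyNA(ord)) stop("unknown contig: ", paste(unique(name[is.na(ord)]), collapse = ", "))
  ord
}

#' Read a reference genome from FASTA
#'
#' @param path FASTA file.
#' @return a [reference_genome()] object; contig order follows file order.
#' @export
read_fasta_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  reference_genome(seqs)
}

#' Write a reference genome to FASTA with a sidecar .fai index
#'
#' Sequences are wrapped at 60 columns; the `.fai` sidecar (name, length,
#' offset, linebases, linewidth) is computed from the same layout.
#'
#' @param genome a `ref_genome`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta_genome <- function(genome, path) {
  width <- 60L
  ss <- Biostrings::DNAStringSet(genome$seq)
  names(ss) <- genome$names
  Biostrings::writeXStringSet(ss, path, width = width)
  # sidecar index: offsets assume ">name\n" headers and unix line endings
  off <- 0
  fai <- character(length(genome$names))
  for (i in seq_along(genome$names)) {
    off <- off + nchar(genome$names[i]) + 2L      # ">" + name + "\n"
    len <- genome$lengths[[i]]
    fai[i] <- paste(genome$names[i], len, off, width, width + 1L, sep = "\t")
    off <- off + len + ceiling(len / width)        # sequence bytes + newlines
  }
  writeLines(fai, paste0(path, ".fai"))
  invisible(path)
}
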