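# Minimal VCF 4.x text I/O for the caller's own records and truth sets.
# Internal positions are 0-based; VCF text stays 1-based.

#' Read a VCF file into a variant table
#'
#' @param path VCF 4.x file (plain or gzipped). A `#CHROM` header line is
#'   required.
#' @param genome optional [reference_genome()]; if given, contigs and ref
#'   alleles are validated against it.
#' @return a `data.table` with columns contig, pos (0-based), id, ref, alt,
#'   qual, filter, info.
#' @export
read_vcf <- function(path, genome = NULL) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  hdr <- startsWith(lines, "#")
  if (!any(startsWith(lines, "#CHROM")))
    stop("missing #CHROM header line in ", path)
  body <- lines[!hdr]
  if (!length(body)) return(empty_variants())
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) < 8L)) stop("malformed VCF record (fewer than 8 fields)")
  field <- function(k) vapply(parts, `[[`, character(1), k)
  v <- data.table::data.table(
    contig = field(1), pos = as.integer(field(2)) - 1L, id = field(3),
    ref = field(4), alt = field(5), qual = field(6), filter = field(7),
    info = field(8))
  if (!is.null(genome)) {
    ord <- match(v$contig, genome$names)
    if (anyNA(ord)) stop("VCF names contig absent from genome: ",
                         v$contig[is.na(ord)][1])
    refseen <- substr(genome$seq[ord], v$pos + 1L, v$pos + nchar(v$ref))
    if (any(refseen != v$ref))
      stop("VCF ref allele disagrees with reference sequence at ",
           v$contig[refseen != v$ref][1], ":", v$pos[refseen != v$ref][1] + 1L)
  }
  v[]
}

empty_variants <- function() {
  data.table::data.table(contig = character(), pos = integer(), id = character(),
                         ref = character(), alt = character(), qual = character(),
                         filter = character(), info = character())
}

#' Write a variant table to VCF 4.2 text
#'
#' @param variants table as returned by [read_vcf()] or the caller.
#' @param genome a [reference_genome()] for `##contig` header lines.
#' @param path output path.
#' @param info_defs optional character vector of `##INFO=...` header lines.
#' @return number of records written, invisibly.
#' @export
write_vcf <- function(variants, genome, path, info_defs = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", genome$names, ",length=", genome$lengths, ">"),
           info_defs,
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- vcf_format_body(variants)
  writeLines(c(hdr, body), path)
  invisible(length(body))
}

vcf_format_body <- function(variants) {
  if (!nrow(variants)) return(character())
  paste(variants$contig, variants$pos + 1L, variants$id, variants$ref,
        variants$alt, variants$qual, variants$filter, variants$info, sep = "\t")
}

#' Known-sites mask for recalibration
#'
#' Converts a known-variants table to per-contig logical masks of positions
#' excluded from BQSR counting: SNV positions themselves and, for indel
#' records (ref/alt length differ), the affected interval padded by
#' `indel_pad` bases on each side.
#'
#' @param known variant table from [read_vcf()].
#' @param genome a [reference_genome()].
#' @param indel_pad padding around indel intervals, in bases.
#' @return named list (per contig) of logical vectors, TRUE = masked.
#' @export
known_sites_mask <- function(known, genome, indel_pad = 5L) {
  mask <- lapply(genome$lengths, function(n) logical(n))
  names(mask) <- genome$names
  if (!nrow(known)) return(mask)
  for (i in seq_len(nrow(known))) {
    ctg <- known$contig[i]
    if (!ctg %in% genome$names) stop("known site on unknown contig ", ctg)
    span <- max(nchar(known$ref[i]), 1L)
    alts <- strsplit(known$alt[i], ",", fixed = TRUE)[[1]]
    is_indel <- any(nchar(alts) != nchar(known$ref[i]))
    from <- known$pos[i]
    to <- known$pos[i] + span - 1L
    if (is_indel) { from <- from - indel_pad; to <- to + indel_pad }
    from <- max(from, 0L)
    to <- min(to, genome$lengths[[ctg]] - 1L)
    mask[[ctg]][(from + 1L):(to + 1L)] <- TRUE
  }
  mask
}
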