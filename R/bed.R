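# RegionSpec import/export as BED (0-based half-open) with a 4th
# region-ordinal column.

#' Write a region specification to BED
#'
#' @param spec a `region_spec` (see [compute_regions()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_region_bed <- function(spec, path) {
  writeLines(paste(spec$regions$contig, spec$regions$start, spec$regions$end,
                   spec$regions$region, sep = "\t"), path)
  invisible(path)
}

#' Read a region specification from BED
#'
#' @param path BED file written by [write_region_bed()].
#' @param genome a [reference_genome()]; the spec is validated against it.
#' @return a `region_spec`.
#' @export
read_region_bed <- function(path, genome) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("contig", "start", "end", "region"),
                          colClasses = list(character = 1, integer = 2:4))
  new_region_spec(dt, genome)
}
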