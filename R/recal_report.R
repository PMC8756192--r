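# Tab-separated recalibration-report serialization: the on-disk form of the
# partial and merged genome-wide covariate tables.

RECAL_COLS <- c("read_group", "reported_q", "cycle", "dinuc_context",
                "observations", "errors")

#' Create an (empty) recalibration covariate table
#'
#' A recal table maps (read group, reported quality, machine-cycle bin,
#' dinucleotide context) to integer observation and mismatch counts.
#'
#' @param rows optional data.frame with the six report columns.
#' @param metadata named list with `genome_id` and `known_id` identifying the
#'   inputs the counts were taken against; tables merge only if these match.
#' @return a `recal_table` (a keyed data.table with a `metadata` attribute).
#' @export
recal_table <- function(rows = NULL, metadata = list(genome_id = "", known_id = "")) {
  if (is.null(rows)) {
    rows <- data.table::data.table(
      read_group = character(), reported_q = integer(), cycle = integer(),
      dinuc_context = character(), observations = integer(), errors = integer())
  } else {
    rows <- data.table::as.data.table(rows)[, RECAL_COLS, with = FALSE]
  }
  validate_recal_rows(rows)
  data.table::setkeyv(rows, c("read_group", "reported_q", "cycle", "dinuc_context"))
  data.table::setattr(rows, "metadata", metadata)
  data.table::setattr(rows, "class", c("recal_table", class(rows)))
  rows
}

validate_recal_rows <- function(rows) {
  if (nrow(rows)) {
    if (any(rows$observations < 0L) || any(rows$errors < 0L))
      stop("negative count in recalibration table")
    if (any(rows$errors > rows$observations))
      stop("recalibration table has errors > observations")
  }
  invisible(rows)
}

#' Write a recalibration table to its tab-separated report format
#'
#' @param table a [recal_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recal_report <- function(table, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(paste0("#genome_id=", attr(table, "metadata")$genome_id), con)
  writeLines(paste0("#known_id=", attr(table, "metadata")$known_id), con)
  writeLines(paste(RECAL_COLS, collapse = "\t"), con)
  if (nrow(table))
    writeLines(paste(table$read_group, table$reported_q, table$cycle,
                     table$dinuc_context, table$observations, table$errors,
                     sep = "\t"), con)
  invisible(path)
}

#' Read a recalibration report
#'
#' @param path report written by [write_recal_report()].
#' @return a [recal_table()]; counts are validated (`0 <= errors <=
#'   observations`).
#' @export
read_recal_report <- function(path) {
  lines <- readLines(path)
  meta_lines <- lines[startsWith(lines, "#")]
  meta <- list(genome_id = "", known_id = "")
  for (m in meta_lines) {
    kv <- sub("^#", "", m)
    key <- sub("=.*$", "", kv)
    if (key %in% names(meta)) meta[[key]] <- sub("^[^=]*=", "", kv)
  }
  body <- lines[!startsWith(lines, "#")]
  if (!length(body) || body[1] != paste(RECAL_COLS, collapse = "\t"))
    stop("recalibration report missing column header")
  if (length(body) == 1L) return(recal_table(metadata = meta))
  dt <- data.table::fread(text = body[-1], header = FALSE, sep = "\t",
                          col.names = RECAL_COLS,
                          colClasses = list(character = c(1, 4), integer = c(2, 3, 5, 6)))
  recal_table(dt, metadata = meta)
}
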