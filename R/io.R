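# TSV readers and writers for count tables, sample metadata and taxonomy.

#' Read an OTU count table from TSV
#'
#' Expects a tab-separated file whose header row holds sample IDs and whose
#' first column holds taxon IDs; all remaining cells must be non-negative
#' integers. The same layout is produced by [write_count_table()], and the
#' two functions round-trip tables exactly.
#'
#' @param path path to a TSV file.
#' @return integer matrix (taxa x samples) with taxon rownames and sample
#'   colnames.
#' @seealso [write_count_table()]
#' @export
read_count_table <- function(path) {
  if (!file.exists(path))
    stop_phantax(paste("file not found:", path), "io_error")
  lines <- readLines(path)
  if (length(lines) < 1L)
    stop_phantax(paste("empty count table file:", path), "parse_error")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_expected <- length(fields[[1L]])
  bad <- which(vapply(fields, length, 1L) != ncol_expected)
  if (length(bad))
    stop_phantax(sprintf("ragged row at line %d of %s", bad[1L], path),
                 "parse_error")
  header <- fields[[1L]][-1L]
  body <- fields[-1L]
  taxa <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(taxa))
    stop_phantax(sprintf("duplicate taxon ID '%s' in %s",
                         taxa[duplicated(taxa)][1L], path), "parse_error")
  if (anyDuplicated(header))
    stop_phantax(sprintf("duplicate sample ID '%s' in %s",
                         header[duplicated(header)][1L], path), "parse_error")
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1L]), numeric(ncol_expected - 1L))
  )
  if (anyNA(vals)) {
    bad_row <- which(vapply(body, function(f)
      anyNA(suppressWarnings(as.numeric(f[-1L]))), TRUE))[1L]
    stop_phantax(sprintf("non-numeric count at line %d of %s", bad_row + 1L, path),
                 "parse_error")
  }
  mat <- matrix(vals, ncol = length(body),
                dimnames = list(header, taxa))
  mat <- t(mat)
  validate_count_table(mat, path)
  storage.mode(mat) <- "integer"
  mat
}

#' Write an OTU count table to TSV
#'
#' @param table integer count matrix (taxa x samples).
#' @param path output file path.
#' @param id_col header label for the taxon-ID column.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path, id_col = "taxon_id") {
  validate_count_table(table)
  df <- data.frame(rownames(table), table, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a sample-metadata table
#'
#' Metadata rows describe sequencing libraries: the design coordinates
#' (soil, treatment, timepoint, mesocosm, technical replicate), the nucleic
#' acid of the library (DNA or cDNA), a negative-control flag, and a
#' `pair_id` linking the DNA and cDNA libraries from the same biological
#' sample.
#'
#' @param path TSV file path.
#' @return data.frame with one row per library.
#' @export
read_sample_metadata <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.character(meta$is_negative_control))
    meta$is_negative_control <- as.logical(meta$is_negative_control)
  validate_metadata(meta)
  meta
}

#' @rdname read_sample_metadata
#' @param meta metadata data.frame.
#' @export
write_sample_metadata <- function(meta, path) {
  validate_metadata(meta)
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy table
#'
#' First column `taxon_id`, remaining columns taxonomic ranks (strings; may
#' be empty). Classification itself is out of scope; the table is consumed
#' by [filter_taxonomy()].
#'
#' @param path TSV file path.
#' @return data.frame with unique `taxon_id`.
#' @export
read_taxonomy <- function(path) {
  tax <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"taxon_id" %in% names(tax))
    stop_phantax("taxonomy table must have a taxon_id column", "parse_error")
  if (anyDuplicated(tax$taxon_id))
    stop_phantax("taxonomy table has duplicate taxon IDs", "parse_error")
  tax
}
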