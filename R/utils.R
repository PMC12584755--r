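# Internal validators shared across modules.

stop_phantax <- function(msg, class) {
  stop(structure(
    class = c(class, "phantax_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Validate a count table
#'
#' A count table is an integer matrix of taxa (rows) by samples (columns)
#' with unique, non-empty dimnames and no negative entries.
#'
#' @param x object to validate.
#' @param arg name used in error messages.
#' @return `x`, invisibly, with storage mode integer.
#' @keywords internal
validate_count_table <- function(x, arg = "table") {
  if (!is.matrix(x) || !is.numeric(x))
    stop_phantax(sprintf("%s must be a numeric matrix", arg), "validation_error")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop_phantax(sprintf("%s must have taxon rownames and sample colnames", arg),
                 "validation_error")
  if (anyDuplicated(rownames(x)))
    stop_phantax(sprintf("%s has duplicate taxon IDs: %s", arg,
                         paste(unique(rownames(x)[duplicated(rownames(x))]),
                               collapse = ", ")), "validation_error")
  if (anyDuplicated(colnames(x)))
    stop_phantax(sprintf("%s has duplicate sample IDs", arg), "validation_error")
  if (anyNA(x) || any(x < 0))
    stop_phantax(sprintf("%s contains negative or missing counts", arg),
                 "validation_error")
  if (any(x != round(x)))
    stop_phantax(sprintf("%s contains non-integer counts", arg), "validation_error")
  storage.mode(x) <- "integer"
  invisible(x)
}

# Check two matrices are taxon/sample aligned.
check_aligned <- function(a, b, what = "tables") {
  if (!identical(dim(a), dim(b)) ||
      !identical(rownames(a), rownames(b)) ||
      !identical(colnames(a), colnames(b)))
    stop_phantax(sprintf("%s are not aligned (dimensions or dimnames differ)", what),
                 "alignment_error")
  invisible(TRUE)
}

required_meta_cols <- c("sample_id", "nucleic_acid", "soil", "treatment",
                        "timepoint", "mesocosm_id", "tech_rep",
                        "is_negative_control", "pair_id")

validate_metadata <- function(meta) {
  if (!is.data.frame(meta))
    stop_phantax("metadata must be a data.frame", "validation_error")
  missing <- setdiff(required_meta_cols, names(meta))
  if (length(missing))
    stop_phantax(paste("metadata missing columns:", paste(missing, collapse = ", ")),
                 "validation_error")
  if (anyDuplicated(meta$sample_id))
    stop_phantax("metadata sample_id values are not unique", "validation_error")
  bad <- !meta$nucleic_acid %in% c("DNA", "cDNA")
  if (any(bad))
    stop_phantax("nucleic_acid must be 'DNA' or 'cDNA'", "validation_error")
  # each pair_id maps to at most one DNA and one cDNA library
  tab <- table(meta$pair_id, meta$nucleic_acid)
  if (any(tab > 1))
    stop_phantax("a pair_id maps to more than one library of the same nucleic acid",
                 "validation_error")
  invisible(meta)
}
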