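#' Write an intensity table to TSV with a metadata header
#'
#' The header block consists of `#key<TAB>value` lines (currently the
#' detection floor) followed by a standard tab-separated table.
#'
#' @param table `intensity_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  con <- file(path, "w")
  on.exit(close(con))
  floor <- attr(table, "detection_floor")
  if (!is.null(floor))
    writeLines(sprintf("#detection_floor\t%.15g", floor), con)
  utils::write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an intensity table written by [write_intensity_table()]
#'
#' Peptide intensity tables in the same long schema produced by the
#' generator (columns `species`, `replicate`, `intensity` plus arbitrary
#' condition columns) can also be supplied by the user.
#'
#' @param path TSV file, optionally with `#key<TAB>value` header lines.
#' @return `intensity_table` data.frame.
#' @export
read_intensity_table <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines)
  floor <- NULL
  if (length(meta)) {
    kv <- strsplit(sub("^#", "", lines[meta]), "\t")
    for (p in kv) if (p[1] == "detection_floor") floor <- as.numeric(p[2])
  }
  body <- if (length(meta)) lines[-meta] else lines
  df <- utils::read.table(text = body, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("species", "replicate", "intensity") %in% names(df)))
  structure(df, class = c("intensity_table", "data.frame"),
            detection_floor = floor)
}

#' Read or write substitution / error-frequency tables
#'
#' TSV with columns `protein_id`, `position`, `from_aa`, `to_aa`,
#' `parent_codon`, `mismatch_class`, `ef`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_ef_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "from_aa", "to_aa", "parent_codon",
            "mismatch_class", "ef")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("ef table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df
}

#' @rdname read_ef_table
#' @param table data.frame to write.
#' @export
write_ef_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
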