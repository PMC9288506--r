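#' Default column map for peptide reports
#'
#' Maps the package's canonical field names to the column names of a
#' peptide-level quantification export. Exports from DIA search tools vary
#' by vendor and version, so every entry is overridable;
#' `stripped_sequence` and `dose` may be absent from the file
#' (they are then derived from `modified_sequence` and `dose_label`).
#'
#' @return Named list of column names.
#' @export
default_column_map <- function() {
  list(
    protein_id = "protein_id",
    modified_sequence = "modified_sequence",
    stripped_sequence = "stripped_sequence",
    dose = "dose",
    dose_label = "dose_label",
    replicate = "replicate",
    quantity = "quantity"
  )
}

#' Read a peptide-level quantification report
#'
#' Reads a tab- or comma-separated peptide report (as exported from a DIA
#' search tool) into the validated long-format quant table the pipeline
#' consumes. Modification annotations are stripped to produce
#' `stripped_sequence` when the file does not carry one, and doses may be
#' given either as molar numbers (`dose` column) or as labels like `"2mM"`
#' (`dose_label` column, parsed by [parse_dose_label()]).
#'
#' @param path Path to a TSV/CSV file.
#' @param column_map Named list mapping canonical names to file columns;
#'   see [default_column_map()]. Partial maps are merged over the default.
#' @return A validated peptide quant tibble (see [validate_quant_table()]).
#' @export
read_peptide_report <- function(path, column_map = default_column_map()) {
  if (!file.exists(path)) {
    abort(paste0("report file not found: ", path),
          class = "lipsite_error_io")
  }
  column_map <- utils::modifyList(default_column_map(), column_map)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (nrow(raw) == 0) {
    abort(paste0("report '", path, "' contains no data rows"),
          class = "lipsite_error_empty_table")
  }
  need <- c("protein_id", "modified_sequence", "replicate", "quantity")
  for (field in need) {
    if (!column_map[[field]] %in% names(raw)) {
      abort(paste0("required column '", column_map[[field]],
                   "' (", field, ") not found in report"),
            class = "lipsite_error_missing_column")
    }
  }
  out <- tibble(
    protein_id = as.character(raw[[column_map$protein_id]]),
    modified_sequence = as.character(raw[[column_map$modified_sequence]]),
    replicate = as.character(raw[[column_map$replicate]]),
    quantity = as.numeric(raw[[column_map$quantity]])
  )
  out$stripped_sequence <-
    if (column_map$stripped_sequence %in% names(raw)) {
      as.character(raw[[column_map$stripped_sequence]])
    } else {
      strip_modifications(out$modified_sequence)
    }
  if (column_map$dose %in% names(raw)) {
    out$dose <- as.numeric(raw[[column_map$dose]])
  } else if (column_map$dose_label %in% names(raw)) {
    out$dose <- parse_dose_label(as.character(raw[[column_map$dose_label]]))
  } else {
    abort(paste0("neither a '", column_map$dose, "' nor a '",
                 column_map$dose_label, "' column found in report"),
          class = "lipsite_error_missing_column")
  }
  validate_quant_table(
    out[, c("protein_id", "modified_sequence", "stripped_sequence",
            "dose", "replicate", "quantity")])
}

#' Write a peptide quant table as TSV
#'
#' @param quant A validated peptide quant table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_report <- function(quant, path) {
  quant <- validate_quant_table(quant)
  readr::write_tsv(quant, path, progress = FALSE)
  invisible(path)
}
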