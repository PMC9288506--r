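#' Validate a peptide quantification table
#'
#' The long-format peptide quantification table is the pipeline's central
#' currency: one row per (modified peptide, dose, replicate) with a strictly
#' positive intensity. `modified_sequence` may carry bracketed modification
#' annotations; `stripped_sequence` is the plain upper-case one-letter
#' sequence used for structure mapping.
#'
#' @param quant A data frame with columns `protein_id`, `modified_sequence`,
#'   `stripped_sequence`, `dose`, `replicate`, `quantity`.
#' @return The validated table as a tibble.
#' @export
validate_quant_table <- function(quant) {
  quant <- as_tibble(quant)
  needed <- c("protein_id", "modified_sequence", "stripped_sequence",
              "dose", "replicate", "quantity")
  missing <- setdiff(needed, names(quant))
  if (length(missing)) {
    abort(paste0("peptide quant table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "lipsite_error_missing_column")
  }
  if (nrow(quant) == 0) {
    abort("peptide quant table is empty", class = "lipsite_error_empty_table")
  }
  bad <- which(!is.finite(quant$quantity) | quant$quantity <= 0)
  if (length(bad)) {
    abort(paste0("non-positive or non-finite quantity in row(s): ",
                 paste(head(bad, 10), collapse = ", ")),
          class = "lipsite_error_bad_quantity")
  }
  key <- paste(quant$modified_sequence, quant$dose, quant$replicate,
               sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    first <- strsplit(key[dup[1]], "\r", fixed = TRUE)[[1]]
    abort(paste0("duplicate (peptide, dose, replicate) key: peptide '",
                 first[1], "', dose ", first[2], ", replicate '",
                 first[3], "'"),
          class = "lipsite_error_duplicate_key")
  }
  exp_strip <- strip_modifications(quant$modified_sequence)
  if (!all(quant$stripped_sequence == exp_strip)) {
    abort("stripped_sequence does not match modified_sequence with annotations removed",
          class = "lipsite_error_sequence_mismatch")
  }
  quant
}

#' Remove modification annotations from a peptide sequence
#'
#' Strips square- or parenthesis-bracketed modification annotations (e.g.
#' `"C[Carbamidomethyl]TLADIK"`) and any flanking underscores, returning the
#' plain upper-case sequence.
#'
#' @param modified_sequence Character vector of modified peptide sequences.
#' @return Character vector of stripped sequences.
#' @examples
#' strip_modifications("_C[Carbamidomethyl]TLADIK_")
#' @export
strip_modifications <- function(modified_sequence) {
  s <- gsub("\\[[^]]*\\]|\\([^)]*\\)", "", modified_sequence)
  toupper(gsub("_", "", s, fixed = TRUE))
}

#' Median-centre log2 quantities per sample
#'
#' Adds a `log2_norm` column: `log2(quantity)` minus the per-sample
#' (dose x replicate) median of `log2(quantity)` across all peptides. This
#' removes loading differences between runs before any statistics; all
#' differential tests and dose-response fits operate on `log2_norm`.
#'
#' @param quant A peptide quant table (see [validate_quant_table()]).
#' @param center Logical; `FALSE` sets `log2_norm = log2(quantity)` without
#'   centring (useful for single-peptide toy inputs).
#' @return The table with a `log2_norm` column appended.
#' @export
normalize_quant <- function(quant, center = TRUE) {
  quant <- validate_quant_table(quant)
  quant$log2_norm <- log2(quant$quantity)
  if (center) {
    quant <- quant |>
      dplyr::group_by(.data$dose, .data$replicate) |>
      dplyr::mutate(log2_norm = .data$log2_norm -
                      stats::median(.data$log2_norm)) |>
      dplyr::ungroup()
  }
  quant
}
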