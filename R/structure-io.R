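# IUPAC 2021 standard atomic weights, rounded; covers the elements seen in
# protein crystal structures (incl. common ions/cofactors).
.element_masses <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  "NA" = 22.990, K = 39.098, MG = 24.305, CA = 40.078, MN = 54.938,
  FE = 55.845, CO = 58.933, NI = 58.693, CU = 63.546, ZN = 65.38,
  MO = 95.95, W = 183.84
)

# Element from the atom-name field when columns 77-78 are blank. Two-letter
# ions/metals appear as atom names equal to the residue name (e.g. "ZN"/ZN);
# otherwise the first alphabetic character after stripping digits wins
# (handles "1HB", "CA" = alpha carbon, "OXT", ...).
guess_element <- function(atom_name, resid) {
  nm <- toupper(gsub("[^A-Za-z]", "", atom_name))
  two <- toupper(substr(nm, 1, 2))
  ifelse(two == toupper(resid) & two %in% names(.element_masses),
         two, substr(nm, 1, 1))
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM (and optionally HETATM) records into a flat atom table.
#' Elements come from the PDB element column when present, falling back to an
#' atom-name heuristic; each atom is assigned its standard atomic mass.
#' Hydrogens are excluded by default (crystal structures rarely resolve
#' them), alternate locations are resolved to the blank/'A' conformer, and
#' only one MODEL of a multi-model file is kept.
#'
#' @param path Path to a PDB file.
#' @param altloc_policy `"first"` keeps blank/'A' altLocs only; `"all"`
#'   keeps every conformer.
#' @param model_index Which MODEL to keep in multi-model files (default 1).
#' @param include_hetatm Keep HETATM records? Default `FALSE`.
#' @param keep_hydrogens Keep hydrogen/deuterium atoms? Default `FALSE`.
#' @return A tibble of class `lip_structure` with columns `record`, `chain`,
#'   `resno`, `insert`, `resid`, `atom_name`, `element`, `mass`, `x`, `y`,
#'   `z` (coordinates in Angstrom, author residue numbering).
#' @export
read_structure <- function(path, altloc_policy = c("first", "all"),
                           model_index = 1L, include_hetatm = FALSE,
                           keep_hydrogens = FALSE) {
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(path)) {
    abort(paste0("structure file not found: ", path),
          class = "lipsite_error_io")
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) {
      abort(paste0("failed to parse PDB file '", path, "': ",
                   conditionMessage(e)),
            class = "lipsite_error_pdb_parse")
    })
  at <- as_tibble(pdb$atom)
  if (nrow(at) == 0 || !any(at$type == "ATOM")) {
    abort(paste0("no ATOM records in '", path, "'"),
          class = "lipsite_error_pdb_parse")
  }
  n_models <- nrow(pdb$xyz)
  if (model_index < 1 || model_index > n_models) {
    abort(paste0("model_index ", model_index, " out of range (file has ",
                 n_models, " model(s))"),
          class = "lipsite_error_pdb_parse")
  }
  xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
  at$x <- xyz[, 1]
  at$y <- xyz[, 2]
  at$z <- xyz[, 3]

  if (!include_hetatm) at <- at[at$type == "ATOM", ]
  if (altloc_policy == "first") {
    at <- at[is.na(at$alt) | at$alt %in% c("", "A"), ]
  }
  elesy <- toupper(trimws(ifelse(is.na(at$elesy), "", at$elesy)))
  fallback <- guess_element(at$elety, at$resid)
  element <- ifelse(elesy == "", fallback, elesy)
  unknown <- !(element %in% names(.element_masses))
  if (any(unknown)) {
    k <- which(unknown)[1]
    abort(paste0("cannot resolve element for atom '", at$elety[k],
                 "' in residue ", at$resid[k], " ", at$resno[k],
                 " (chain ", at$chain[k], ")"),
          class = "lipsite_error_unknown_element")
  }
  out <- tibble(
    record = at$type,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    resid = at$resid,
    atom_name = at$elety,
    element = element,
    mass = unname(.element_masses[element]),
    x = at$x, y = at$y, z = at$z
  )
  if (!keep_hydrogens) out <- out[!out$element %in% c("H", "D"), ]
  if (any(!is.finite(out$x + out$y + out$z))) {
    abort("non-finite coordinates in structure",
          class = "lipsite_error_pdb_parse")
  }
  class(out) <- c("lip_structure", class(out))
  out
}

#' Residues of one chain, in author order
#'
#' @param structure A `lip_structure` atom table.
#' @param chain Chain identifier.
#' @return Tibble with one row per residue: `resno`, `insert`, `resid`,
#'   `one_letter` (`"X"` for non-standard residues), ordered by
#'   (`resno`, `insert`).
#' @export
chain_residues <- function(structure, chain) {
  at <- structure[structure$chain == chain & structure$record == "ATOM", ]
  if (nrow(at) == 0) {
    abort(paste0("chain '", chain, "' not found in structure"),
          class = "lipsite_error_chain")
  }
  res <- dplyr::distinct(at, .data$resno, .data$insert, .data$resid)
  res <- res[order(res$resno, res$insert), ]
  one <- suppressWarnings(bio3d::aa321(res$resid))
  one[is.na(one) | !(one %in% .standard_aa)] <- "X"
  res$one_letter <- one
  res
}

#' One-letter sequence of a chain
#'
#' @inheritParams chain_residues
#' @return Single string; unresolved/non-standard residues appear as `"X"`.
#' @export
structure_sequence <- function(structure, chain) {
  paste(chain_residues(structure, chain)$one_letter, collapse = "")
}
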