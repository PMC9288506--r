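#' Map a peptide sequence onto a structure chain
#'
#' Exact substring match of the stripped peptide against the chain's
#' one-letter sequence (derived from the resolved residues in author
#' order). A unique match yields the residue range and its atoms; no match
#' yields a non-fatal "unmapped" row; multiple matches raise an error
#' listing all positions, since the caller must disambiguate.
#'
#' @param peptide Stripped (unmodified) peptide sequence.
#' @param structure A `lip_structure` atom table.
#' @param chain Chain identifier.
#' @param il_equivalent Treat isoleucine and leucine as equivalent during
#'   matching (mass spectrometry cannot distinguish them)? Default `FALSE`:
#'   structures can.
#' @return A one-row tibble: `peptide`, `chain`, `mapped`, `start_resno`,
#'   `end_resno`, `n_residues`, `unresolved`, and an `atoms` list-column
#'   holding the resolved atoms of the matched residues.
#' @export
map_peptide_to_structure <- function(peptide, structure, chain,
                                     il_equivalent = FALSE) {
  res <- chain_residues(structure, chain)
  seq_chain <- paste(res$one_letter, collapse = "")
  pat <- toupper(peptide)
  subj <- seq_chain
  if (il_equivalent) {
    pat <- gsub("L", "I", pat, fixed = TRUE)
    subj <- gsub("L", "I", subj, fixed = TRUE)
  }
  # overlapping occurrences too (lookahead), so ambiguity is never missed
  hits <- gregexpr(paste0("(?=", pat, ")"), subj, perl = TRUE)[[1]]
  hits <- as.integer(hits[hits > 0])
  empty <- tibble(peptide = peptide, chain = chain, mapped = FALSE,
                  start_resno = NA_integer_, end_resno = NA_integer_,
                  n_residues = 0L, unresolved = 0L,
                  atoms = list(tibble()))
  if (length(hits) == 0) return(empty)
  if (length(hits) > 1) {
    abort(paste0("peptide '", peptide, "' matches chain ", chain,
                 " at multiple positions: ",
                 paste(hits, collapse = ", "),
                 "; disambiguate before mapping"),
          class = "lipsite_error_ambiguous_match")
  }
  span <- res[hits:(hits + nchar(pat) - 1L), ]
  at <- structure[structure$chain == chain &
                    structure$record == "ATOM", ]
  key_at <- paste(at$resno, at$insert)
  key_span <- paste(span$resno, span$insert)
  atoms <- at[key_at %in% key_span, ]
  start <- span$resno[1]
  end <- span$resno[nrow(span)]
  tibble(peptide = peptide, chain = chain, mapped = TRUE,
         start_resno = start, end_resno = end,
         n_residues = nrow(span),
         unresolved = max(0L, as.integer(end - start + 1L - nrow(span))),
         atoms = list(atoms))
}

#' Map several peptides onto a structure
#'
#' @param peptides Character vector of stripped peptide sequences.
#' @param structure A `lip_structure` atom table.
#' @param chain Chain identifier; `NULL` (default) picks the first chain
#'   containing all peptides and errors when no single chain does.
#' @inheritParams map_peptide_to_structure
#' @return A tibble with one row per peptide (see
#'   [map_peptide_to_structure()]).
#' @export
map_peptides <- function(peptides, structure, chain = NULL,
                         il_equivalent = FALSE) {
  if (is.null(chain)) {
    chains <- unique(structure$chain[structure$record == "ATOM"])
    ok <- NULL
    for (ch in chains) {
      s <- structure_sequence(structure, ch)
      if (all(vapply(peptides, function(p) grepl(p, s, fixed = TRUE),
                     logical(1)))) {
        ok <- ch
        break
      }
    }
    if (is.null(ok)) {
      abort("no single chain contains all peptides; pass `chain` explicitly",
            class = "lipsite_error_chain")
    }
    chain <- ok
  }
  purrr::map_dfr(peptides, map_peptide_to_structure,
                 structure = structure, chain = chain,
                 il_equivalent = il_equivalent)
}

#' Centre of mass of an atom set
#'
#' Per-axis weighted mean \eqn{\sum w_i x_i / \sum w_i}, with weights equal
#' to standard atomic masses (`"mass"`, default) or to 1 (`"geometric"`).
#'
#' @param atoms Atom table with `x`, `y`, `z` and (for mass weighting)
#'   `mass` columns.
#' @param weighting `"mass"` or `"geometric"`.
#' @return Named numeric vector `c(x, y, z)` in Angstrom.
#' @export
center_of_mass <- function(atoms, weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  if (is.null(atoms) || nrow(atoms) == 0) {
    abort("cannot compute the centre of mass of an empty atom set",
          class = "lipsite_error_empty_atoms")
  }
  w <- if (weighting == "mass") atoms$mass else rep(1, nrow(atoms))
  c(x = sum(w * atoms$x) / sum(w),
    y = sum(w * atoms$y) / sum(w),
    z = sum(w * atoms$z) / sum(w))
}

#' Triangulate a binding site from mapped peptides
#'
#' Pools the atoms of all usable peptide mappings (atoms shared by
#' overlapping peptides counted once by default), computes their centre of
#' mass, and lists the residues with any atom within `neighbor_radius` of
#' it — the package's structural prediction of where the compound binds.
#'
#' @param mappings Mapping tibble from [map_peptides()], optionally carrying
#'   fit columns (`r_squared`, `ec50`) for reporting.
#' @param structure The `lip_structure` the mappings refer to.
#' @param weighting `"mass"` (default) or `"geometric"`.
#' @param neighbor_radius Radius (Angstrom) for the nearby-residue report.
#' @param dedupe Count atoms shared by overlapping peptides once
#'   (default `TRUE`)?
#' @return An object of class `lip_site`: `com` (named xyz), `atoms`,
#'   `n_atoms`, `peptides` (the usable mappings), `nearby` (residues
#'   sorted by distance), `weighting`, `neighbor_radius`, `structure`.
#' @export
predict_binding_site <- function(mappings, structure,
                                 weighting = c("mass", "geometric"),
                                 neighbor_radius = 8, dedupe = TRUE) {
  weighting <- match.arg(weighting)
  usable <- mappings[mappings$mapped &
                       vapply(mappings$atoms, nrow, integer(1)) > 0, ]
  if (nrow(usable) == 0) {
    abort("no usable peptide mappings (all unmapped or atom-free)",
          class = "lipsite_error_no_mappings")
  }
  atoms <- dplyr::bind_rows(usable$atoms)
  if (dedupe) {
    atoms <- dplyr::distinct(atoms, .data$chain, .data$resno, .data$insert,
                             .data$atom_name, .keep_all = TRUE)
  }
  com <- center_of_mass(atoms, weighting)
  st <- structure[structure$record == "ATOM", ]
  dist <- sqrt((st$x - com["x"])^2 + (st$y - com["y"])^2 +
                 (st$z - com["z"])^2)
  near <- st
  near$dist <- dist
  nearby <- near |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert, .data$resid) |>
    dplyr::summarise(min_dist = min(.data$dist), .groups = "drop") |>
    dplyr::filter(.data$min_dist <= neighbor_radius) |>
    dplyr::arrange(.data$min_dist)
  structure(list(com = com, atoms = atoms, n_atoms = nrow(atoms),
                 peptides = usable, nearby = nearby,
                 weighting = weighting, neighbor_radius = neighbor_radius,
                 structure = structure),
            class = "lip_site")
}

#' @export
print.lip_site <- function(x, ...) {
  cat("<lip_site> predicted binding site\n")
  cat(sprintf("  CoM (%s-weighted): (%.3f, %.3f, %.3f) A from %d atoms\n",
              x$weighting, x$com["x"], x$com["y"], x$com["z"], x$n_atoms))
  cat(sprintf("  %d contributing peptide(s); %d residue(s) within %.1f A\n",
              nrow(x$peptides), nrow(x$nearby), x$neighbor_radius))
  invisible(x)
}

#' @rdname predict_binding_site
#' @param x,object A `lip_site` prediction.
#' @param ... Unused.
#' @export
tidy.lip_site <- function(x, ...) x$nearby

#' @rdname predict_binding_site
#' @export
glance.lip_site <- function(x, ...) {
  tibble(com_x = unname(x$com["x"]), com_y = unname(x$com["y"]),
         com_z = unname(x$com["z"]), n_atoms = x$n_atoms,
         n_peptides = nrow(x$peptides), n_nearby = nrow(x$nearby),
         weighting = x$weighting)
}

#' Plot a binding-site prediction
#'
#' Orthographic x/y projection: the structure in grey, pooled peptide
#' atoms in red, the centre of mass as an orange diamond.
#'
#' @param object A `lip_site` prediction.
#' @param ... Unused.
#' @export
autoplot.lip_site <- function(object, ...) {
  st <- object$structure[object$structure$record == "ATOM", ]
  ggplot2::ggplot(st, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(colour = "grey70", size = 0.6) +
    ggplot2::geom_point(data = object$atoms, colour = "firebrick",
                        size = 1) +
    ggplot2::annotate("point", x = object$com["x"], y = object$com["y"],
                      colour = "darkorange", shape = 18, size = 5) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (Å)", y = "y (Å)",
                  title = "Predicted binding site (x/y projection)")
}

#' Overlap report between two mapped peptide sets
#'
#' Two peptides overlap when their mapped residue ranges (inclusive author
#' numbering) share at least one residue. Used to compare the binding
#' peptides found for two different compounds.
#'
#' @param set_a,set_b Tibbles with columns `peptide`, `start_resno`,
#'   `end_resno` (e.g. from [map_peptides()]).
#' @return Tibble of overlapping pairs: `peptide_a`, `peptide_b`,
#'   `overlap_start`, `overlap_end`, `n_shared`; the number of overlapping
#'   pairs is its row count, also stored in attribute `n_pairs`.
#' @export
compare_peptide_sets <- function(set_a, set_b) {
  pairs <- tidyr::expand_grid(i = seq_len(nrow(set_a)),
                              j = seq_len(nrow(set_b)))
  a <- set_a[pairs$i, ]
  b <- set_b[pairs$j, ]
  lo <- pmax(a$start_resno, b$start_resno)
  hi <- pmin(a$end_resno, b$end_resno)
  keep <- !is.na(lo) & !is.na(hi) & lo <= hi
  out <- tibble(peptide_a = a$peptide[keep], peptide_b = b$peptide[keep],
                overlap_start = lo[keep], overlap_end = hi[keep],
                n_shared = hi[keep] - lo[keep] + 1L)
  attr(out, "n_pairs") <- nrow(out)
  out
}

#' Write the binding-site result files
#'
#' Writes (i) `<prefix>_site.tsv` — one row per contributing peptide with
#' its fit statistics (when present), mapped residue range, the CoM
#' coordinates and the nearby residues — and (ii) `<prefix>_site.pdb` —
#' the analysed structure plus a single HETATM pseudo-atom (residue `COM`)
#' at the predicted centre of mass, for molecular-graphics inspection.
#'
#' @param prediction A `lip_site` object.
#' @param prefix Output path prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_site_outputs <- function(prediction, prefix) {
  stopifnot(inherits(prediction, "lip_site"))
  pep <- prediction$peptides
  nearby_str <- paste(sprintf("%s%d(%.1fA)", prediction$nearby$resid,
                              prediction$nearby$resno,
                              prediction$nearby$min_dist),
                      collapse = ";")
  tab <- tibble(
    peptide = pep$peptide,
    chain = pep$chain,
    start_resno = pep$start_resno,
    end_resno = pep$end_resno,
    r_squared = if ("r_squared" %in% names(pep)) pep$r_squared else NA_real_,
    ec50 = if ("ec50" %in% names(pep)) pep$ec50 else NA_real_,
    com_x = unname(prediction$com["x"]),
    com_y = unname(prediction$com["y"]),
    com_z = unname(prediction$com["z"]),
    n_atoms_pooled = prediction$n_atoms,
    nearby_residues = nearby_str
  )
  tsv <- paste0(prefix, "_site.tsv")
  pdb <- paste0(prefix, "_site.pdb")
  readr::write_tsv(tab, tsv, progress = FALSE)

  st <- prediction$structure
  pseudo <- tibble(record = "HETATM", chain = st$chain[1],
                   resno = max(st$resno) + 1L, insert = "",
                   resid = "COM", atom_name = "COM", element = "C",
                   mass = .element_masses[["C"]],
                   x = unname(prediction$com["x"]),
                   y = unname(prediction$com["y"]),
                   z = unname(prediction$com["z"]))
  all_atoms <- dplyr::bind_rows(
    st[, c("record", "chain", "resno", "insert", "resid", "atom_name",
           "element", "mass", "x", "y", "z")],
    pseudo)
  write_structure(all_atoms, pdb)
  invisible(c(tsv = tsv, pdb = pdb))
}
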