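.standard_aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Ideal-geometry backbone (+ CB) coordinates for one chain segment.
# Helix: CA on a 2.3 A radius / 1.5 A rise / 100 deg-per-residue spiral,
# which gives the canonical 3.8 A CA(i)-CA(i+1) spacing. Extended: CA every
# 3.8 A along x. N/C/O/CB are placed at plausible offsets in a local frame;
# only connectivity-free per-atom positions are needed downstream.
build_segment_atoms <- function(sequence, geometry = c("helix", "extended"),
                                resno_start = 1L) {
  geometry <- match.arg(geometry)
  res <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(res), .standard_aa)
  if (length(bad)) {
    abort(paste0("non-standard residue letter(s): ",
                 paste(bad, collapse = ", ")),
          class = "lipsite_error_bad_residue")
  }
  n <- length(res)
  i <- seq_len(n) - 1
  if (geometry == "helix") {
    theta <- i * 100 * pi / 180
    ca <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
  } else {
    ca <- cbind(3.8 * i, 0, 0)
  }
  # local frames
  tvec <- rbind(ca[-1, , drop = FALSE], NA) - rbind(NA, ca[-n, , drop = FALSE])
  if (n == 1) {
    tvec <- matrix(c(1, 0, 0), 1, 3)
  } else {
    tvec[1, ] <- ca[2, ] - ca[1, ]
    tvec[n, ] <- ca[n, ] - ca[n - 1, ]
  }
  tvec <- tvec / sqrt(rowSums(tvec^2))
  if (geometry == "helix") {
    uvec <- cbind(cos(i * 100 * pi / 180), sin(i * 100 * pi / 180), 0)
  } else {
    uvec <- matrix(rep(c(0, 1, 0), each = n), n, 3)
  }
  vvec <- cbind(tvec[, 2] * uvec[, 3] - tvec[, 3] * uvec[, 2],
                tvec[, 3] * uvec[, 1] - tvec[, 1] * uvec[, 3],
                tvec[, 1] * uvec[, 2] - tvec[, 2] * uvec[, 1])
  nrm <- sqrt(rowSums(vvec^2))
  nrm[nrm < 1e-8] <- 1
  vvec <- vvec / nrm

  rows <- lapply(seq_len(n), function(k) {
    names <- c("N", "CA", "C", "O")
    xyz <- rbind(ca[k, ] - 1.46 * tvec[k, ] + 0.30 * uvec[k, ],
                 ca[k, ],
                 ca[k, ] + 1.52 * tvec[k, ] + 0.30 * uvec[k, ],
                 ca[k, ] + 1.52 * tvec[k, ] + 1.53 * uvec[k, ])
    if (res[k] != "G") {
      names <- c(names, "CB")
      xyz <- rbind(xyz, ca[k, ] + 1.53 * vvec[k, ] - 0.50 * tvec[k, ])
    }
    tibble(resno = resno_start + k - 1L,
           resid = bio3d::aa123(res[k]),
           atom_name = names,
           element = substr(names, 1, 1),
           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  })
  dplyr::bind_rows(rows)
}

# rigid-body transform helpers for placing segments in space
translate_atoms <- function(atoms, shift) {
  atoms$x <- atoms$x + shift[1]
  atoms$y <- atoms$y + shift[2]
  atoms$z <- atoms$z + shift[3]
  atoms
}

recenter_atoms <- function(atoms, center) {
  translate_atoms(atoms, center - c(mean(atoms$x), mean(atoms$y),
                                    mean(atoms$z)))
}

#' Write a minimal toy protein structure
#'
#' Builds a single-chain structure with ideal backbone geometry (N, CA, C, O
#' and CB for non-glycine residues; no hydrogens or further side-chain atoms)
#' and writes it as a PDB file. Intended for testing sequence-to-structure
#' mapping and centre-of-mass triangulation with fully known coordinates.
#'
#' @param sequence One-letter amino-acid string (20 standard residues).
#' @param geometry `"helix"` (alpha-helical spiral) or `"extended"`
#'   (straight 3.8 Angstrom CA spacing).
#' @param path Output PDB path.
#' @param chain Chain identifier, default `"A"`.
#' @return The structure, invisibly, as read back by [read_structure()] so
#'   the returned object reflects exactly what the file round-trips to.
#' @examples
#' tf <- tempfile(fileext = ".pdb")
#' s <- write_toy_structure("GASDF", "helix", tf)
#' @export
write_toy_structure <- function(sequence, geometry = c("helix", "extended"),
                                path, chain = "A") {
  geometry <- match.arg(geometry)
  atoms <- build_segment_atoms(sequence, geometry)
  atoms$chain <- chain
  write_structure(atoms, path)
  invisible(read_structure(path))
}

#' Write an atom table as a PDB file
#'
#' Serialises a structure atom table (columns `chain`, `resno`, `resid`,
#' `atom_name`, `element`, `x`, `y`, `z`, optionally `record`) to PDB
#' fixed-width format. HETATM rows are supported via `record = "HETATM"`.
#'
#' @param atoms Atom table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(atoms, path) {
  rec <- if ("record" %in% names(atoms)) atoms$record else
    rep("ATOM", nrow(atoms))
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
    type = rec,
    resno = atoms$resno,
    resid = atoms$resid,
    eleno = seq_len(nrow(atoms)),
    elety = atoms$atom_name,
    chain = atoms$chain,
    elesy = atoms$element,
    o = rep(1, nrow(atoms)),
    b = rep(0, nrow(atoms))
  )
  invisible(path)
}
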