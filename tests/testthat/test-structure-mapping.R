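toy_structure <- function(sequence) {
  tf <- withr::local_tempfile(fileext = ".pdb",
                              .local_envir = parent.frame())
  write_toy_structure(sequence, "helix", tf)
}

test_that("peptides map to the expected residue ranges", {
  s <- toy_structure("MKTAYIAKQRQISFVK")
  full <- map_peptide_to_structure("MKTAYIAKQRQISFVK", s, "A")
  expect_true(full$mapped)
  expect_equal(c(full$start_resno, full$end_resno), c(1, 16))
  expect_equal(full$n_residues, 16)
  # planted at a known offset: 17 residues of prefix, peptide starts at 18
  s2 <- toy_structure(paste0("MKTAYIAKQRQISFVKG", "WDNPECH", "STVMKTA"))
  m <- map_peptide_to_structure("WDNPECH", s2, "A")
  expect_equal(m$start_resno, 18)
  expect_equal(m$end_resno, 24)
  expect_equal(nrow(m$atoms[[1]]), 7 * 5)  # N, CA, C, O, CB per residue
})

test_that("absent and ambiguous peptides are handled as specified", {
  s <- toy_structure("AGAGAGADDDD")
  un <- map_peptide_to_structure("WWWW", s, "A")
  expect_false(un$mapped)
  expect_equal(nrow(un$atoms[[1]]), 0)
  err <- expect_error(map_peptide_to_structure("GAG", s, "A"),
                      class = "lipsite_error_ambiguous_match")
  expect_match(conditionMessage(err), "2, 4")
  expect_error(map_peptide_to_structure("AAA", s, "B"),
               class = "lipsite_error_chain")
})

test_that("I/L equivalence is opt-in", {
  s <- toy_structure("MKTAYLAKQR")
  expect_false(map_peptide_to_structure("TAYIAK", s, "A")$mapped)
  expect_true(map_peptide_to_structure("TAYIAK", s, "A",
                                       il_equivalent = TRUE)$mapped)
})

test_that("mapping is idempotent", {
  s <- toy_structure("MKTAYIAKQRQISFVK")
  m1 <- map_peptide_to_structure("TAYIAK", s, "A")
  m2 <- map_peptide_to_structure("TAYIAK", s, "A")
  expect_identical(m1[, setdiff(names(m1), "atoms")],
                   m2[, setdiff(names(m2), "atoms")])
})

test_that("centre of mass matches trivial geometry", {
  a1 <- tibble::tibble(element = "C", mass = 12.011, x = 1, y = 2, z = 3)
  expect_equal(center_of_mass(a1), c(x = 1, y = 2, z = 3))
  expect_equal(center_of_mass(a1, "geometric"), c(x = 1, y = 2, z = 3))
  a2 <- tibble::tibble(element = "O", mass = 15.999,
                       x = c(0, 2), y = 0, z = 0)
  expect_equal(center_of_mass(a2), c(x = 1, y = 0, z = 0))
  expect_error(center_of_mass(a1[0, ]),
               class = "lipsite_error_empty_atoms")
})

test_that("centre of mass equals the brute-force oracle", {
  withr::with_seed(123, {
    for (rep in 1:30) {
      atoms <- random_atoms(sample(5:100, 1))
      expect_equal(center_of_mass(atoms, "mass"), com_oracle(atoms, TRUE),
                   tolerance = 1e-9)
      expect_equal(center_of_mass(atoms, "geometric"),
                   com_oracle(atoms, FALSE), tolerance = 1e-9)
    }
  })
})

test_that("centre of mass is translation- and rotation-equivariant", {
  withr::with_seed(7, {
    atoms <- random_atoms(80)
    com <- center_of_mass(atoms)
    shift <- c(11.5, -3.2, 42)
    rot <- qr.Q(qr(matrix(rnorm(9), 3)))
    moved <- atoms
    xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rot)
    moved$x <- xyz[, 1] + shift[1]
    moved$y <- xyz[, 2] + shift[2]
    moved$z <- xyz[, 3] + shift[3]
    expect_equal(unname(center_of_mass(moved)),
                 unname(as.numeric(rot %*% com) + shift),
                 tolerance = 1e-9)
  })
})

test_that("element masses agree with an independent reference", {
  # atom2mass resolves the reference mass table from the global workspace
  utils::data("elements", package = "bio3d", envir = globalenv())
  withr::defer(rm("elements", envir = globalenv()))
  ref <- bio3d::atom2mass(c("C", "N", "O", "S"))
  expect_equal(unname(lipsite:::.element_masses[c("C", "N", "O", "S")]),
               ref, tolerance = 0.01)
})

test_that("symmetric peptide placements triangulate the symmetry centre", {
  seg <- lipsite:::build_segment_atoms("ACDEFKR", "helix")
  seg$chain <- "A"
  seg$insert <- ""
  seg$mass <- unname(lipsite:::.element_masses[seg$element])
  seg0 <- lipsite:::recenter_atoms(seg, c(10, 0, 0))
  rot_z <- function(atoms, deg) {
    th <- deg * pi / 180
    out <- atoms
    out$x <- atoms$x * cos(th) - atoms$y * sin(th)
    out$y <- atoms$x * sin(th) + atoms$y * cos(th)
    out
  }
  m <- tibble::tibble(
    peptide = c("PEP1", "PEP2", "PEP3"), chain = "A", mapped = TRUE,
    start_resno = c(1, 11, 21), end_resno = c(7, 17, 27),
    n_residues = 7, unresolved = 0L,
    atoms = list(seg0, rot_z(seg0, 120), rot_z(seg0, 240)))
  # distinct resno ranges so deduplication keeps all atoms
  m$atoms[[2]]$resno <- m$atoms[[2]]$resno + 10L
  m$atoms[[3]]$resno <- m$atoms[[3]]$resno + 20L
  st <- dplyr::bind_rows(m$atoms)
  st$record <- "ATOM"
  site <- predict_binding_site(m, st, neighbor_radius = 30)
  # 3-fold symmetry about z: x and y cancel exactly; z keeps the segment's
  # mass-weighted offset (rotation about z preserves z)
  expect_equal(unname(site$com[c("x", "y")]), c(0, 0), tolerance = 1e-6)
  expect_equal(unname(site$com["z"]),
               unname(center_of_mass(seg0, "mass")["z"]),
               tolerance = 1e-9)
  expect_equal(site$n_atoms, 3 * nrow(seg0))
})

test_that("overlapping peptides pool their atoms once by default", {
  s <- toy_structure("MKTAYIAKQRQISFVKWDNPECH")
  m <- map_peptides(c("MKTAYIAK", "YIAKQRQI"), s, "A")
  site <- predict_binding_site(m, s)
  # union: residues 1-12 (YIAK shared), not 8 + 8 residues
  pooled <- dplyr::bind_rows(m$atoms)
  n_union <- nrow(unique(pooled[, c("resno", "atom_name")]))
  expect_equal(site$n_atoms, n_union)
  site_dup <- predict_binding_site(m, s, dedupe = FALSE)
  expect_gt(site_dup$n_atoms, site$n_atoms)
  # single atom degenerates to that atom's position
  one <- m[1, ]
  one$atoms[[1]] <- one$atoms[[1]][1, ]
  site1 <- predict_binding_site(one, s)
  expect_equal(unname(site1$com),
               c(one$atoms[[1]]$x, one$atoms[[1]]$y, one$atoms[[1]]$z))
  # all-unmapped input is a named error
  un <- map_peptide_to_structure("WWWWW", s, "A")
  expect_error(predict_binding_site(un, s),
               class = "lipsite_error_no_mappings")
})

test_that("nearby residues are sorted by distance within the radius", {
  s <- toy_structure("MKTAYIAKQRQISFVK")
  m <- map_peptides("TAYIAK", s, "A")
  site <- predict_binding_site(m, s, neighbor_radius = 6)
  expect_true(all(diff(site$nearby$min_dist) >= 0))
  expect_true(all(site$nearby$min_dist <= 6))
})

test_that("peptide-set overlap uses inclusive residue ranges", {
  a <- tibble::tibble(peptide = c("A1", "A2", "A3"),
                      start_resno = c(1, 30, 60),
                      end_resno = c(10, 40, 70))
  expect_equal(nrow(compare_peptide_sets(a, a)), 3)   # disjoint ranges
  b <- tibble::tibble(peptide = "B1", start_resno = 20, end_resno = 30)
  ov <- compare_peptide_sets(a, b)
  expect_equal(nrow(ov), 1)                 # 30-40 vs 20-30 share residue 30
  expect_equal(ov$n_shared, 1L)
  # planted: exactly 2 of 3 overlap
  c2 <- tibble::tibble(peptide = c("C1", "C2", "C3"),
                       start_resno = c(5, 35, 200),
                       end_resno = c(12, 44, 210))
  expect_equal(nrow(compare_peptide_sets(a, c2)), 2)
})
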