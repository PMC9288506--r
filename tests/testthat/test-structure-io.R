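pdb_line <- function(serial, name, resid, chain, resno, x, y, z,
                     element = "", alt = " ", record = "ATOM") {
  name4 <- formatC(paste0(" ", name), width = -4)
  sprintf("%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name4, alt, resid, chain, resno, " ",
          x, y, z, 1, 0, formatC(element, width = 2))
}

test_that("a minimal hand-written ATOM record parses correctly", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_line(1, "CA", "GLY", "A", 1, 1, 2, 3, "C"), "END"), tf)
  s <- read_structure(tf)
  expect_equal(nrow(s), 1)
  expect_equal(length(unique(s$chain)), 1)
  expect_equal(s$element, "C")
  expect_equal(s$resid, "GLY")
  expect_equal(c(s$x, s$y, s$z), c(1, 2, 3))
  expect_equal(s$mass, 12.011)
})

test_that("only the requested MODEL is retained", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("MODEL     1",
               pdb_line(1, "CA", "ALA", "A", 1, 1, 1, 1, "C"),
               "ENDMDL",
               "MODEL     2",
               pdb_line(1, "CA", "ALA", "A", 1, 9, 9, 9, "C"),
               "ENDMDL", "END"), tf)
  s1 <- read_structure(tf)
  expect_equal(c(s1$x, s1$y, s1$z), c(1, 1, 1))
  s2 <- read_structure(tf, model_index = 2)
  expect_equal(c(s2$x, s2$y, s2$z), c(9, 9, 9))
  expect_error(read_structure(tf, model_index = 3),
               class = "lipsite_error_pdb_parse")
})

test_that("hydrogens, altLocs and HETATM follow the default policies", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0, "C", alt = "A"),
    pdb_line(2, "CA", "ALA", "A", 1, 5, 5, 5, "C", alt = "B"),
    pdb_line(3, "HB1", "ALA", "A", 1, 1, 1, 1, "H"),
    pdb_line(4, "O", "HOH", "A", 2, 2, 2, 2, "O", record = "HETATM"),
    "END"), tf)
  s <- read_structure(tf)
  expect_equal(nrow(s), 1)           # altLoc B, hydrogen, HETATM all dropped
  expect_equal(s$atom_name, "CA")
  expect_equal(nrow(read_structure(tf, altloc_policy = "all")), 2)
  expect_equal(nrow(read_structure(tf, keep_hydrogens = TRUE)), 2)
  expect_equal(sum(read_structure(tf, include_hetatm = TRUE)$record ==
                     "HETATM"), 1)
})

test_that("element falls back to the atom-name heuristic", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_line(1, "NZ", "LYS", "A", 1, 0, 0, 0, ""),
               pdb_line(2, "ZN", "ZN", "A", 2, 1, 1, 1, ""),
               "END"), tf)
  s <- read_structure(tf)
  expect_equal(s$element, c("N", "ZN"))
})

test_that("files without ATOM records or with unknown elements error", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HEADER    EMPTY", "END"), tf)
  expect_error(read_structure(tf), class = "lipsite_error_pdb_parse")
  writeLines(c(pdb_line(1, "XX", "GLY", "A", 1, 0, 0, 0, ""), "END"), tf)
  expect_error(read_structure(tf),
               class = "lipsite_error_unknown_element")
  expect_error(read_structure("/nonexistent.pdb"),
               class = "lipsite_error_io")
})

test_that("site outputs round-trip through the PDB pseudo-atom", {
  sim <- simulate_lip_experiment(30, 3, seed = 8)
  run <- suppressMessages(run_site_prediction(
    lip_config(quant = sim$quant, structure = sim$structure)))
  prefix <- file.path(withr::local_tempdir(), "out")
  paths <- write_site_outputs(run$site, prefix)
  tab <- readr::read_tsv(paths["tsv"], show_col_types = FALSE)
  expect_equal(nrow(tab), nrow(run$site$peptides))
  expect_equal(tab$com_x[1], unname(run$site$com["x"]), tolerance = 1e-12)
  back <- read_structure(paths["pdb"], include_hetatm = TRUE)
  pseudo <- back[back$record == "HETATM", ]
  expect_equal(nrow(pseudo), 1)
  expect_true(all(abs(c(pseudo$x, pseudo$y, pseudo$z) -
                        unname(run$site$com)) <= 1e-3 + 1e-12))
})

test_that("a CoM at the origin writes zero coordinates", {
  sim <- simulate_lip_experiment(10, 1, seed = 2)
  m <- map_peptides(sim$truth$responsive$peptide, sim$structure)
  site <- predict_binding_site(m, sim$structure)
  site$com <- c(x = 0, y = 0, z = 0)
  prefix <- file.path(withr::local_tempdir(), "zero")
  paths <- write_site_outputs(site, prefix)
  pdb_lines <- readLines(paths["pdb"])
  het <- grep("^HETATM", pdb_lines, value = TRUE)
  expect_length(het, 1)
  expect_match(het, "0\\.000\\s+0\\.000\\s+0\\.000")
})
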