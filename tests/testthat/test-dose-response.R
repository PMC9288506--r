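test_that("zero-noise fits recover all four parameters to 1e-6 relative", {
  ec50_grid <- 10^seq(log10(2e-9), log10(2e-3), length.out = 5)
  for (i in seq_along(ec50_grid)) {
    sim <- simulate_lip_experiment(12, 2, ec50 = ec50_grid[i],
                                   noise_cv = 0, seed = 100 + i)
    nq <- normalize_quant(sim$quant, center = FALSE)
    tr <- sim$truth$responsive
    for (j in seq_len(nrow(tr))) {
      f <- fit_peptide(nq, tr$peptide[j])
      expect_false(f$degenerate)
      base <- log2(sim$quant$quantity[
        sim$quant$modified_sequence == tr$peptide[j] &
          sim$quant$dose == 0][1])
      expect_equal(f$bottom, base, tolerance = 1e-6)
      expect_equal(f$top, base + tr$direction[j] * 1.5, tolerance = 1e-6)
      expect_equal(f$ec50, ec50_grid[i], tolerance = 1e-6)
      expect_equal(f$slope, 1, tolerance = 1e-6)
      expect_equal(f$r_squared, 1, tolerance = 1e-10)
    }
  }
})

test_that("degenerate inputs are flagged, not thrown", {
  # constant quantities: zero total variance
  q <- tibble::tibble(
    protein_id = "P", modified_sequence = "CONSTK",
    stripped_sequence = "CONSTK",
    dose = rep(c(0, 2e-9, 2e-8, 2e-7, 2e-6, 2e-5), each = 3),
    replicate = rep(paste0("R", 1:3), 6),
    quantity = 512)
  f <- fit_peptide(normalize_quant(q, center = FALSE), "CONSTK")
  expect_true(f$degenerate)
  expect_false(f$converged)
  # too few distinct doses
  q2 <- q[q$dose %in% c(0, 2e-6, 2e-5), ]
  q2$quantity <- 2^rnorm(nrow(q2), 9)
  f2 <- fit_peptide(normalize_quant(q2, center = FALSE), "CONSTK")
  expect_true(f2$degenerate)
})

test_that("pure-noise peptides rarely reach r-squared above 0.9", {
  sim <- simulate_lip_experiment(200, 0, seed = 55)
  fits <- fit_dose_response(sim$quant)
  expect_equal(nrow(fits), 200)
  expect_lte(sum(fits$r_squared > 0.9, na.rm = TRUE), 2)  # <= 1%
})

test_that("r-squared is invariant to a constant intensity shift", {
  sim <- simulate_lip_experiment(15, 2, seed = 31)
  nq <- normalize_quant(sim$quant, center = FALSE)
  p <- sim$truth$responsive$peptide[1]
  f1 <- fit_peptide(nq, p)
  shifted <- sim$quant
  shifted$quantity <- shifted$quantity * 2^3.7
  f2 <- fit_peptide(normalize_quant(shifted, center = FALSE), p)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-8)
  expect_equal(f2$ec50, f1$ec50, tolerance = 1e-6)
})

test_that("EC50 recovery under 5% noise stays within 2-fold (median)", {
  sim <- simulate_lip_experiment(60, 50, noise_cv = 0.05, seed = 77)
  fits <- fit_dose_response(normalize_quant(sim$quant),
                            sim$truth$responsive$peptide)
  err <- abs(log10(fits$ec50 / 1e-6))
  expect_lt(median(err), log10(2))
})

test_that("ranking orders by r-squared with the EC50/sequence tie rules", {
  fits <- tibble::tibble(
    peptide = c("PEPA", "PEPB", "PEPC", "PEPD", "PEPE"),
    bottom = 0, top = 1,
    ec50 = c(1e-5, 1e-7, 1e-5, 1e-6, 1e-6),
    slope = 1,
    r_squared = c(0.95, 0.99, 0.2, 0.95, 0.95),
    n_points = 30, converged = TRUE,
    degenerate = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  r <- rank_peptides(fits)
  expect_equal(nrow(r), 4)                       # degenerate dropped
  expect_equal(r$peptide[1], "PEPB")             # highest r2 first
  # tie at 0.95: lower ec50 wins, then sequence
  expect_equal(r$peptide[2:3], c("PEPD", "PEPA"))
  expect_equal(r$above_threshold, c(TRUE, TRUE, TRUE, FALSE))
})

test_that("ranking agrees with an independent stable-sort oracle", {
  withr::with_seed(9, {
    fits <- tibble::tibble(
      peptide = sprintf("P%03d", 1:40),
      bottom = 0, top = 1,
      ec50 = 10^runif(40, -8, -3),
      slope = 1,
      r_squared = round(runif(40), 2),   # force some ties
      n_points = 30, converged = TRUE, degenerate = FALSE)
    r <- rank_peptides(fits)
    oracle <- fits[order(-fits$r_squared, fits$ec50, fits$peptide), ]
    expect_equal(r$peptide, oracle$peptide)
  })
})

test_that("top-k selection takes the k best, warning when short", {
  fits <- tibble::tibble(
    peptide = sprintf("P%02d", 1:10), bottom = 0, top = 1,
    ec50 = 1e-6, slope = 1, r_squared = seq(0.99, 0.09, by = -0.1),
    n_points = 30, converged = TRUE, degenerate = FALSE)
  r <- rank_peptides(fits)
  top <- select_top(r)                           # default k = 3
  expect_equal(nrow(top), 3)
  expect_equal(sort(top$r_squared, decreasing = TRUE),
               sort(fits$r_squared, decreasing = TRUE)[1:3])
  expect_equal(nrow(select_top(r[1:3, ], k = 3)), 3)
  expect_warning(short <- select_top(r, k = 20), "available")
  expect_equal(nrow(short), 10)
  expect_error(select_top(r, k = 0), class = "lipsite_error_bad_k")
  # candidate restriction
  top_c <- select_top(r, k = 2, candidates = c("P05", "P07", "P09"))
  expect_equal(top_c$peptide, c("P05", "P07"))
})
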