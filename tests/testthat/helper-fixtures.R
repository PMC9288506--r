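# A quant table with one focal peptide and a block of low, constant
# background peptides: the backgrounds pin the per-sample median so that
# median-centring subtracts the same constant from every sample.
make_focal_quant <- function(dose_values, vehicle_values, dose = 2e-6,
                             n_background = 9) {
  reps <- paste0("R", seq_along(dose_values))
  bg <- tidyr::expand_grid(p = sprintf("BG%02dK", seq_len(n_background)),
                           d = c(dose, 0),
                           r = reps)
  bg_level <- 2^(seq_len(n_background))   # far below the focal values
  rows <- dplyr::bind_rows(
    tibble::tibble(protein_id = "P1", modified_sequence = "FOCALK",
                   stripped_sequence = "FOCALK", dose = dose,
                   replicate = reps, quantity = dose_values),
    tibble::tibble(protein_id = "P1", modified_sequence = "FOCALK",
                   stripped_sequence = "FOCALK", dose = 0,
                   replicate = reps, quantity = vehicle_values),
    tibble::tibble(protein_id = "P1", modified_sequence = bg$p,
                   stripped_sequence = bg$p, dose = bg$d,
                   replicate = bg$r,
                   quantity = bg_level[match(bg$p,
                                             unique(bg$p))] / 1e6)
  )
  rows
}

# brute-force BH step-up oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- ps * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# brute-force per-axis weighted mean
com_oracle <- function(atoms, use_mass = TRUE) {
  sx <- sy <- sz <- sw <- 0
  for (i in seq_len(nrow(atoms))) {
    w <- if (use_mass) atoms$mass[i] else 1
    sx <- sx + w * atoms$x[i]
    sy <- sy + w * atoms$y[i]
    sz <- sz + w * atoms$z[i]
    sw <- sw + w
  }
  c(x = sx / sw, y = sy / sw, z = sz / sw)
}

random_atoms <- function(n) {
  els <- c("C", "N", "O", "S", "P", "FE", "ZN")
  el <- sample(els, n, replace = TRUE)
  tibble::tibble(
    chain = "A", resno = seq_len(n), insert = "",
    resid = "GLY", atom_name = paste0("A", seq_len(n)),
    element = el, mass = unname(lipsite:::.element_masses[el]),
    x = stats::rnorm(n, sd = 20), y = stats::rnorm(n, sd = 20),
    z = stats::rnorm(n, sd = 20))
}
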