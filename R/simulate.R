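# deterministic, roughly uniform directions on the unit sphere
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

random_tryptic_peptide <- function(min_len = 7, max_len = 14) {
  len <- sample(min_len:max_len, 1)
  body <- sample(setdiff(.standard_aa, c("K", "R")), len - 1, replace = TRUE)
  paste0(paste(body, collapse = ""), sample(c("K", "R"), 1))
}

#' Simulate a dose-resolved LiP-MS experiment with known ground truth
#'
#' Generates a peptide quantification table over a concentration series, a
#' toy protein structure whose chain contains the responsive peptides
#' clustered around a designated pocket, and the ground truth needed for
#' parameter-recovery tests.
#'
#' Non-responsive peptides have dose-independent log-normal intensities.
#' Responsive peptides follow a four-parameter log-logistic mean curve with
#' asymptote separation `effect_log2` (sign drawn per peptide: limited
#' proteolysis can raise or lower a peptide's yield) and multiplicative
#' log-normal noise of coefficient of variation `noise_cv`. In the
#' structure, each responsive peptide is built as an ideal helical segment
#' whose centroid sits `pocket_radius` Angstrom from `pocket_center`;
#' non-responsive filler segments are placed far away, so the pocket centre
#' is a geometric ground truth for site triangulation.
#'
#' @param n_peptides Total number of peptides.
#' @param n_responsive Number of dose-responsive peptides
#'   (`<= n_peptides`).
#' @param dose_series Dose series tibble, default [default_dose_series()].
#' @param ec50 True midpoint concentration (molar) of responsive peptides.
#' @param effect_log2 Asymptote separation in log2 units.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (0 gives exactly on-curve data).
#' @param n_replicates Replicates per dose (default 3).
#' @param seed Integer seed; identical arguments and seed reproduce the
#'   output bit for bit.
#' @param pocket_center 3-vector, Angstrom; default the origin.
#' @param pocket_radius Distance of each responsive segment centroid from
#'   the pocket centre (default 5 Angstrom).
#' @param n_filler Non-responsive filler segments in the structure.
#' @return A list with elements `quant` (peptide quant table), `structure`
#'   (`lip_structure`), and `truth` (list: `responsive` tibble with
#'   `peptide`, `ec50`, `direction`; `pocket_center`; `noise_cv`; `seed`;
#'   `warnings`).
#' @export
simulate_lip_experiment <- function(n_peptides, n_responsive,
                                    dose_series = default_dose_series(),
                                    ec50 = 1e-6, effect_log2 = 1.5,
                                    noise_cv = 0.05, n_replicates = 3,
                                    seed, pocket_center = c(0, 0, 0),
                                    pocket_radius = 5, n_filler = 5) {
  if (missing(seed)) {
    abort("a seed is required for reproducible simulation",
          class = "lipsite_error_sim_args")
  }
  if (n_peptides < 1 || n_responsive < 0 || n_responsive > n_peptides) {
    abort("need 1 <= n_peptides and 0 <= n_responsive <= n_peptides",
          class = "lipsite_error_sim_args")
  }
  if (noise_cv < 0) {
    abort("noise_cv must be >= 0", class = "lipsite_error_sim_args")
  }
  dose_series <- validate_dose_series(dose_series)
  conc <- dose_series$concentration
  warnings <- character()
  rng <- range(conc[conc > 0])
  if (ec50 < rng[1] * (1 - 1e-9) || ec50 > rng[2] * (1 + 1e-9)) {
    warnings <- c(warnings,
                  sprintf("ec50 %.3g M lies outside the dose range [%.3g, %.3g]",
                          ec50, rng[1], rng[2]))
    warn(warnings[length(warnings)])
  }

  withr::with_seed(seed, {
    # unique peptide sequences; responsive ones must occur exactly once in
    # the assembled chain so structure mapping is unambiguous
    peptides <- character(0)
    while (length(peptides) < n_peptides) {
      peptides <- unique(c(peptides, replicate(
        n_peptides - length(peptides) + 10, random_tryptic_peptide())))
    }
    peptides <- peptides[seq_len(n_peptides)]
    responsive <- if (n_responsive > 0) peptides[seq_len(n_responsive)]
                  else character(0)
    fillers <- replicate(n_filler, random_tryptic_peptide(10, 14))

    for (try in seq_len(100)) {
      chain_seq <- paste(c(responsive, fillers), collapse = "")
      hits <- vapply(responsive, function(p)
        length(gregexpr(p, chain_seq, fixed = TRUE)[[1]][
          gregexpr(p, chain_seq, fixed = TRUE)[[1]] > 0]), integer(1))
      if (n_responsive == 0 || all(hits == 1)) break
      k <- which(hits != 1)[1]
      responsive[k] <- random_tryptic_peptide()
      peptides[k] <- responsive[k]
    }

    direction <- if (n_responsive > 0) sample(c(1, -1), n_responsive,
                                              replace = TRUE) else integer(0)
    base <- rnorm(n_peptides, mean = 14, sd = 1.5)
    sd_log2 <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) / log(2) else 0

    grid <- tidyr::expand_grid(
      peptide = peptides,
      dose = conc,
      replicate = paste0("R", seq_len(n_replicates))
    )
    idx <- match(grid$peptide, peptides)
    mu <- base[idx]
    resp <- idx <= n_responsive
    if (any(resp)) {
      mu[resp] <- four_pl(grid$dose[resp],
                          bottom = base[idx[resp]],
                          top = base[idx[resp]] +
                            direction[idx[resp]] * effect_log2,
                          ec50 = ec50, slope = 1)
    }
    eps <- if (sd_log2 > 0) rnorm(nrow(grid), 0, sd_log2) else 0
    quant <- tibble(
      protein_id = "SIMPROT",
      modified_sequence = grid$peptide,
      stripped_sequence = grid$peptide,
      dose = grid$dose,
      replicate = grid$replicate,
      quantity = 2^(mu + eps)
    )

    # structure: responsive segments around the pocket, fillers far away
    segs <- c(responsive, fillers)
    n_seg <- length(segs)
    dirs <- fibonacci_sphere(max(n_seg, 2))
    centers <- matrix(rep(pocket_center, n_seg), n_seg, 3, byrow = TRUE)
    if (n_responsive > 0) {
      centers[seq_len(n_responsive), ] <-
        centers[seq_len(n_responsive), , drop = FALSE] +
        pocket_radius * dirs[seq_len(n_responsive), , drop = FALSE]
    }
    if (n_filler > 0) {
      far <- n_responsive + seq_len(n_filler)
      centers[far, ] <- centers[far, , drop = FALSE] +
        (60 + 10 * seq_len(n_filler)) * dirs[far, , drop = FALSE]
    }
    resno_start <- 1L
    atom_list <- vector("list", n_seg)
    for (s in seq_len(n_seg)) {
      a <- build_segment_atoms(segs[s], "helix", resno_start)
      atom_list[[s]] <- recenter_atoms(a, centers[s, ])
      resno_start <- resno_start + nchar(segs[s])
    }
    atoms <- dplyr::bind_rows(atom_list)
    atoms$chain <- "A"
    atoms$record <- "ATOM"
    atoms$insert <- ""
    atoms$mass <- unname(.element_masses[atoms$element])
    atoms <- atoms[, c("record", "chain", "resno", "insert", "resid",
                       "atom_name", "element", "mass", "x", "y", "z")]
    class(atoms) <- c("lip_structure", class(atoms))

    truth <- list(
      responsive = tibble(peptide = responsive,
                          ec50 = rep(ec50, n_responsive),
                          direction = direction),
      pocket_center = pocket_center,
      noise_cv = noise_cv,
      seed = seed,
      warnings = warnings
    )
    list(quant = quant, structure = atoms, truth = truth)
  })
}

#' Simulate an isobaric-label competition pulldown
#'
#' Emulates a reverse competition experiment: proteins enriched on
#' immobilised compound, with free compound at 8, 80 and 800 uM competing
#' true targets off the beads. One planted target shows dose-increasing
#' competition reaching `target_log2fc` at the highest dose in every
#' replicate; background proteins scatter around 0.
#'
#' @param n_proteins Number of proteins (>= 2).
#' @param target_log2fc Planted log2 fold-change of the target at the
#'   highest free-compound dose.
#' @param n_replicates Replicates (>= 2).
#' @param background_sd Standard deviation of background log2 ratios.
#' @param seed Integer seed.
#' @return List with `table` (competition tibble: `protein_id`,
#'   `replicate`, `channel`, `concentration`, `log2_ratio`,
#'   `unique_peptides`) and `truth` (list: `target`, `target_log2fc`,
#'   `seed`).
#' @export
simulate_competition_experiment <- function(n_proteins = 500,
                                            target_log2fc = 3,
                                            n_replicates = 2,
                                            background_sd = 0.3,
                                            seed) {
  if (missing(seed)) {
    abort("a seed is required for reproducible simulation",
          class = "lipsite_error_sim_args")
  }
  if (n_replicates < 2) {
    abort("n_replicates must be >= 2", class = "lipsite_error_sim_args")
  }
  if (n_proteins < 2) {
    abort("n_proteins must be >= 2", class = "lipsite_error_sim_args")
  }
  channels <- tibble(
    channel = c("vehicle", "low", "mid", "high"),
    concentration = c(0, 8e-6, 8e-5, 8e-4)
  )
  withr::with_seed(seed, {
    ids <- c("TARGET", sprintf("P%04d", seq_len(n_proteins - 1)))
    upep <- rpois(n_proteins, 8) + 1L
    upep[1] <- 25L
    tab <- tidyr::expand_grid(
      protein_id = ids,
      replicate = paste0("R", seq_len(n_replicates)),
      channel = channels$channel
    )
    tab$concentration <- channels$concentration[
      match(tab$channel, channels$channel)]
    tab$log2_ratio <- rnorm(nrow(tab), 0, background_sd)
    is_target <- tab$protein_id == "TARGET"
    frac <- c(vehicle = 0, low = 1 / 3, mid = 2 / 3, high = 1)
    tab$log2_ratio[is_target] <-
      target_log2fc * frac[tab$channel[is_target]] +
      rnorm(sum(is_target), 0, 0.05)
    tab$log2_ratio[tab$channel == "vehicle"] <- 0
    tab$unique_peptides <- upep[match(tab$protein_id, ids)]
    list(table = tab,
         truth = list(target = "TARGET", target_log2fc = target_log2fc,
                      seed = seed))
  })
}
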