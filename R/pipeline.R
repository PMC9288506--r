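#' Pipeline configuration
#'
#' Collects every tunable of the site-prediction and competition pipelines
#' with the defaults used throughout: q < 0.01 and |log2FC| > 0.46 for the
#' candidate filter, R-squared threshold 0.9, top k = 3 peptides, 8 A
#' neighbour radius, mass weighting. Inputs may be given as paths or as
#' in-memory objects (the object wins when both are set).
#'
#' @param quant,structure In-memory peptide quant table / `lip_structure`.
#' @param quant_path,structure_path Paths read with
#'   [read_peptide_report()] / [read_structure()] when the in-memory
#'   objects are absent.
#' @param competition_table In-memory competition tibble for
#'   [run_competition()].
#' @param out_prefix Optional path prefix; when set, every stage writes
#'   its TSV next to it.
#' @param column_map Column map for [read_peptide_report()].
#' @param comparison_doses,q_threshold,fc_threshold,fdr_scope,rule
#'   Differential-stage settings (see [differential_analysis()] and
#'   [filter_candidates()]).
#' @param r2_threshold,k Ranking/selection settings.
#' @param chain Chain to map onto (`NULL`: first chain containing all top
#'   peptides).
#' @param weighting,neighbor_radius,il_equivalent Site-triangulation
#'   settings.
#' @param competition_threshold Significance threshold for
#'   [rank_targets()].
#' @param seed Optional seed for any resampling.
#' @return A validated list of class `lip_config`.
#' @export
lip_config <- function(quant = NULL, quant_path = NULL,
                       structure = NULL, structure_path = NULL,
                       competition_table = NULL,
                       out_prefix = NULL,
                       column_map = default_column_map(),
                       comparison_doses = c(2e-6, 2e-5, 1e-4),
                       q_threshold = 0.01, fc_threshold = 0.46,
                       fdr_scope = "per_comparison", rule = "any",
                       r2_threshold = 0.9, k = 3, chain = NULL,
                       weighting = "mass", neighbor_radius = 8,
                       il_equivalent = FALSE,
                       competition_threshold = 2, seed = NULL) {
  if (q_threshold <= 0 || fc_threshold <= 0 || r2_threshold <= 0 ||
      neighbor_radius <= 0 || competition_threshold <= 0) {
    abort("all thresholds must be positive", class = "lipsite_error_config")
  }
  if (!is.numeric(k) || length(k) != 1 || k < 1) {
    abort("k must be a single integer >= 1", class = "lipsite_error_config")
  }
  structure(list(quant = quant, quant_path = quant_path,
                 structure = structure, structure_path = structure_path,
                 competition_table = competition_table,
                 out_prefix = out_prefix, column_map = column_map,
                 comparison_doses = comparison_doses,
                 q_threshold = q_threshold, fc_threshold = fc_threshold,
                 fdr_scope = fdr_scope, rule = rule,
                 r2_threshold = r2_threshold, k = as.integer(k),
                 chain = chain, weighting = weighting,
                 neighbor_radius = neighbor_radius,
                 il_equivalent = il_equivalent,
                 competition_threshold = competition_threshold,
                 seed = seed),
            class = "lip_config")
}

stage_log <- function(stage, ...) {
  kv <- c(...)
  message(sprintf("[%s] stage=%s %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage,
                  paste(names(kv), unname(kv), sep = "=", collapse = " ")))
}

#' Run the full site-prediction pipeline
#'
#' Executes the stages in order — differential filtering against vehicle,
#' per-candidate dose-response fitting, R-squared ranking, top-k
#' selection, structure mapping and centre-of-mass triangulation — with a
#' machine-parseable count log per stage. When `config$out_prefix` is set,
#' each stage writes its table (`_differential.tsv`, `_fits.tsv`,
#' `_site.tsv`, `_site.pdb`). Deterministic given identical inputs and
#' configuration.
#'
#' @param config A [lip_config()].
#' @return List of class `lip_site_run`: `differential`, `candidates`,
#'   `fits`, `ranking`, `top`, `mappings`, `site`.
#' @export
run_site_prediction <- function(config) {
  stopifnot(inherits(config, "lip_config"))
  quant <- config$quant
  if (is.null(quant)) {
    if (is.null(config$quant_path)) {
      abort("config needs `quant` or `quant_path`",
            class = "lipsite_error_config")
    }
    quant <- read_peptide_report(config$quant_path, config$column_map)
  }
  quant <- validate_quant_table(quant)
  structure_mod <- config$structure
  if (is.null(structure_mod)) {
    if (is.null(config$structure_path)) {
      abort("config needs `structure` or `structure_path`",
            class = "lipsite_error_config")
    }
    structure_mod <- read_structure(config$structure_path)
  }
  stage_log("read", peptides = length(unique(quant$modified_sequence)),
            rows = nrow(quant))

  diff <- differential_analysis(
    quant, comparison_doses = config$comparison_doses,
    q_threshold = config$q_threshold, fc_threshold = config$fc_threshold,
    fdr_scope = config$fdr_scope)
  if (!is.null(config$out_prefix)) {
    readr::write_tsv(diff, paste0(config$out_prefix, "_differential.tsv"),
                     progress = FALSE)
  }
  candidates <- filter_candidates(diff, config$q_threshold,
                                  config$fc_threshold, config$rule)
  stage_log("differential", tests = nrow(diff),
            candidates = length(candidates))
  if (length(candidates) == 0) {
    abort("no candidate peptides pass the differential filter",
          class = "lipsite_error_no_candidates")
  }

  fits <- fit_dose_response(quant, peptides = candidates)
  ranking <- rank_peptides(fits, config$r2_threshold)
  if (!is.null(config$out_prefix)) {
    readr::write_tsv(ranking, paste0(config$out_prefix, "_fits.tsv"),
                     progress = FALSE)
  }
  stage_log("dose_response", fits = nrow(fits),
            converged = sum(fits$converged),
            above_r2 = sum(ranking$above_threshold))

  top <- select_top(ranking, k = config$k)
  stripped <- quant$stripped_sequence[
    match(top$peptide, quant$modified_sequence)]
  mappings <- map_peptides(stripped, structure_mod, chain = config$chain,
                           il_equivalent = config$il_equivalent)
  mappings$r_squared <- top$r_squared
  mappings$ec50 <- top$ec50
  site <- predict_binding_site(mappings, structure_mod,
                               weighting = config$weighting,
                               neighbor_radius = config$neighbor_radius)
  stage_log("site", top_k = nrow(top), atoms_pooled = site$n_atoms,
            nearby = nrow(site$nearby))
  if (!is.null(config$out_prefix)) {
    write_site_outputs(site, config$out_prefix)
  }
  structure(list(differential = diff, candidates = candidates,
                 fits = fits, ranking = ranking, top = top,
                 mappings = mappings, site = site),
            class = "lip_site_run")
}

#' Run the competition-pulldown target ranking
#'
#' Median normalisation followed by high-dose target ranking, with a count
#' log and an optional `_targets.tsv` output.
#'
#' @param config A [lip_config()] with `competition_table` set.
#' @return Ranked target tibble (see [rank_targets()]).
#' @export
run_competition <- function(config) {
  stopifnot(inherits(config, "lip_config"))
  tab <- config$competition_table
  if (is.null(tab) || nrow(tab) == 0) {
    abort("config needs a non-empty `competition_table`",
          class = "lipsite_error_empty_table")
  }
  norm <- median_normalize(tab)
  ranked <- rank_targets(norm, threshold = config$competition_threshold)
  stage_log("competition", proteins = nrow(ranked),
            significant = sum(ranked$significant))
  if (!is.null(config$out_prefix)) {
    readr::write_tsv(ranked, paste0(config$out_prefix, "_targets.tsv"),
                     progress = FALSE)
  }
  ranked
}
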