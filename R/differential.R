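#' Log2 fold-change of one peptide between a dose and vehicle
#'
#' Difference of mean normalised log2 quantities (dose minus vehicle),
#' equivalent to the log2 ratio of geometric-mean intensities after
#' per-sample median-centring.
#'
#' @param quant A quant table carrying a `log2_norm` column (see
#'   [normalize_quant()]).
#' @param peptide Modified peptide sequence.
#' @param dose Comparison dose (molar).
#' @param vehicle Vehicle dose, default 0.
#' @return A single number, or `NA` when the peptide is missing at either
#'   condition (such peptides are excluded downstream).
#' @export
log2_fold_change <- function(quant, peptide, dose, vehicle = 0) {
  if (!"log2_norm" %in% names(quant)) {
    abort("run normalize_quant() first ('log2_norm' column missing)",
          class = "lipsite_error_not_normalized")
  }
  a <- quant$log2_norm[quant$modified_sequence == peptide &
                         quant$dose == dose]
  b <- quant$log2_norm[quant$modified_sequence == peptide &
                         quant$dose == vehicle]
  if (length(a) < 1 || length(b) < 1) return(NA_real_)
  mean(a) - mean(b)
}

#' Welch t-test of one peptide between a dose and vehicle
#'
#' Two-sided Welch (unequal-variance) t-test on normalised log2 quantities.
#' Degenerate groups with zero pooled variance return p = 1 when the means
#' are equal and p = 0 otherwise (a noiseless difference is maximally
#' significant).
#'
#' @inheritParams log2_fold_change
#' @return A p-value, or `NA` when either group has fewer than 2
#'   replicates.
#' @export
differential_test <- function(quant, peptide, dose, vehicle = 0) {
  if (!"log2_norm" %in% names(quant)) {
    abort("run normalize_quant() first ('log2_norm' column missing)",
          class = "lipsite_error_not_normalized")
  }
  a <- quant$log2_norm[quant$modified_sequence == peptide &
                         quant$dose == dose]
  b <- quant$log2_norm[quant$modified_sequence == peptide &
                         quant$dose == vehicle]
  welch_p(a, b)
}

welch_p <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) return(NA_real_)
  if (stats::var(a) + stats::var(b) == 0) {
    return(if (mean(a) == mean(b)) 1 else 0)
  }
  stats::t.test(a, b, var.equal = FALSE)$p.value
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjusted p-values controlling the false discovery rate;
#' order-preserving, in `[0, 1]`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (`NA` allowed and
#'   propagated).
#' @return Vector of q-values, same length and order.
#' @examples
#' adjust_fdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
adjust_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    abort("p-values must lie in [0, 1]", class = "lipsite_error_bad_p")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Differential peptide analysis against vehicle
#'
#' For every peptide and every comparison dose, computes the log2
#' fold-change and Welch p-value versus vehicle on median-centred log2
#' quantities, then Benjamini-Hochberg q-values, and flags rows passing
#' both thresholds. The default comparison doses are the three
#' concentrations above a typical compound IC50 (2, 20 and 100 uM); the
#' default thresholds are q < 0.01 and |log2FC| > 0.46.
#'
#' @param quant A peptide quant table.
#' @param comparison_doses Doses compared against vehicle (molar).
#' @param vehicle Vehicle dose, default 0.
#' @param q_threshold q-value cut-off (default 0.01).
#' @param fc_threshold absolute log2 fold-change cut-off (default 0.46).
#' @param fdr_scope `"per_comparison"` (default) adjusts p-values within
#'   each comparison dose; `"global"` adjusts across all comparisons at
#'   once.
#' @param center Median-centre per sample before testing (default `TRUE`).
#' @return Tibble with one row per (peptide, comparison dose): `peptide`,
#'   `dose`, `log2_fc`, `p_value`, `q_value`, `passes`.
#' @export
differential_analysis <- function(quant,
                                  comparison_doses = c(2e-6, 2e-5, 1e-4),
                                  vehicle = 0,
                                  q_threshold = 0.01,
                                  fc_threshold = 0.46,
                                  fdr_scope = c("per_comparison", "global"),
                                  center = TRUE) {
  fdr_scope <- match.arg(fdr_scope)
  quant <- normalize_quant(quant, center = center)
  present <- unique(quant$dose)
  missing_doses <- setdiff(comparison_doses, present)
  if (length(missing_doses)) {
    abort(paste0("comparison dose(s) absent from the table: ",
                 paste(signif(missing_doses, 3), collapse = ", ")),
          class = "lipsite_error_missing_dose")
  }
  sub <- quant[quant$dose %in% c(comparison_doses, vehicle), ]
  stats_tbl <- sub |>
    dplyr::group_by(.data$modified_sequence, .data$dose) |>
    dplyr::summarise(mean_l2 = mean(.data$log2_norm),
                     var_l2 = stats::var(.data$log2_norm),
                     n = dplyr::n(), .groups = "drop")
  veh <- stats_tbl[stats_tbl$dose == vehicle, ]
  res <- stats_tbl[stats_tbl$dose %in% comparison_doses, ]
  i <- match(res$modified_sequence, veh$modified_sequence)
  out <- tibble(
    peptide = res$modified_sequence,
    dose = res$dose,
    log2_fc = res$mean_l2 - veh$mean_l2[i]
  )
  # Welch from the sufficient statistics (same result as t.test on raw values)
  v1 <- res$var_l2 / res$n
  v2 <- veh$var_l2[i] / veh$n[i]
  tt <- out$log2_fc / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (res$n - 1) + v2^2 / (veh$n[i] - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  zerovar <- !is.na(v1) & !is.na(v2) & (v1 + v2) == 0
  p[zerovar] <- ifelse(out$log2_fc[zerovar] == 0, 1, 0)
  p[res$n < 2 | veh$n[i] < 2 | is.na(i)] <- NA_real_
  out$p_value <- p
  out <- out[order(out$dose, out$peptide), ]
  if (fdr_scope == "global") {
    out$q_value <- adjust_fdr(out$p_value)
  } else {
    out <- out |>
      dplyr::group_by(.data$dose) |>
      dplyr::mutate(q_value = adjust_fdr(.data$p_value)) |>
      dplyr::ungroup()
  }
  out$passes <- !is.na(out$q_value) &
    out$q_value < q_threshold & abs(out$log2_fc) > fc_threshold
  out
}

#' Candidate peptides from a differential result
#'
#' A peptide is a candidate when the pass rule holds over its comparisons:
#' `"any"` (default) requires at least one comparison passing both
#' thresholds, `"all"` requires every comparison to pass.
#'
#' @param results A differential tibble from [differential_analysis()].
#' @param q_threshold,fc_threshold Thresholds re-applied to the stored
#'   `q_value`/`log2_fc` columns (defaults 0.01 and 0.46).
#' @param rule `"any"` or `"all"`.
#' @return Sorted character vector of candidate peptide sequences.
#' @export
filter_candidates <- function(results, q_threshold = 0.01,
                              fc_threshold = 0.46,
                              rule = c("any", "all")) {
  rule <- match.arg(rule)
  pass <- !is.na(results$q_value) &
    results$q_value < q_threshold & abs(results$log2_fc) > fc_threshold
  agg <- tapply(pass, results$peptide, if (rule == "any") any else all)
  sort(names(agg)[agg])
}
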