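#' Median-normalise a competition table
#'
#' Keeps only proteins quantified in every (replicate, channel)
#' combination present in the table, then subtracts the per-channel,
#' per-replicate median log2 ratio across proteins, so each channel's
#' median is exactly 0. Idempotent.
#'
#' @param table Competition tibble with columns `protein_id`, `replicate`,
#'   `channel`, `concentration`, `log2_ratio` (and optionally
#'   `unique_peptides`).
#' @return The normalised tibble.
#' @export
median_normalize <- function(table) {
  combos <- dplyr::distinct(table, .data$replicate, .data$channel)
  counts <- table |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(n = dplyr::n_distinct(paste(.data$replicate,
                                                 .data$channel)),
                     .groups = "drop")
  complete <- counts$protein_id[counts$n == nrow(combos)]
  out <- table[table$protein_id %in% complete, ]
  out |>
    dplyr::group_by(.data$replicate, .data$channel) |>
    dplyr::mutate(log2_ratio = .data$log2_ratio -
                    stats::median(.data$log2_ratio)) |>
    dplyr::ungroup()
}

#' Rank candidate targets from a competition pulldown
#'
#' Orders proteins by their log2 fold-change at the highest free-compound
#' concentration, aggregated across replicates with the minimum
#' (`replicates_required = "all"`, default: every replicate must clear the
#' threshold for a significant call) or the maximum (`"any"`).
#'
#' @param table A (normalised) competition tibble.
#' @param threshold Significance threshold on the aggregated log2
#'   fold-change (default 2).
#' @param replicates_required `"all"` or `"any"`.
#' @return Tibble ordered by descending score: `rank`, `protein_id`,
#'   `log2_fc` (aggregated high-dose value), per-replicate high-dose
#'   values in `log2_fc_min`/`log2_fc_max`, `unique_peptides`,
#'   `significant`.
#' @export
rank_targets <- function(table, threshold = 2,
                         replicates_required = c("all", "any")) {
  replicates_required <- match.arg(replicates_required)
  if (nrow(table) == 0) {
    abort("competition table is empty", class = "lipsite_error_empty_table")
  }
  top_conc <- max(table$concentration)
  high <- table[table$concentration == top_conc, ]
  agg <- high |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      log2_fc_min = min(.data$log2_ratio),
      log2_fc_max = max(.data$log2_ratio),
      unique_peptides = if ("unique_peptides" %in% names(high))
        max(.data$unique_peptides) else NA_integer_,
      .groups = "drop")
  agg$log2_fc <- if (replicates_required == "all") agg$log2_fc_min else
    agg$log2_fc_max
  agg <- agg[order(-agg$log2_fc, agg$protein_id), ]
  agg$rank <- seq_len(nrow(agg))
  agg$significant <- agg$log2_fc > threshold
  agg[, c("rank", "protein_id", "log2_fc", "log2_fc_min", "log2_fc_max",
          "unique_peptides", "significant")]
}

#' Competition ranking plot
#'
#' Rank-versus-fold-change scatter in the style of a competition pulldown
#' summary: point size tracks the number of unique peptides, significant
#' targets (above the threshold in the required replicates) in red.
#'
#' @param ranked Output of [rank_targets()].
#' @param threshold Threshold line to draw (default 2).
#' @return A ggplot object.
#' @export
plot_competition <- function(ranked, threshold = 2) {
  ggplot2::ggplot(ranked,
                  ggplot2::aes(x = .data$rank, y = .data$log2_fc,
                               size = .data$unique_peptides,
                               colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::labs(x = "protein rank", y = "log2 fold-change (competed)",
                  size = "unique\npeptides")
}
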