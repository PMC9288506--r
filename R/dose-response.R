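# 4PL with log10(EC50) as the free parameter; dose 0 evaluated by the
# analytic limit so the vehicle point needs no pseudo-dose.
fpl_lec50 <- function(dose, bottom, top, lec50, slope) {
  out <- rep(bottom, length(dose))
  nz <- dose > 0
  out[nz] <- bottom + (top - bottom) /
    (1 + 10^(slope * (lec50 - log10(dose[nz]))))
  out
}

#' Fit a four-parameter dose-response curve to one peptide
#'
#' Least-squares fit of the 4PL log-logistic model to a peptide's
#' replicate-level normalised log2 quantities. The fit is parameterised in
#' log10(EC50) (bounded to two decades beyond the dose range) with a
#' positive slope; the response direction is carried by the sign of
#' top - bottom. Five multi-starts with log-spaced EC50 guesses guard
#' against local minima; the best residual sum of squares wins.
#' R-squared is computed over the replicate-level points, not dose means.
#'
#' Fits are flagged `degenerate` (and excluded from ranking) when there are
#' fewer than `min_doses` distinct doses with data, when the response has
#' zero total variance, or when no start converges; degeneracy is a flag,
#' never an exception.
#'
#' @param quant Quant table with a `log2_norm` column ([normalize_quant()]).
#' @param peptide Modified peptide sequence to fit.
#' @param min_doses Minimum distinct doses required (default 5).
#' @param weights Optional per-observation weights (default equal).
#' @return An object of class `lip_drc`: parameters `bottom`, `top`,
#'   `ec50` (molar), `slope`, plus `r_squared`, `n_points`, `converged`,
#'   `degenerate`, and the fitted data.
#' @export
fit_peptide <- function(quant, peptide, min_doses = 5, weights = NULL) {
  if (!"log2_norm" %in% names(quant)) {
    abort("run normalize_quant() first ('log2_norm' column missing)",
          class = "lipsite_error_not_normalized")
  }
  d <- quant[quant$modified_sequence == peptide, ]
  obj <- structure(list(peptide = peptide,
                        data = tibble(dose = d$dose,
                                      replicate = d$replicate,
                                      y = d$log2_norm),
                        bottom = NA_real_, top = NA_real_,
                        ec50 = NA_real_, slope = NA_real_,
                        r_squared = NA_real_, n_points = nrow(d),
                        converged = FALSE, degenerate = TRUE),
                   class = "lip_drc")
  doses <- unique(d$dose)
  if (length(doses) < min_doses || !any(doses == 0)) return(obj)
  y <- d$log2_norm
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot < 1e-12) return(obj)

  nz <- sort(doses[doses > 0])
  lo <- log10(min(nz)) - 2
  hi <- log10(max(nz)) + 2
  bottom0 <- mean(y[d$dose == 0])
  top0 <- mean(y[d$dose == max(nz)])
  if (abs(top0 - bottom0) < 1e-8) top0 <- bottom0 + 0.1
  starts <- seq(log10(min(nz)), log10(max(nz)), length.out = 5)
  w <- if (is.null(weights)) rep(1, nrow(d)) else weights

  best <- NULL
  best_ss <- Inf
  for (s0 in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        y ~ fpl_lec50(dose, bottom, top, lec50, slope),
        data = d,
        start = list(bottom = bottom0, top = top0, lec50 = s0, slope = 1),
        lower = c(-Inf, -Inf, lo, 0.05),
        upper = c(Inf, Inf, hi, 20),
        weights = w,
        control = minpack.lm::nls.lm.control(
          maxiter = 500, ftol = 1e-15, ptol = 1e-15))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      ss <- sum(stats::resid(fit)^2)
      if (ss < best_ss) {
        best_ss <- ss
        best <- fit
      }
    }
  }
  if (is.null(best)) return(obj)
  cf <- coef(best)
  obj$bottom <- unname(cf["bottom"])
  obj$top <- unname(cf["top"])
  obj$ec50 <- 10^unname(cf["lec50"])
  obj$slope <- unname(cf["slope"])
  obj$r_squared <- 1 - best_ss / ss_tot
  obj$converged <- TRUE
  obj$degenerate <- FALSE
  obj
}

#' @export
print.lip_drc <- function(x, ...) {
  cat("<lip_drc> peptide", x$peptide, "\n")
  if (x$degenerate) {
    cat("  degenerate fit (", x$n_points, "points )\n")
  } else {
    cat(sprintf("  bottom %.3f  top %.3f  EC50 %.3g M  slope %.3f\n",
                x$bottom, x$top, x$ec50, x$slope))
    cat(sprintf("  R-squared %.4f over %d points\n",
                x$r_squared, x$n_points))
  }
  invisible(x)
}

#' @rdname fit_peptide
#' @param x,object A `lip_drc` fit.
#' @param ... Unused.
#' @export
tidy.lip_drc <- function(x, ...) {
  tibble(term = c("bottom", "top", "ec50", "slope"),
         estimate = c(x$bottom, x$top, x$ec50, x$slope))
}

#' @rdname fit_peptide
#' @export
glance.lip_drc <- function(x, ...) {
  tibble(peptide = x$peptide, bottom = x$bottom, top = x$top,
         ec50 = x$ec50, slope = x$slope, r_squared = x$r_squared,
         n_points = x$n_points, converged = x$converged,
         degenerate = x$degenerate)
}

#' @rdname fit_peptide
#' @param newdata Optional data frame with a `dose` column.
#' @export
predict.lip_drc <- function(object, newdata = NULL, ...) {
  dose <- if (is.null(newdata)) object$data$dose else newdata$dose
  if (object$degenerate) return(rep(NA_real_, length(dose)))
  four_pl(dose, object$bottom, object$top, object$ec50, object$slope)
}

#' Plot a fitted dose-response curve
#'
#' Replicate-level points and the fitted 4PL curve on a log10 dose axis;
#' the vehicle is drawn two decades below the lowest non-zero dose.
#'
#' @param object A `lip_drc` fit.
#' @param ... Unused.
#' @export
autoplot.lip_drc <- function(object, ...) {
  d <- object$data
  nz <- sort(unique(d$dose[d$dose > 0]))
  veh_pos <- min(nz) / 100
  d$dose_plot <- ifelse(d$dose == 0, veh_pos, d$dose)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$dose_plot, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (M, vehicle at left edge)",
                  y = "normalised log2 intensity",
                  title = object$peptide)
  if (!object$degenerate) {
    grid <- tibble(dose = c(0, 10^seq(log10(veh_pos), log10(max(nz)),
                                      length.out = 200)))
    grid$yhat <- predict(object, grid)
    grid$dose_plot <- ifelse(grid$dose == 0, veh_pos, grid$dose)
    p <- p + ggplot2::geom_line(data = grid,
                                ggplot2::aes(y = .data$yhat),
                                colour = "firebrick") +
      ggplot2::labs(subtitle = sprintf("EC50 %.3g M, R² %.3f",
                                       object$ec50, object$r_squared))
  }
  p
}

#' Fit dose-response curves for many peptides
#'
#' Median-centres the table (once, across all peptides) unless a
#' `log2_norm` column is already present, then fits each peptide with
#' [fit_peptide()].
#'
#' @param quant A peptide quant table.
#' @param peptides Peptides to fit; default all in the table.
#' @param min_doses Passed to [fit_peptide()].
#' @param keep_fits Keep the full `lip_drc` objects in a `fit`
#'   list-column? Default `FALSE`.
#' @return Tibble with one row per peptide: `peptide`, `bottom`, `top`,
#'   `ec50`, `slope`, `r_squared`, `n_points`, `converged`, `degenerate`.
#' @export
fit_dose_response <- function(quant, peptides = NULL, min_doses = 5,
                              keep_fits = FALSE) {
  if (!"log2_norm" %in% names(quant)) quant <- normalize_quant(quant)
  if (is.null(peptides)) peptides <- unique(quant$modified_sequence)
  fits <- purrr::map(peptides, function(p)
    fit_peptide(quant, p, min_doses = min_doses))
  out <- purrr::map_dfr(fits, glance)
  if (keep_fits) out$fit <- fits
  out
}

#' Rank peptide fits by dose-response correlation
#'
#' Non-degenerate fits ordered by R-squared (descending), ties broken by
#' lower EC50 then peptide sequence. Fits below `r2_threshold` stay in the
#' ranking but are flagged.
#'
#' @param fits A fit tibble from [fit_dose_response()].
#' @param r2_threshold R-squared flagging threshold (default 0.9).
#' @return The non-degenerate rows, ordered, with `rank` and
#'   `above_threshold` columns.
#' @export
rank_peptides <- function(fits, r2_threshold = 0.9) {
  keep <- fits[!fits$degenerate, ]
  keep <- keep[order(-keep$r_squared, keep$ec50, keep$peptide), ]
  keep$rank <- seq_len(nrow(keep))
  keep$above_threshold <- keep$r_squared > r2_threshold
  keep
}

#' Select the top-ranked peptides
#'
#' @param ranking A ranked fit tibble from [rank_peptides()].
#' @param k Number of peptides to take (default 3).
#' @param candidates Optional peptide set to restrict to (e.g. from
#'   [filter_candidates()]).
#' @return The first `k` rows (fewer, with a warning, when not enough are
#'   available).
#' @export
select_top <- function(ranking, k = 3, candidates = NULL) {
  if (k < 1) {
    abort("k must be >= 1", class = "lipsite_error_bad_k")
  }
  if (nrow(ranking) == 0) {
    abort("ranking is empty", class = "lipsite_error_empty_ranking")
  }
  if (!is.null(candidates)) {
    ranking <- ranking[ranking$peptide %in% candidates, ]
  }
  if (nrow(ranking) < k) {
    warn(sprintf("only %d of the requested %d peptides available",
                 nrow(ranking), k))
  }
  head(ranking, k)
}
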