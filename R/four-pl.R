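#' Four-parameter log-logistic dose-response model
#'
#' Evaluates the 4PL (LL.4-family) curve on the log2-intensity scale:
#' \deqn{f(d) = bottom + \frac{top - bottom}{1 + (ec50/d)^{slope}}}
#' For `dose = 0` the analytic limit (with `slope > 0`) is `bottom`, so the
#' vehicle point is always usable without a pseudo-dose. The response
#' direction is carried by the sign of `top - bottom`; `slope` is a
#' Hill-type steepness and must be positive here (the fitter constrains it).
#'
#' @param dose Numeric vector of molar concentrations (0 allowed).
#' @param bottom Asymptote at zero dose (log2 intensity).
#' @param top Asymptote at infinite dose (log2 intensity).
#' @param ec50 Midpoint concentration (molar), strictly positive.
#' @param slope Positive Hill-type slope.
#' @return Numeric vector of predicted log2 intensities.
#' @examples
#' four_pl(c(0, 1e-6, 1e-5), bottom = 1, top = 2, ec50 = 1e-6, slope = 1)
#' @export
four_pl <- function(dose, bottom, top, ec50, slope) {
  if (!is.numeric(ec50) || any(ec50 <= 0)) {
    abort("ec50 must be strictly positive", class = "lipsite_error_four_pl")
  }
  if (any(dose < 0)) {
    abort("dose must be non-negative", class = "lipsite_error_four_pl")
  }
  n <- length(dose)
  bottom <- rep_len(bottom, n)
  top <- rep_len(top, n)
  ec50 <- rep_len(ec50, n)
  slope <- rep_len(slope, n)
  out <- bottom
  nz <- dose > 0
  out[nz] <- bottom[nz] + (top[nz] - bottom[nz]) /
    (1 + (ec50[nz] / dose[nz])^slope[nz])
  out
}
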