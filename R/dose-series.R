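#' Standard 10-point LiP-MS dose series
#'
#' Returns the concentration ladder used throughout the package: 7-to-10-fold
#' serial dilutions from a high of 2 mM, two intermediate concentrations
#' (1 mM and 100 uM) that stabilise curve fitting around the upper doses, and
#' a vehicle control at 0 M.
#'
#' @return A tibble with one row per dose and columns
#'   \describe{
#'     \item{label}{unique human-readable dose label, e.g. `"200uM"` or
#'       `"vehicle"`}
#'     \item{concentration}{molar concentration; 0 for the vehicle}
#'     \item{is_vehicle}{logical, exactly one `TRUE` row}
#'   }
#' @examples
#' default_dose_series()
#' @export
default_dose_series <- function() {
  ds <- tibble(
    label = c("2mM", "1mM", "200uM", "100uM", "20uM",
              "2uM", "200nM", "20nM", "2nM", "vehicle"),
    concentration = c(2e-3, 1e-3, 2e-4, 1e-4, 2e-5,
                      2e-6, 2e-7, 2e-8, 2e-9, 0)
  )
  ds$is_vehicle <- ds$concentration == 0
  validate_dose_series(ds)
}

#' Validate a dose series
#'
#' Checks the invariants every dose series must satisfy: unique labels,
#' exactly one vehicle (0 M) entry, and strictly monotone positive
#' concentrations for the non-vehicle doses.
#'
#' @param dose_series A data frame with columns `label` and `concentration`
#'   (and optionally `is_vehicle`, which is recomputed).
#' @return The validated dose series as a tibble, invisibly usable downstream.
#' @export
validate_dose_series <- function(dose_series) {
  ds <- as_tibble(dose_series)
  if (!all(c("label", "concentration") %in% names(ds))) {
    abort("dose series needs columns 'label' and 'concentration'",
          class = "lipsite_error_dose_series")
  }
  if (anyDuplicated(ds$label)) {
    abort("dose series labels must be unique",
          class = "lipsite_error_dose_series")
  }
  if (sum(ds$concentration == 0) != 1) {
    abort("dose series must contain exactly one vehicle (0 M) entry",
          class = "lipsite_error_dose_series")
  }
  conc <- ds$concentration[ds$concentration != 0]
  if (any(conc < 0)) {
    abort("non-vehicle concentrations must be strictly positive",
          class = "lipsite_error_dose_series")
  }
  d <- diff(conc)
  if (!(all(d > 0) || all(d < 0))) {
    abort("non-vehicle concentrations must be strictly monotone",
          class = "lipsite_error_dose_series")
  }
  ds$is_vehicle <- ds$concentration == 0
  ds
}

#' Parse a dose label into a molar concentration
#'
#' Understands `<number><unit>` with units M, mM, uM (or the micro sign), nM,
#' pM, and the vehicle aliases `"vehicle"`, `"dmso"`, `"control"`, `"0"`.
#'
#' @param label Character vector of dose labels.
#' @return Numeric vector of molar concentrations.
#' @examples
#' parse_dose_label(c("2mM", "100uM", "vehicle"))
#' @export
parse_dose_label <- function(label) {
  scale <- c(M = 1, mM = 1e-3, uM = 1e-6, "µM" = 1e-6,
             nM = 1e-9, pM = 1e-12)
  out <- vapply(label, function(lb) {
    s <- trimws(lb)
    if (tolower(s) %in% c("vehicle", "dmso", "control", "0")) {
      return(0)
    }
    m <- regmatches(s, regexec("^([0-9.]+)\\s*(M|mM|uM|µM|nM|pM)$", s))[[1]]
    if (length(m) != 3) {
      abort(paste0("unparseable dose label: '", lb, "'"),
            class = "lipsite_error_dose_label")
    }
    as.numeric(m[2]) * scale[[m[3]]]
  }, numeric(1), USE.NAMES = FALSE)
  out
}
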