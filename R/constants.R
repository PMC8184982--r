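#' Physical constants of the qSIP density-shift calculation
#'
#' Returns the constants used to translate DNA buoyant densities into
#' isotope excess atom fractions: the GC-content calibration of unlabeled
#' buoyant density, the mean nucleotide molecular weight as a function of
#' GC, and per-isotope maximum mass gain and natural abundance. These are
#' the published values of the 18O/13C qSIP method; all are overridable so
#' alternative calibrations can be explored.
#'
#' @param isotope `"18O"` or `"13C"`.
#' @param overrides named list replacing any of the defaults.
#'
#' @return A named list with elements `gc_slope`, `gc_intercept` (buoyant
#'   density of unlabeled DNA as a linear function of GC fraction),
#'   `mw_slope`, `mw_intercept` (mean nucleotide molecular weight vs GC),
#'   `mass_gain_max` (molecular-weight gain at 100 atom % labeling) and
#'   `natural_abundance` (atom fraction of the heavy isotope in unlabeled
#'   material).
#' @export
#' @examples
#' isotope_constants("18O")$mass_gain_max  # 12.07747
isotope_constants <- function(isotope = c("18O", "13C"), overrides = NULL) {
  isotope <- match.arg(isotope)
  cst <- list(
    gc_slope     = 0.083506,
    gc_intercept = 1.646057,
    mw_slope     = 0.496,
    mw_intercept = 307.691
  )
  if (isotope == "18O") {
    cst$mass_gain_max     <- 12.07747
    cst$natural_abundance <- 0.002000429
  } else {
    cst$mass_gain_max     <- 9.974564
    cst$natural_abundance <- 0.01111233
  }
  cst$isotope <- isotope
  if (!is.null(overrides)) {
    stopifnot(is.list(overrides), all(names(overrides) %in% names(cst)))
    cst[names(overrides)] <- overrides
  }
  cst
}

# Mean nucleotide molecular weight of unlabeled DNA given its buoyant density.
# GC fraction is recovered from the density calibration first.
.mw_light <- function(w_light, cst) {
  gc <- (w_light - cst$gc_intercept) / cst$gc_slope
  cst$mw_slope * gc + cst$mw_intercept
}

#' Days per week used when converting daily rates to weekly fluxes
#' @keywords internal
DAYS_PER_WEEK <- 7
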