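# Internal helpers and the single unit-conversion layer.
#
# Unit regime (audited end-to-end by the |k| derivation test):
#   lengths um, areas um^2, moments of area um^4, strain microstrain (ue),
#   forces N, bending moments N mm, Young's modulus GPa, time days at the
#   biology interface / seconds for waveforms, diffusivity um^2/day
#   internally (cm^2/s at the interface), concentration nmol/um^3 internally
#   (nM at the interface), stimulus flow nmol/day, MAR um/day.

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_num1 <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is_num1(x)) stopf("'%s' must be a single finite number", name)
  if (x < lower || x > upper)
    stopf("'%s' = %g outside allowed range [%g, %g]", name, x, lower, upper)
  invisible(x)
}

#' Convert a diffusivity from cm^2/s to um^2/day
#'
#' One cm^2 is 1e8 um^2 and one day is 86400 s, so the factor is 8.64e12.
#' The default calcium diffusivity 5.3e-6 cm^2/s maps to 4.5792e7 um^2/day.
#'
#' @param D_cm2_s diffusivity in cm^2/s
#' @return diffusivity in um^2/day
#' @export
#' @examples
#' diffusivity_um2_day(5.3e-6)
diffusivity_um2_day <- function(D_cm2_s) {
  check_num1(D_cm2_s, "D_cm2_s", lower = 0)
  D_cm2_s * 1e8 * 86400
}

#' Convert a concentration from nM to nmol/um^3
#'
#' 1 nM = 1e-9 mol/L = 1 nmol per 1e15 um^3, i.e. 1e-15 nmol/um^3.
#'
#' @param conc_nM concentration in nM (may be a vector)
#' @return concentration in nmol/um^3
#' @export
nM_to_nmol_um3 <- function(conc_nM) conc_nM * 1e-15
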