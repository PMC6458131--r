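# Osteoblast flux -> mineral apposition rate, the three closed-form
# calibrations of k, and the worked derivations of h, beta and |k|.
#
# MAR at the i-th osteoblast is m_i = k q_i with k a negative constant
# (q_i at a sink is negative, MAR is non-negative). Aggregate BFR/BS over
# a surface is the mean MAR of that surface's osteoblasts; BFR/BS
# (um^3/um^2/day) and mean MAR (um/day) are numerically identified.

#' MAR per osteoblast from stimulus flow rates
#'
#' @param q_nmol_day named stimulus flow rates at osteoblasts, nmol/day
#'   (non-positive for sinks)
#' @param k proportionality constant, um/nmol (negative)
#' @param surface optional per-osteoblast surface tag
#'   (`periosteal`/`endocortical`); default all periosteal
#' @return object of class `mar_result`: data.frame `mar` (id, surface,
#'   mar_um_day), per-surface `bfr_bs` and osteoblast counts `n_b`
#' @export
#' @examples
#' mar_from_flux(c(b1 = -1, b2 = -2, b3 = -3), k = -2)
mar_from_flux <- function(q_nmol_day, k, surface = NULL) {
  check_num1(k, "k")
  if (!length(q_nmol_day)) stopf("no osteoblast fluxes given")
  ids <- names(q_nmol_day) %||% paste0("ob", seq_along(q_nmol_day))
  if (is.null(surface)) surface <- rep("periosteal", length(q_nmol_day))
  m <- k * as.numeric(q_nmol_day)
  tab <- data.frame(id = ids, surface = surface, mar_um_day = m,
                    stringsAsFactors = FALSE)
  bfr <- tapply(tab$mar_um_day, tab$surface, mean)
  n_b <- tapply(tab$mar_um_day, tab$surface, length)
  structure(list(mar = tab, bfr_bs = bfr, n_b = n_b, k = k),
            class = "mar_result")
}

#' @export
print.mar_result <- function(x, ...) {
  cat(sprintf("mar_result: %d osteoblast(s)\n", nrow(x$mar)))
  for (s in names(x$bfr_bs))
    cat(sprintf("  %s BFR/BS = %.4g um^3/um^2/day over %d osteoblast(s)\n",
                s, x$bfr_bs[[s]], x$n_b[[s]]))
  invisible(x)
}

#' Calibrate the MAR proportionality constant k
#'
#' Three closed-form least-squares modes:
#' * `site_mar`: per-osteoblast observed MAR `m0_i`;
#'   `k = sum(m0_i q_i) / sum(q_i^2)`
#' * `single_avg`: one observed average `B0`; `k = B0 n_b / sum(q_i)`
#' * `multi_avg`: observed `B0_l` per protocol with matching flux sets;
#'   `k = n_b sum_l(B0_l S_l) / sum_l(S_l^2)` with `S_l = sum_i q_i^l`
#'
#' @param mode calibration mode, see above
#' @param observed numeric: `m0` vector (site_mar), scalar `B0`
#'   (single_avg), or `B0` vector (multi_avg)
#' @param q_data flux data: `q` vector (site_mar, single_avg) or list of
#'   `q` vectors (multi_avg), nmol/day
#' @param n_b osteoblast count for the averaged surface; defaults to the
#'   flux vector length
#' @return object of class `calibration_result`: `k` (signed, um/nmol),
#'   `k_magnitude`, `objective`, `residuals`, `mode`
#' @export
calibrate_k <- function(mode = c("site_mar", "single_avg", "multi_avg"),
                        observed, q_data, n_b = NULL) {
  mode <- match.arg(mode)
  if (mode == "site_mar") {
    m0 <- as.numeric(observed); q <- as.numeric(q_data)
    if (length(m0) != length(q)) stopf("observed MAR and flux lengths differ")
    if (all(q == 0)) stopf("all fluxes zero: k undefined")
    k <- sum(m0 * q) / sum(q^2)
    res <- m0 - k * q
  } else if (mode == "single_avg") {
    B0 <- check_num1(as.numeric(observed)[1], "B0")
    q <- as.numeric(q_data)
    n_b <- n_b %||% length(q)
    if (sum(q) == 0) stopf("fluxes sum to zero: k undefined")
    k <- B0 * n_b / sum(q)
    res <- B0 - k * sum(q) / n_b
  } else {
    B0 <- as.numeric(observed)
    if (!is.list(q_data)) stopf("multi_avg needs a list of flux vectors")
    if (length(B0) != length(q_data)) stopf("one B0 per protocol required")
    n_b <- n_b %||% length(q_data[[1]])
    S <- vapply(q_data, sum, 0)
    if (all(S == 0)) stopf("all flux sums zero: k undefined")
    k <- n_b * sum(B0 * S) / sum(S^2)
    res <- B0 - k * S / n_b
  }
  structure(list(k = k, k_magnitude = abs(k), objective = sum(res^2),
                 residuals = res, mode = mode),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration_result (%s): k = %.6g um/nmol (|k| = %.6g), objective %.3g\n",
              x$mode, x$k, x$k_magnitude, x$objective))
  invisible(x)
}

#' Stimulus gain h from a single-pulse calcium-spike experiment
#'
#' A single load pulse raising the matrix strain to `applied_strain_ue`
#' produces a cytosolic calcium spike of `fold_increase` times the
#' `baseline_nM` concentration; with xi ~ 1 for rest-inserted single-pulse
#' loading, `h = spike / (applied - threshold)`.
#'
#' @param baseline_nM baseline cytosolic concentration, nM
#' @param fold_increase spike amplitude as a multiple of baseline
#' @param applied_strain_ue applied matrix strain, ue (must exceed threshold)
#' @param eps_thres_ue formation threshold strain, ue
#' @return list with `spike_nM` and `h_nM_per_ue`
#' @export
#' @examples
#' worked_h(50, 1.7, 1546, 856.126)  # h ~ 0.123 nM/ue
worked_h <- function(baseline_nM, fold_increase, applied_strain_ue,
                     eps_thres_ue) {
  check_num1(baseline_nM, "baseline_nM", lower = 0)
  check_num1(fold_increase, "fold_increase", lower = 0)
  check_num1(applied_strain_ue, "applied_strain_ue", lower = 0)
  check_num1(eps_thres_ue, "eps_thres_ue", lower = 0)
  if (applied_strain_ue <= eps_thres_ue)
    stopf("applied strain (%g ue) must exceed the threshold (%g ue)",
          applied_strain_ue, eps_thres_ue)
  spike <- fold_increase * baseline_nM
  list(spike_nM = spike,
       h_nM_per_ue = spike / (applied_strain_ue - eps_thres_ue))
}

#' Days-per-week exponent from two lumped calibration constants
#'
#' Two calibrations of the lump `k h D A0 d^beta` at different d share the
#' same `k h D A0`, so `beta = log(lump_b/lump_a) / log(d_b/d_a)`.
#'
#' @param lump_a,lump_b lumped constants (um^2/day/ue), same sign
#' @param d_a,d_b the corresponding days-per-week values (distinct)
#' @return beta, dimensionless
#' @export
#' @examples
#' derive_beta(-1.8563e-3, 3, -2.7527e-3, 7)  # ~0.465
derive_beta <- function(lump_a, d_a, lump_b, d_b) {
  check_num1(lump_a, "lump_a"); check_num1(lump_b, "lump_b")
  check_num1(d_a, "d_a", lower = .Machine$double.xmin)
  check_num1(d_b, "d_b", lower = .Machine$double.xmin)
  if (d_a == d_b) stopf("d_a and d_b must differ")
  if (sign(lump_a) != sign(lump_b) || lump_a == 0 || lump_b == 0)
    stopf("lumped constants must be nonzero and share a sign")
  log(lump_b / lump_a) / log(d_b / d_a)
}

#' Magnitude of k from a lumped constant and the physical constants
#'
#' `|k| = |lump / d^beta| / (h D A0)` with the documented unit regime:
#' D converted cm^2/s -> um^2/day and h converted nM/ue -> nmol/um^3/ue,
#' yielding k in um/nmol. This derivation audits the package's entire
#' unit-conversion layer.
#'
#' @param lump_with_d lumped constant `k h D A0 d^beta`, um^2/day/ue
#' @param d days per week used in that calibration
#' @param beta days exponent
#' @param h_nM_per_ue stimulus gain, nM/ue
#' @param D_cm2_s diffusivity, cm^2/s
#' @param A0_um2 process cross-sectional area, um^2
#' @return |k| in um/nmol
#' @export
#' @examples
#' derive_k_value(-2.7527e-3, 7, 0.465, 0.123, 5.3e-6, 0.025)  # ~7.91e6
derive_k_value <- function(lump_with_d, d, beta, h_nM_per_ue, D_cm2_s,
                           A0_um2) {
  check_num1(lump_with_d, "lump_with_d")
  check_num1(d, "d", lower = .Machine$double.xmin)
  check_num1(beta, "beta")
  check_num1(h_nM_per_ue, "h_nM_per_ue", lower = .Machine$double.xmin)
  check_num1(A0_um2, "A0_um2", lower = .Machine$double.xmin)
  denom <- nM_to_nmol_um3(h_nM_per_ue) * diffusivity_um2_day(D_cm2_s) * A0_um2
  if (denom == 0) stopf("zero denominator: h, D and A0 must all be positive")
  abs(lump_with_d / d^beta) / denom
}
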