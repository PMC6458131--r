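# The explicit average bone-formation-rate law, its calibration, and its
# algebraic inversions.
#
# B = p (eps_peak - eps_thres) * xi * N^q * d^beta   for eps_peak >= eps_thres
#   = 0 otherwise,
# with xi = delta_eps_max/eps_peak the viscoelastic oscillation ratio of the
# protocol's waveform (a function of the characteristic time r = 2 pi eta/E).
# When all protocols share the same d, p and beta are not separately
# identifiable and the lump p*d^beta is fitted instead.

#' Mechanostat model parameters
#'
#' Either give `p` (um/day/ue) together with `beta`, or the lump
#' `p_d_beta = p * d^beta` (valid only for protocols sharing the
#' calibration's days-per-week d).
#'
#' @param q dimensionless cycle-count exponent (0 < q < 1 expected; values
#'   outside are kept but flagged with a warning)
#' @param eps_thres strain threshold for formation, ue
#' @param r_s viscoelastic characteristic time 2 pi eta / E, seconds
#' @param p surface- and loading-mode-specific gain, um/day/ue
#' @param beta days-per-week exponent
#' @param p_d_beta lumped gain p * d^beta, um/day/ue
#' @param h stimulus gain, nM/ue (site-specific chain)
#' @param D_cm2_s stimulus diffusivity, cm^2/s
#' @param A0_um2 osteocyte process cross-sectional area, um^2
#' @param k MAR-per-flux constant, um/nmol, negative (site-specific chain)
#' @return object of class `model_parameters`
#' @export
#' @examples
#' model_parameters(q = 0.404736, eps_thres = 856.126, r_s = 0.436235,
#'                  p_d_beta = 1.06859e-4)
model_parameters <- function(q, eps_thres, r_s = 0, p = NULL, beta = NULL,
                             p_d_beta = NULL, h = NULL, D_cm2_s = 5.3e-6,
                             A0_um2 = 0.025, k = NULL) {
  check_num1(q, "q")
  check_num1(eps_thres, "eps_thres", lower = 0)
  check_num1(r_s, "r_s", lower = 0)
  if (is.null(p) && is.null(p_d_beta))
    stopf("give one of 'p' (with 'beta') or 'p_d_beta'")
  if (!is.null(p)) {
    check_num1(p, "p", lower = 0)
    if (is.null(beta)) stopf("'beta' required when 'p' is given")
    check_num1(beta, "beta")
  }
  if (!is.null(p_d_beta)) check_num1(p_d_beta, "p_d_beta", lower = 0)
  if (q <= 0 || q >= 1)
    warnf("q = %g outside the expected open interval (0, 1)", q)
  structure(list(p = p, q = q, beta = beta, p_d_beta = p_d_beta,
                 eps_thres = eps_thres, r_s = r_s, h = h,
                 D_cm2_s = D_cm2_s, A0_um2 = A0_um2, k = k),
            class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  gain <- if (!is.null(x$p_d_beta)) sprintf("p.d^beta = %.6g", x$p_d_beta)
          else sprintf("p = %.6g, beta = %.6g", x$p, x$beta)
  cat(sprintf("model_parameters: %s um/day/ue, q = %.6g, eps_thres = %.6g ue, r = %.6g s\n",
              gain, x$q, x$eps_thres, x$r_s))
  invisible(x)
}

# gain * d^beta in force for a protocol: lump if present, else p*d^beta
effective_gain <- function(params, d) {
  if (!is.null(params$p_d_beta)) params$p_d_beta else params$p * d^params$beta
}

#' A periodic loading protocol
#'
#' @param label identifier string
#' @param waveform a [make_waveform()] object
#' @param peak_strain_ue peak strain at the section's critical point, ue
#'   (the measured/viscoelastic peak)
#' @param N cycles per loading bout (one bout per loading day)
#' @param d loading days per week, 1..7
#' @param weeks optional protocol duration, weeks
#' @return object of class `loading_protocol`
#' @export
loading_protocol <- function(label, waveform, peak_strain_ue, N, d, weeks = NULL) {
  if (!inherits(waveform, "unit_waveform")) stopf("'waveform' must be a unit_waveform")
  check_num1(peak_strain_ue, "peak_strain_ue", lower = 0)
  check_num1(N, "N", lower = 1)
  check_num1(d, "d", lower = 1, upper = 7)
  structure(list(label = as.character(label), waveform = waveform,
                 peak_strain_ue = peak_strain_ue, N = N, d = d, weeks = weeks),
            class = "loading_protocol")
}

#' Forward average-BFR prediction
#'
#' @param params [model_parameters()]
#' @param protocol [loading_protocol()]
#' @param xi oscillation ratio for the protocol's waveform at `params$r_s`;
#'   computed internally when omitted
#' @return predicted BFR/BS, um^3/um^2/day (exactly 0 below threshold)
#' @export
#' @examples
#' pars <- model_parameters(q = 0.404736, eps_thres = 856.126,
#'                          r_s = 0.436235, p_d_beta = 1.06859e-4)
#' wf <- make_waveform("trapezoid",
#'                     list(rise_s = 0.1, hold_s = 0.8, fall_s = 0.1),
#'                     rest_s = 10)
#' bfr_forward(pars, loading_protocol("P6", wf, 1600, 50, 3))
bfr_forward <- function(params, protocol, xi = NULL) {
  if (!inherits(params, "model_parameters")) stopf("'params' must be model_parameters")
  if (!inherits(protocol, "loading_protocol")) stopf("'protocol' must be a loading_protocol")
  if (is.null(xi)) xi <- protocol_xi(protocol$waveform, params$r_s)$xi
  eps <- protocol$peak_strain_ue
  if (eps < params$eps_thres) return(0)
  effective_gain(params, protocol$d) * (eps - params$eps_thres) * xi *
    protocol$N^params$q
}

#' Calibrate the average-BFR model to observed formation rates
#'
#' Levenberg-Marquardt minimization of `sum((B0_l - B_l)^2)` over the free
#' parameters, with multi-start (the objective is non-convex in r and
#' eps_thres). Each residual evaluation recomputes every protocol's xi at
#' the current r, since xi depends on the fitted viscosity.
#'
#' Free parameters default to the lump parameterization
#' `c("p_d_beta", "q", "r_s", "eps_thres")`. Fitting `p` and `beta`
#' separately requires variation in d across protocols. Bounds:
#' p, p_d_beta >= 0; q, beta in [0, 2]; r in [0, 10] s; eps_thres in
#' [0, min osteogenic peak strain].
#'
#' @param protocols list of [loading_protocol()] objects
#' @param observations data.frame with columns `label`, `B0`
#'   (um^3/um^2/day) and optionally `se`, `n`
#' @param free character vector of free parameter names
#' @param fixed named list of fixed parameter values (e.g. `list(beta = 0)`)
#' @param n_starts number of dispersed optimizer starts
#' @param seed seed for start dispersion
#' @param max_iter LM iteration cap per start
#' @return object of class `bfr_fit`: `params` ([model_parameters()]),
#'   `residuals`, `objective`, `converged`, `predicted`, `flags`
#' @export
fit_average_model <- function(protocols, observations,
                              free = c("p_d_beta", "q", "r_s", "eps_thres"),
                              fixed = list(), n_starts = 5L, seed = 101L,
                              max_iter = 200L) {
  if (!length(protocols) || !all(vapply(protocols, inherits, TRUE, "loading_protocol")))
    stopf("'protocols' must be a non-empty list of loading_protocol objects")
  if (!is.data.frame(observations) || !all(c("label", "B0") %in% names(observations)))
    stopf("'observations' needs columns 'label' and 'B0'")
  labs <- vapply(protocols, `[[`, "", "label")
  idx <- match(observations$label, labs)
  if (anyNA(idx)) stopf("observation label(s) %s match no protocol",
                        paste(observations$label[is.na(idx)], collapse = ", "))
  prot <- protocols[idx]
  B0 <- observations$B0
  if (any(B0 < 0)) stopf("observed B0 must be >= 0")

  all_names <- c("p", "p_d_beta", "q", "beta", "r_s", "eps_thres")
  if (!all(free %in% all_names)) stopf("unknown free parameter name")
  if (all(c("p", "p_d_beta") %in% free)) stopf("'p' and 'p_d_beta' cannot both be free")
  d_vals <- vapply(prot, `[[`, 0, "d")
  if (all(c("p", "beta") %in% free) && length(unique(d_vals)) == 1L)
    stopf("d is constant (%g) across protocols: p and beta are not jointly identifiable; fit 'p_d_beta' instead",
          d_vals[1])
  if (length(B0) < length(free))
    stopf("need at least as many observations (%d) as free parameters (%d)",
          length(B0), length(free))

  flags <- character(0)
  if (all(B0 == 0)) {
    # degenerate: the zero model fits exactly and the threshold is free
    flags <- c(flags, "all observations zero: p set to 0, eps_thres unidentifiable")
    lump <- "p_d_beta" %in% free || !is.null(fixed$p_d_beta)
    params <- if (lump)
      model_parameters(q = fixed$q %||% 0.5, eps_thres = fixed$eps_thres %||% 0,
                       r_s = fixed$r_s %||% 0, p_d_beta = 0)
    else
      model_parameters(q = fixed$q %||% 0.5, eps_thres = fixed$eps_thres %||% 0,
                       r_s = fixed$r_s %||% 0, p = 0, beta = fixed$beta %||% 0)
    return(structure(list(params = params, residuals = rep(0, length(B0)),
                          objective = 0, converged = TRUE,
                          predicted = rep(0, length(B0)), flags = flags,
                          free = free),
                     class = "bfr_fit"))
  }

  eps_osteo <- vapply(prot[B0 > 0], `[[`, 0, "peak_strain_ue")
  thres_max <- min(eps_osteo)
  bound_tbl <- list(p = c(0, Inf), p_d_beta = c(0, Inf), q = c(0, 2),
                    beta = c(0, 2), r_s = c(0, 10), eps_thres = c(0, thres_max))
  lower <- vapply(free, function(nm) bound_tbl[[nm]][1], 0)
  upper <- vapply(free, function(nm) bound_tbl[[nm]][2], 0)

  build_params <- function(theta) {
    v <- as.list(theta); names(v) <- free
    get <- function(nm, def = NULL) v[[nm]] %||% fixed[[nm]] %||% def
    model_parameters(q = get("q"), eps_thres = get("eps_thres"),
                     r_s = get("r_s", 0), p = get("p"), beta = get("beta"),
                     p_d_beta = get("p_d_beta"))
  }

  predict_all <- function(params) {
    vapply(prot, function(pr) {
      xi <- protocol_xi(pr$waveform, params$r_s)$xi
      bfr_forward(params, pr, xi)
    }, 0)
  }
  resid_fn <- function(theta) {
    params <- suppressWarnings(build_params(theta))
    B0 - predict_all(params)
  }

  # dispersed starts: one heuristic + seeded uniform draws inside the box
  gain_guess <- max(B0) / max((max(eps_osteo) - 0.7 * thres_max), 1) /
    max(vapply(prot, `[[`, 0, "N"))^0.5
  heuristic <- vapply(free, function(nm) switch(nm,
    p = gain_guess, p_d_beta = gain_guess, q = 0.5, beta = 0.5,
    r_s = 0.2, eps_thres = 0.7 * thres_max), 0)
  starts <- list(heuristic)
  if (n_starts > 1L) {
    set.seed(seed)
    for (s in seq_len(n_starts - 1L)) {
      starts[[s + 1L]] <- vapply(seq_along(free), function(i) {
        nm <- free[i]
        if (nm %in% c("p", "p_d_beta"))
          gain_guess * 10^stats::runif(1, -1, 1)
        else stats::runif(1, lower[i] + 0.02 * (upper[i] - lower[i]),
                          upper[i] - 0.02 * (upper[i] - lower[i]))
      }, 0)
    }
  }

  fit <- multi_start_lm(resid_fn, starts, lower = lower, upper = upper,
                        max_iter = max_iter)
  params <- suppressWarnings(build_params(fit$par))
  if (!fit$converged) flags <- c(flags, "optimizer did not report convergence")
  if (params$q <= 0 || params$q >= 1)
    flags <- c(flags, sprintf("fitted q = %g outside (0, 1)", params$q))

  structure(list(params = params, residuals = fit$residuals,
                 objective = fit$objective, converged = fit$converged,
                 predicted = predict_all(params), flags = flags,
                 free = free, iterations = fit$iterations,
                 start_objectives = fit$start_objectives,
                 objective_trace = fit$objective_trace),
            class = "bfr_fit")
}

#' @export
print.bfr_fit <- function(x, ...) {
  cat("Average-BFR model fit\n")
  print(x$params)
  cat(sprintf("  objective %.6g over %d observation(s); converged: %s\n",
              x$objective, length(x$residuals), x$converged))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Peak strain required for a target average BFR
#'
#' Closed-form inversion `eps_peak = eps_thres + B / (p xi N^q d^beta)`.
#'
#' @param B_target target BFR/BS, um^3/um^2/day (>= 0)
#' @param params [model_parameters()]
#' @param N cycles per bout
#' @param d days per week
#' @param xi oscillation ratio of the intended waveform
#' @return required peak strain, ue
#' @export
invert_peak_strain <- function(B_target, params, N, d, xi) {
  check_num1(B_target, "B_target", lower = 0)
  check_num1(N, "N", lower = 1); check_num1(d, "d", lower = 1, upper = 7)
  check_num1(xi, "xi", lower = 0)
  if (B_target == 0) return(params$eps_thres)
  denom <- effective_gain(params, d) * xi * N^params$q
  if (denom <= 0)
    stopf("infeasible: p * xi * N^q * d^beta = 0 but B_target > 0")
  params$eps_thres + B_target / denom
}

#' Cycle count required for a target average BFR
#'
#' `N = [B / (p (eps_peak - eps_thres) xi d^beta)]^(1/q)`; returned both as
#' a real number and rounded up to the next whole cycle.
#'
#' @param B_target target BFR/BS (>= 0)
#' @param params [model_parameters()]
#' @param eps_peak peak strain, ue; must exceed the threshold
#' @param d days per week
#' @param xi oscillation ratio
#' @return list with `N` (real) and `N_ceiling` (integer)
#' @export
invert_cycles <- function(B_target, params, eps_peak, d, xi) {
  check_num1(B_target, "B_target", lower = 0)
  check_num1(eps_peak, "eps_peak")
  check_num1(d, "d", lower = 1, upper = 7); check_num1(xi, "xi", lower = 0)
  if (params$q == 0) stopf("q = 0: cycle count cannot be inverted")
  if (B_target == 0) return(list(N = 0, N_ceiling = 0L))
  if (eps_peak <= params$eps_thres)
    stopf("eps_peak must exceed eps_thres for a positive target BFR")
  denom <- effective_gain(params, d) * (eps_peak - params$eps_thres) * xi
  if (denom <= 0) stopf("infeasible: zero gain but B_target > 0")
  N <- (B_target / denom)^(1 / params$q)
  list(N = N, N_ceiling = as.integer(ceiling(N - 1e-9)))
}
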