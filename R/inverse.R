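# Forward site-specific MAR from sectional loads, and the inverse problem:
# recover (Fz0, Mx0, My0) producing a prescribed MAR pattern.
#
# Forward chain: beam-theory elastic strain amplitude at each osteocyte ->
# viscoelastic peak (elastic amplitude times the unit-waveform gain) ->
# stimulus s_i -> steady-state diffusion -> m_i = k q_i. The inverse
# minimizes lambda (B0 - B)^2 + sum_j (m0_j - m_j)^2 over the three load
# amplitudes with Levenberg-Marquardt and multi-start; the unit waveform,
# N and d stay prescribed.

#' Site-specific MAR prediction from sectional loads
#'
#' @param loads a [section_loads()] object
#' @param waveform a [make_waveform()] object
#' @param N cycles per bout
#' @param d days per week
#' @param params [model_parameters()] with `h` set (and `r_s`, `eps_thres`,
#'   `q`; `beta` defaults to 0 when absent so d^beta = 1)
#' @param k MAR constant, um/nmol (negative)
#' @param network a [cell_network()]
#' @param section a [section_properties()] object
#' @param E_GPa Young's modulus, GPa
#' @param K optional precomputed conductance matrix (performance; must
#'   match `network` and `params$D_cm2_s`)
#' @param smooth_ue optional softplus threshold smoothing, ue (see
#'   [osteocyte_stimulus()]); 0 = the model's hard hinge
#' @return a `mar_result` with extra fields `eps_peak_ue` (per osteocyte),
#'   `xi`, `gain`, `B_periosteal`
#' @export
forward_mar <- function(loads, waveform, N, d, params, k, network, section,
                        E_GPa = 20, K = NULL, smooth_ue = 0) {
  if (!inherits(params, "model_parameters")) stopf("'params' must be model_parameters")
  if (is.null(params$h)) stopf("params$h (stimulus gain) is required")
  check_num1(k, "k")
  vr <- protocol_xi(waveform, params$r_s, E_GPa)
  beta <- params$beta %||% 0

  cells <- network$cells
  oc <- cells$kind == "osteocyte"
  eps_el <- strain_amplitude_at(loads, section,
                                cbind(cells$x_um[oc], cells$y_um[oc]), E_GPa)
  eps_peak <- abs(eps_el) * vr$gain
  s <- osteocyte_stimulus(eps_peak, cells$kind[oc], params$h,
                          params$eps_thres, vr$xi, N, params$q, d, beta,
                          smooth_ue = smooth_ue)
  names(s) <- cells$id[oc]

  if (is.null(K))
    K <- assemble_stiffness(network, diffusivity_um2_day(params$D_cm2_s))
  full <- stats::setNames(rep(0, nrow(cells)), cells$id)
  full[names(s)] <- s
  sol <- solve_fluxes(K, full, network)

  ob <- cells$kind == "osteoblast"
  res <- mar_from_flux(sol$q_osteoblast_nmol_day, k, cells$surface[ob])
  res$eps_peak_ue <- stats::setNames(eps_peak, cells$id[oc])
  res$xi <- vr$xi
  res$gain <- vr$gain
  res$B_periosteal <- if ("periosteal" %in% names(res$bfr_bs))
    res$bfr_bs[["periosteal"]] else 0
  res$fluxes <- sol
  res
}

#' Specify an inverse loading problem
#'
#' At least three constraints (prescribed MARs plus an optional overall
#' BFR target) are required for the three load unknowns. `lambda` defaults
#' to 0 when `B0` is absent and to `n_p * mean(m0)^2 / B0^2` otherwise so
#' the two terms carry comparable weight.
#'
#' @param prescriptions data.frame with columns `id` (osteoblast id) and
#'   `mar0_um_day` (prescribed MAR, um/day)
#' @param waveform,N,d the prescribed loading regimen
#' @param params,k,network,section forward-chain ingredients as in
#'   [forward_mar()]
#' @param B0 optional target periosteal BFR/BS, um^3/um^2/day
#' @param lambda optional weight on the BFR term
#' @param initial_guess optional [section_loads()] starting point; default
#'   puts the extreme periosteal fiber at 1.5 x eps_thres under pure Mx
#'   bending
#' @param E_GPa Young's modulus, GPa
#' @return object of class `inverse_problem`
#' @export
inverse_problem <- function(prescriptions, waveform, N, d, params, k,
                            network, section, B0 = NULL, lambda = NULL,
                            initial_guess = NULL, E_GPa = 20) {
  if (!is.data.frame(prescriptions) ||
      !all(c("id", "mar0_um_day") %in% names(prescriptions)))
    stopf("'prescriptions' needs columns id, mar0_um_day")
  ob_ids <- network$cells$id[network$cells$kind == "osteoblast"]
  bad <- setdiff(as.character(prescriptions$id), ob_ids)
  if (length(bad)) stopf("prescribed id(s) not osteoblasts: %s",
                         paste(bad, collapse = ", "))
  n_con <- nrow(prescriptions) + !is.null(B0)
  if (n_con < 3L)
    stopf("underdetermined: %d constraint(s) for 3 load unknowns; prescribe at least 3 of B0 and MAR values",
          n_con)
  if (is.null(B0)) {
    lambda <- 0
  } else if (is.null(lambda)) {
    lambda <- if (B0 > 0)
      nrow(prescriptions) * max(mean(prescriptions$mar0_um_day), 1e-12)^2 / B0^2
    else 1
  }
  check_num1(lambda, "lambda", lower = 0)

  if (is.null(initial_guess)) {
    peri <- section$periosteal_um
    per_unit <- strain_amplitude_at(section_loads(Mx0_Nmm = 1), section,
                                    peri, E_GPa)
    mx <- 1.5 * params$eps_thres / max(abs(per_unit))
    initial_guess <- section_loads(Mx0_Nmm = mx)
  }

  structure(list(prescriptions = prescriptions, B0 = B0, lambda = lambda,
                 waveform = waveform, N = N, d = d, params = params, k = k,
                 network = network, section = section,
                 initial_guess = initial_guess, E_GPa = E_GPa),
            class = "inverse_problem")
}

#' Recover sectional loads for a prescribed MAR pattern
#'
#' Levenberg-Marquardt on the residual vector
#' `[sqrt(lambda) (B0 - B), m0_j - m_j]` over (Fz0, Mx0, My0), run from
#' `n_starts` seeded perturbations of the initial guess (sign flips on the
#' moments included: the threshold in the stimulus law makes the objective
#' piecewise-smooth and multi-modal).
#'
#' Because the osteocyte stimulus depends on the strain magnitude, a load
#' set and its global negation produce identical MAR maps; solutions are
#' therefore unique only up to an overall sign, and which of the pair is
#' returned depends on the initial guess.
#'
#' @param problem an [inverse_problem()]
#' @param n_starts number of optimizer starts
#' @param seed seed for start generation
#' @param max_iter LM iteration cap per start
#' @param smooth_ue optional softplus threshold smoothing (ue) applied
#'   during optimization only; the hinge makes the objective
#'   piecewise-smooth and an iterate with every osteocyte sub-threshold
#'   sees a zero gradient. The reported solution is always evaluated with
#'   the exact hinge.
#' @return object of class `inverse_solution`: `loads`, `residual`
#'   (objective value), `converged`, `iterations`, `mar` (forward MAR at
#'   the solution), `peak_tensile_ue`, `peak_compressive_ue`,
#'   `neutral_axis_deg`, `objective_trace`
#' @export
solve_inverse <- function(problem, n_starts = 8L, seed = 42L,
                          max_iter = 200L, smooth_ue = 0) {
  if (!inherits(problem, "inverse_problem")) stopf("'problem' must be an inverse_problem")
  p <- problem
  K <- assemble_stiffness(p$network, diffusivity_um2_day(p$params$D_cm2_s))
  ids <- as.character(p$prescriptions$id)
  m0 <- p$prescriptions$mar0_um_day

  fwd <- function(theta, smooth = 0) {
    forward_mar(section_loads(theta[1], theta[2], theta[3]), p$waveform,
                p$N, p$d, p$params, p$k, p$network, p$section, p$E_GPa,
                K = K, smooth_ue = smooth)
  }
  resid_fn <- function(theta) {
    res <- fwd(theta, smooth = smooth_ue)
    m <- res$mar$mar_um_day[match(ids, res$mar$id)]
    out <- m0 - m
    if (!is.null(p$B0))
      out <- c(sqrt(p$lambda) * (p$B0 - res$B_periosteal), out)
    out
  }

  g0 <- c(p$initial_guess$Fz0_N, p$initial_guess$Mx0_Nmm, p$initial_guess$My0_Nmm)
  scale <- max(abs(g0), 1e-3)
  set.seed(seed)
  starts <- list(g0)
  if (n_starts > 1L) {
    for (s in seq_len(n_starts - 1L)) {
      jitter <- stats::runif(3, 0.3, 1.7) * sample(c(-1, 1), 3, replace = TRUE)
      starts[[s + 1L]] <- g0 * jitter + stats::rnorm(3, 0, 0.05 * scale)
    }
  }

  fit <- multi_start_lm(resid_fn, starts, max_iter = max_iter)
  loads <- section_loads(fit$par[1], fit$par[2], fit$par[3])
  mar <- fwd(fit$par)
  peri <- p$section$periosteal_um
  eps_b <- strain_amplitude_at(loads, p$section, peri, p$E_GPa) * mar$gain
  na_deg <- if (loads$Mx0_Nmm != 0 || loads$My0_Nmm != 0)
    neutral_axis_angle(loads$Mx0_Nmm, loads$My0_Nmm) else NA_real_

  structure(list(loads = loads, residual = fit$objective,
                 converged = fit$converged, iterations = fit$iterations,
                 mar = mar, peak_tensile_ue = max(eps_b, 0),
                 peak_compressive_ue = min(eps_b, 0),
                 neutral_axis_deg = na_deg,
                 objective_trace = fit$objective_trace,
                 start_objectives = fit$start_objectives),
            class = "inverse_solution")
}

#' @export
print.inverse_solution <- function(x, ...) {
  cat(sprintf("inverse_solution: Fz0 = %.4g N, Mx0 = %.4g N mm, My0 = %.4g N mm\n",
              x$loads$Fz0_N, x$loads$Mx0_Nmm, x$loads$My0_Nmm))
  cat(sprintf("  residual %.3g (converged: %s, %d iterations)\n",
              x$residual, x$converged, x$iterations))
  cat(sprintf("  section peak strains: %+.4g / %+.4g ue; neutral axis %.3g deg\n",
              x$peak_tensile_ue, x$peak_compressive_ue, x$neutral_axis_deg))
  invisible(x)
}
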