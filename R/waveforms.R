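# Unit loading waveforms and the Kelvin-Voigt viscoelastic strain response.
#
# A loading bout is N cycles of a unit-amplitude waveform u(t); optional
# rest of rest_s seconds is inserted after every n_group cycles, so the
# periodic repeat unit lasts n_group*period_s + rest_s seconds. Bone is
# treated as a Kelvin-Voigt solid (spring E and dashpot eta in parallel,
# sigma = E*eps + eta*deps/dt), a macroscopic surrogate for interstitial
# fluid-flow damping. Loading is force/stress controlled; strain is the
# response, and the metrics eps_peak, delta_eps_max and
# xi = delta_eps_max/eps_peak are read off one steady-state repeat unit.

#' Construct a unit loading waveform
#'
#' All kinds have unit amplitude: `max |u(t)| = 1` over one period.
#'
#' Supported kinds and their `shape_params`:
#' * `trapezoid`: `rise_s`, `hold_s`, `fall_s` (ramp up, hold at 1, ramp down)
#' * `haversine`: `frequency_hz`; u(t) = sin^2(pi t / period)
#' * `triangle`: `frequency_hz`; symmetric 0-1-0 ramp
#' * `rect_pulse`: `duration_s`; u = 1 for the whole duration
#' * `sine`: `frequency_hz`; zero-mean sin(2 pi f t) (fully reversed loading)
#'
#' @param kind waveform kind, see above
#' @param shape_params named list of kind-specific timings (seconds / Hz)
#' @param rest_s rest inserted after every `n_group` cycles, seconds >= 0
#' @param n_group cycles between rests (default 1)
#' @return an object of class `unit_waveform`
#' @export
#' @examples
#' wf <- make_waveform("trapezoid",
#'                     list(rise_s = 0.1, hold_s = 0.8, fall_s = 0.1),
#'                     rest_s = 10)
#' wf$period_s  # 1 s cycle, 11 s repeat unit
make_waveform <- function(kind = c("trapezoid", "haversine", "triangle",
                                   "rect_pulse", "sine"),
                          shape_params = list(), rest_s = 0, n_group = 1L) {
  kind <- match.arg(kind)
  check_num1(rest_s, "rest_s", lower = 0)
  check_num1(n_group, "n_group", lower = 1)
  n_group <- as.integer(n_group)
  sp <- shape_params

  need <- function(nm) {
    v <- sp[[nm]]
    if (is.null(v)) stopf("waveform kind '%s' requires shape_params$%s", kind, nm)
    check_num1(v, nm, lower = .Machine$double.xmin)
    v
  }

  if (kind == "trapezoid") {
    rise <- need("rise_s"); hold <- need("hold_s"); fall <- need("fall_s")
    period <- rise + hold + fall
    ufun <- function(t) {
      ifelse(t < rise, t / rise,
             ifelse(t < rise + hold, 1, pmax(0, (period - t) / fall)))
    }
  } else if (kind == "haversine") {
    f <- need("frequency_hz")
    period <- 1 / f
    ufun <- function(t) sin(pi * t / period)^2
  } else if (kind == "triangle") {
    f <- need("frequency_hz")
    period <- 1 / f
    ufun <- function(t) 1 - abs(2 * t / period - 1)
  } else if (kind == "rect_pulse") {
    dur <- need("duration_s")
    period <- dur
    ufun <- function(t) rep(1, length(t))
  } else { # sine, zero-mean
    f <- need("frequency_hz")
    period <- 1 / f
    ufun <- function(t) sin(2 * pi * t / period)
  }
  if (period <= 0) stopf("waveform period must be positive")

  structure(list(kind = kind, period_s = period, rest_s = rest_s,
                 n_group = n_group, shape_params = sp, u = ufun),
            class = "unit_waveform")
}

#' @export
print.unit_waveform <- function(x, ...) {
  cat(sprintf("unit_waveform: %s, period %.4g s, rest %.4g s after every %d cycle(s)\n",
              x$kind, x$period_s, x$rest_s, x$n_group))
  invisible(x)
}

# Duration of one periodic repeat unit (n_group cycles + trailing rest).
repeat_unit_s <- function(wf) wf$n_group * wf$period_s + wf$rest_s

# Sample grid of u(t) over one repeat unit: u_mid (midpoint values, the
# integrator forcing) and u_end (step-end values, where the integrator
# reports the state; exact for the elastic limit).
waveform_grid <- function(wf, dt) {
  T_unit <- repeat_unit_s(wf)
  n <- max(2L, ceiling(T_unit / dt))
  dt <- T_unit / n
  t_mid <- (seq_len(n) - 0.5) * dt
  t_end <- seq_len(n) * dt
  u_at <- function(t, strict) {
    u <- numeric(length(t))
    loading <- if (strict) t < wf$n_group * wf$period_s
               else t <= wf$n_group * wf$period_s
    u[loading] <- wf$u(t[loading] %% wf$period_s)
    u
  }
  list(t_mid = t_mid, t_end = t_end, u_mid = u_at(t_mid, FALSE),
       u_end = u_at(t_end, TRUE), dt = dt, T_unit = T_unit)
}

# Stable identity string for memoization keys.
waveform_signature <- function(wf) {
  paste(wf$kind, signif(wf$period_s, 12), signif(wf$rest_s, 12), wf$n_group,
        paste(names(wf$shape_params), collapse = ","),
        paste(signif(unlist(wf$shape_params), 12), collapse = ","),
        sep = "|")
}

#' Kelvin-Voigt material constants
#'
#' @param E_GPa Young's modulus, GPa (bone: 20 GPa)
#' @param eta_GPa_s effective viscosity, GPa s; alternatively give `r_s`
#' @param r_s characteristic time r = 2 pi eta / E, seconds
#' @return object of class `viscoelastic_material` with fields `E_GPa`,
#'   `eta_GPa_s` and `r_s`
#' @export
#' @examples
#' viscoelastic_material(20, r_s = 0.436235)
viscoelastic_material <- function(E_GPa = 20, eta_GPa_s = NULL, r_s = NULL) {
  check_num1(E_GPa, "E_GPa", lower = .Machine$double.xmin)
  if (is.null(eta_GPa_s) && is.null(r_s))
    stopf("give one of 'eta_GPa_s' or 'r_s'")
  if (!is.null(eta_GPa_s) && !is.null(r_s))
    stopf("give only one of 'eta_GPa_s' or 'r_s'")
  if (is.null(eta_GPa_s)) {
    check_num1(r_s, "r_s", lower = 0)
    eta_GPa_s <- r_s * E_GPa / (2 * pi)
  } else {
    check_num1(eta_GPa_s, "eta_GPa_s", lower = 0)
  }
  structure(list(E_GPa = E_GPa, eta_GPa_s = eta_GPa_s,
                 r_s = 2 * pi * eta_GPa_s / E_GPa),
            class = "viscoelastic_material")
}

#' Periodic steady-state Kelvin-Voigt strain response
#'
#' Integrates `eta deps/dt + E eps = sigma(t)` with `sigma(t)/E` scaled so a
#' purely elastic response would peak at `elastic_strain_amplitude_ue`
#' microstrain, using an exponential one-step integrator on a midpoint
#' sample grid. The repeat unit (cycles + rest) is integrated repeatedly
#' until the per-unit relative drift of the peak strain falls below `tol`
#' (cap `max_units` units); metrics are taken from the final unit only.
#' For `eta = 0` the exact elastic response `eps = sigma/E` is returned.
#'
#' @param waveform a [make_waveform()] object
#' @param material a [viscoelastic_material()]
#' @param elastic_strain_amplitude_ue nominal elastic peak strain, ue;
#'   alternatively give `stress_amplitude_MPa` (converted via E)
#' @param stress_amplitude_MPa optional stress amplitude, MPa
#' @param dt integration step, s; default `period_s/1000`, must be
#'   at most `period_s/200`
#' @param tol relative steady-state tolerance on the unit peak strain
#' @param max_units cap on integrated repeat units
#' @return object of class `strain_response`: `time_s`, `strain_ue` (one
#'   steady-state repeat unit), `eps_peak_ue`, `delta_eps_max_ue`, `xi`,
#'   `gain` (viscoelastic peak / elastic amplitude), `units_integrated`
#' @export
#' @examples
#' wf <- make_waveform("trapezoid",
#'                     list(rise_s = 0.1, hold_s = 0.8, fall_s = 0.1))
#' m <- viscoelastic_material(20, r_s = 0.436235)
#' resp <- kelvin_voigt_response(wf, m, 1000)
#' resp$xi  # < 1: back-to-back loading never lets strain relax to zero
kelvin_voigt_response <- function(waveform, material,
                                  elastic_strain_amplitude_ue = 1000,
                                  stress_amplitude_MPa = NULL,
                                  dt = NULL, tol = 1e-6, max_units = 200L) {
  if (!inherits(waveform, "unit_waveform")) stopf("'waveform' must be a unit_waveform")
  if (!inherits(material, "viscoelastic_material"))
    stopf("'material' must be a viscoelastic_material")
  if (!is.null(stress_amplitude_MPa)) {
    check_num1(stress_amplitude_MPa, "stress_amplitude_MPa")
    # strain = sigma/E; MPa / GPa = 1e-3 strain = 1000 ue
    elastic_strain_amplitude_ue <- stress_amplitude_MPa / material$E_GPa * 1000
  }
  check_num1(elastic_strain_amplitude_ue, "elastic_strain_amplitude_ue")
  scale <- elastic_strain_amplitude_ue

  if (is.null(dt)) dt <- waveform$period_s / 1000
  check_num1(dt, "dt", lower = .Machine$double.xmin)
  if (dt > waveform$period_s / 200)
    stopf("dt = %g s too coarse; need dt <= period/200 = %g s",
          dt, waveform$period_s / 200)

  grid <- waveform_grid(waveform, dt)
  forcing <- scale * grid$u_mid

  if (material$eta_GPa_s == 0) {
    eps <- scale * grid$u_end
    units <- 1L
  } else {
    tau <- material$eta_GPa_s / material$E_GPa   # seconds
    a <- exp(-grid$dt / tau)
    # exact one-step update for forcing linear within each step:
    # u(s) = u_mid + m (s - dt/2) gives
    # b = (1-a) u_mid + m [dt - (tau + dt/2)(1-a)]
    u0 <- if (waveform$n_group * waveform$period_s > 0) waveform$u(0) else 0
    u_start <- c(u0, grid$u_end[-length(grid$u_end)])
    m_slope <- (grid$u_end - u_start) / grid$dt
    b <- (1 - a) * forcing +
      scale * m_slope * (grid$dt - (tau + grid$dt / 2) * (1 - a))
    eps0 <- 0
    peak_prev <- NA_real_
    units <- 0L
    repeat {
      units <- units + 1L
      eps <- as.numeric(stats::filter(b, a, method = "recursive", init = eps0))
      peak <- max(abs(eps))
      if (units >= 2L && is.finite(peak_prev) &&
          abs(peak - peak_prev) <= tol * max(peak, 1e-300)) break
      if (units >= max_units)
        stopf("no periodic steady state within %d repeat units (drift tol %g)",
              max_units, tol)
      peak_prev <- peak
      eps0 <- eps[length(eps)]
    }
  }

  m <- strain_metrics(eps)
  structure(list(time_s = grid$t_end, strain_ue = eps,
                 eps_peak_ue = m$eps_peak, delta_eps_max_ue = m$delta_eps_max,
                 xi = m$xi, gain = m$eps_peak / abs(scale),
                 units_integrated = units,
                 waveform = waveform, material = material),
            class = "strain_response")
}

#' @export
print.strain_response <- function(x, ...) {
  cat(sprintf("strain_response: eps_peak %.4g ue, delta_eps_max %.4g ue, xi %.4g (%d unit(s))\n",
              x$eps_peak_ue, x$delta_eps_max_ue, x$xi, x$units_integrated))
  invisible(x)
}

#' Strain oscillation metrics over one steady-state repeat unit
#'
#' `eps_peak = max |eps|`, `delta_eps_max` = global max minus global min of
#' the trace, `xi = delta_eps_max/eps_peak` (0, flagged degenerate, for an
#' all-zero trace).
#'
#' @param response a `strain_response` or a numeric strain trace (ue)
#' @return list with `eps_peak`, `delta_eps_max`, `xi`, `degenerate`
#' @export
strain_metrics <- function(response) {
  eps <- if (inherits(response, "strain_response")) response$strain_ue
         else as.numeric(response)
  if (length(eps) < 1L || !all(is.finite(eps))) stopf("invalid strain trace")
  eps_peak <- max(abs(eps))
  delta <- max(eps) - min(eps)
  degenerate <- eps_peak == 0
  xi <- if (degenerate) 0 else delta / eps_peak
  list(eps_peak = eps_peak, delta_eps_max = delta, xi = xi,
       degenerate = degenerate)
}

# xi and viscoelastic gain for a waveform at characteristic time r (s),
# memoized: the calibration re-evaluates this inside every residual.
.xi_cache <- new.env(parent = emptyenv())

protocol_xi <- function(waveform, r_s, E_GPa = 20) {
  key <- paste(waveform_signature(waveform), signif(r_s, 12), E_GPa, sep = "@")
  hit <- .xi_cache[[key]]
  if (!is.null(hit)) return(hit)
  mat <- viscoelastic_material(E_GPa, r_s = r_s)
  resp <- kelvin_voigt_response(waveform, mat, 1000)
  out <- list(xi = resp$xi, gain = resp$gain)
  assign(key, out, envir = .xi_cache)
  out
}

#' Export a strain trace as a two-column CSV
#'
#' Writes `time_s, strain_ue` for one steady-state repeat unit.
#'
#' @param response a `strain_response`
#' @param path output CSV path
#' @return the path, invisibly
#' @export
write_strain_csv <- function(response, path) {
  if (!inherits(response, "strain_response")) stopf("not a strain_response")
  utils::write.csv(data.frame(time_s = response$time_s,
                              strain_ue = response$strain_ue),
                   path, row.names = FALSE)
  invisible(path)
}
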