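# Damped Gauss-Newton (Levenberg-Marquardt) nonlinear least squares.
#
# Both the average-model calibration and the sectional-load inversion
# minimize a sum of squared residuals with a handful of parameters; the
# classic Marquardt-scaled trust step with a numeric forward-difference
# Jacobian is sufficient and keeps the package dependency-free. Box
# constraints are handled by projecting trial iterates, which is the same
# pragmatic scheme widely used for small calibration problems.

num_jacobian <- function(fn, par, r0, typ) {
  n <- length(par)
  m <- length(r0)
  J <- matrix(0, m, n)
  h <- sqrt(.Machine$double.eps) * pmax(abs(par), typ)
  for (i in seq_len(n)) {
    pi_ <- par
    pi_[i] <- pi_[i] + h[i]
    J[, i] <- (fn(pi_) - r0) / h[i]
  }
  J
}

#' Levenberg-Marquardt least squares with box projection
#'
#' Minimizes `sum(fn(par)^2)` over `par`. Intended for the small (3-5
#' parameter) calibration and inverse problems in this package.
#'
#' @param fn function mapping a parameter vector to a residual vector
#' @param start numeric start vector
#' @param lower,upper optional box bounds (recycled to `length(start)`)
#' @param max_iter iteration cap
#' @param ftol relative objective-decrease tolerance for convergence
#' @param ptol relative step-size tolerance for convergence
#' @param lambda0 initial Marquardt damping
#' @return list with `par`, `residuals`, `objective`, `iterations`,
#'   `converged`, and `objective_trace` (objective after each accepted step;
#'   nonincreasing by construction)
#' @export
lm_least_squares <- function(fn, start, lower = NULL, upper = NULL,
                             max_iter = 200L, ftol = 1e-12, ptol = 1e-10,
                             lambda0 = 1e-3) {
  n <- length(start)
  lower <- if (is.null(lower)) rep(-Inf, n) else rep_len(lower, n)
  upper <- if (is.null(upper)) rep(Inf, n) else rep_len(upper, n)
  if (any(lower > upper)) stopf("lower bound exceeds upper bound")
  clamp <- function(p) pmin(pmax(p, lower), upper)

  par <- clamp(start)
  r <- fn(par)
  if (!all(is.finite(r))) stopf("residuals not finite at the start point")
  obj <- sum(r^2)
  typ <- pmax(abs(par), 1e-6)
  lambda <- lambda0
  trace <- obj
  converged <- FALSE
  it <- 0L

  while (it < max_iter) {
    it <- it + 1L
    J <- num_jacobian(fn, par, r, typ)
    g <- drop(crossprod(J, r))
    A <- crossprod(J)
    dA <- pmax(diag(A), 1e-30)
    accepted <- FALSE
    for (inner in 1:30) {
      M <- A + lambda * diag(dA, n)
      delta <- tryCatch(solve(M, -g), error = function(e) NULL)
      if (is.null(delta) || !all(is.finite(delta))) {
        lambda <- lambda * 10
        next
      }
      trial <- clamp(par + delta)
      rt <- fn(trial)
      objt <- if (all(is.finite(rt))) sum(rt^2) else Inf
      if (objt < obj) {
        accepted <- TRUE
        step_rel <- max(abs(trial - par) / pmax(abs(par), typ))
        drop_rel <- (obj - objt) / max(obj, 1e-300)
        par <- trial
        r <- rt
        obj <- objt
        trace <- c(trace, obj)
        lambda <- max(lambda / 3, 1e-12)
        if (drop_rel < ftol || step_rel < ptol || obj < 1e-300)
          converged <- TRUE
        break
      }
      lambda <- lambda * 5
    }
    if (!accepted) {
      # no downhill step found at any damping: at a (possibly constrained)
      # stationary point
      converged <- max(abs(g)) < 1e-8 * max(1, obj)
      break
    }
    if (converged) break
  }

  list(par = par, residuals = r, objective = obj, iterations = it,
       converged = converged, objective_trace = trace)
}

# Run lm_least_squares from several starts, keep the best objective.
multi_start_lm <- function(fn, starts, ...) {
  best <- NULL
  all_obj <- numeric(0)
  for (s in starts) {
    fit <- tryCatch(lm_least_squares(fn, s, ...), error = function(e) NULL)
    if (is.null(fit)) next
    all_obj <- c(all_obj, fit$objective)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) stopf("all optimizer starts failed")
  best$start_objectives <- all_obj
  best
}
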