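# The explicit average-BFR law, its calibration and its inversions.

test_that("forward law reproduces the published-constant arithmetic and the threshold", {
  pars <- truth_params()
  wf <- trapezoid_wf(10)
  # direct arithmetic oracle at xi = 1
  B <- bfr_forward(pars, loading_protocol("P6", wf, 1600, 50, 3), xi = 1)
  expect_equal(B, 1.06859e-4 * (1600 - 856.126) * 50^0.404736, tolerance = 1e-12)
  # sub-threshold and boundary are exactly zero
  expect_identical(bfr_forward(pars, loading_protocol("sub", wf, 855.126, 50, 3), xi = 1), 0)
  expect_identical(bfr_forward(pars, loading_protocol("eq", wf, 856.126, 50, 3), xi = 1), 0)
})

test_that("B is monotone in strain, cycles and days with diminishing cycle returns", {
  pars <- model_parameters(q = 0.4, eps_thres = 856.126, r_s = 0, p = 2e-4,
                           beta = 0.465)
  wf <- trapezoid_wf(10)
  B_of <- function(eps, N, d) bfr_forward(pars, loading_protocol("x", wf, eps, N, d), xi = 1)
  eps_grid <- seq(700, 2000, by = 100)
  expect_true(all(diff(vapply(eps_grid, B_of, 0, N = 50, d = 3)) >= 0))
  N_grid <- c(1, 5, 10, 50, 250, 1000)
  expect_true(all(diff(vapply(N_grid, function(N) B_of(1600, N, 3), 0)) > 0))
  expect_true(all(diff(vapply(1:7, function(d) B_of(1600, 50, d), 0)) > 0))
  # B(2N)/B(N) = 2^q < 2
  expect_equal(B_of(1600, 100, 3) / B_of(1600, 50, 3), 2^0.4, tolerance = 1e-12)
})

test_that("noiseless calibration recovers the generating parameters within 1%", {
  prot <- calibration_protocols()
  truth <- truth_params()
  obs <- make_observations(truth, prot, noise_sd = 0)
  fit <- fit_average_model(prot, obs)
  expect_true(fit$converged)
  expect_equal(fit$params$p_d_beta, truth$p_d_beta, tolerance = 1e-2)
  expect_equal(fit$params$q, truth$q, tolerance = 1e-2)
  expect_equal(fit$params$r_s, truth$r_s, tolerance = 1e-2)
  expect_equal(fit$params$eps_thres, truth$eps_thres, tolerance = 1e-2)
})

test_that("refitting from the recovered optimum is idempotent", {
  prot <- calibration_protocols()
  truth <- truth_params()
  obs <- make_observations(truth, prot, noise_sd = 0.02, seed = 3)
  fit1 <- fit_average_model(prot, obs, n_starts = 3)
  # restart from the optimum only
  refit <- lm_least_squares(function(th) {
    p <- model_parameters(q = th[2], eps_thres = th[4], r_s = th[3],
                          p_d_beta = th[1])
    obs$B0 - vapply(prot, function(pr) bfr_forward(p, pr), 0)
  }, c(fit1$params$p_d_beta, fit1$params$q, fit1$params$r_s,
       fit1$params$eps_thres),
  lower = c(0, 0, 0, 0), upper = c(Inf, 2, 10, 1000))
  expect_equal(refit$objective, fit1$objective, tolerance = 1e-6)
})

test_that("calibration guards identifiability and degenerate data", {
  prot <- calibration_protocols()
  obs <- make_observations(truth_params(), prot, 0)
  expect_error(fit_average_model(prot, obs, free = c("p", "q", "beta", "r_s", "eps_thres")),
               "identifiable")
  zero_obs <- obs
  zero_obs$B0 <- 0
  fit0 <- fit_average_model(prot, zero_obs)
  expect_true(any(grepl("unidentifiable", fit0$flags)))
  expect_equal(fit0$predicted, rep(0, nrow(obs)))
})

test_that("duplicating all protocols and observations leaves the optimum unchanged", {
  prot <- calibration_protocols()
  obs <- make_observations(truth_params(), prot, noise_sd = 0.02, seed = 9)
  fit1 <- fit_average_model(prot, obs, n_starts = 3)
  obs2 <- rbind(obs, obs)
  fit2 <- fit_average_model(prot, obs2, n_starts = 3)
  expect_equal(fit2$params$q, fit1$params$q, tolerance = 1e-4)
  expect_equal(fit2$params$p_d_beta, fit1$params$p_d_beta, tolerance = 1e-3)
  expect_equal(fit2$objective, 2 * fit1$objective, tolerance = 1e-4)
})

test_that("peak-strain inversion is the exact algebraic inverse", {
  pars <- truth_params()
  expect_identical(invert_peak_strain(0, pars, 50, 3, 1), pars$eps_thres)
  for (eps in c(900, 1250, 1600, 2400)) {
    for (N in c(10, 50, 250)) {
      B <- bfr_forward(pars, loading_protocol("x", trapezoid_wf(10), eps, N, 3), xi = 1)
      expect_equal(invert_peak_strain(B, pars, N, 3, 1), eps, tolerance = 1e-10)
    }
  }
  # linearity of the excess over threshold
  e1 <- invert_peak_strain(0.2, pars, 50, 3, 1) - pars$eps_thres
  e2 <- invert_peak_strain(0.4, pars, 50, 3, 1) - pars$eps_thres
  expect_equal(e2, 2 * e1, tolerance = 1e-12)
  # infeasible: zero gain with positive target
  zero <- model_parameters(q = 0.4, eps_thres = 800, r_s = 0, p_d_beta = 0)
  expect_error(invert_peak_strain(0.1, zero, 50, 3, 1), "infeasible")
})

test_that("cycle-count inversion round-trips and handles edge cases", {
  pars <- truth_params()
  B <- bfr_forward(pars, loading_protocol("x", trapezoid_wf(10), 1600, 50, 3), xi = 1)
  inv <- invert_cycles(B, pars, 1600, 3, 1)
  expect_equal(inv$N, 50, tolerance = 1e-10)
  expect_equal(inv$N_ceiling, 50L)
  expect_equal(invert_cycles(0, pars, 1600, 3, 1)$N, 0)
  expect_error(invert_cycles(0.1, pars, 800, 3, 1), "exceed")
  lin <- suppressWarnings(model_parameters(q = 1, eps_thres = 800, r_s = 0,
                                           p_d_beta = 1e-4))
  expect_equal(invert_cycles(0.2, lin, 1800, 3, 1)$N,
               2 * invert_cycles(0.1, lin, 1800, 3, 1)$N)
  q0 <- suppressWarnings(model_parameters(q = 0, eps_thres = 800, r_s = 0,
                                          p_d_beta = 1e-4))
  expect_error(invert_cycles(0.1, q0, 1800, 3, 1), "q = 0")
})
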