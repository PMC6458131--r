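# Stimulus, conductance assembly and the steady-state diffusion solve.

two_cell_net <- function(L = 100) {
  cell_network(
    data.frame(id = c("oc1", "ob1"), kind = c("osteocyte", "osteoblast"),
               x_um = c(0, L), y_um = 0,
               surface = c(NA, "periosteal")),
    data.frame(id_a = "oc1", id_b = "ob1"))
}

test_that("stimulus follows the hinge law and zeroes non-osteocytes", {
  s <- osteocyte_stimulus(c(846.126, 856.126, 1546, 1546),
                          c("osteocyte", "osteocyte", "osteocyte", "osteoblast"),
                          h = 0.123, eps_thres = 856.126, xi = 1, N = 1,
                          q_exp = 0.404736, d = 1, beta = 0.465)
  expect_equal(s[1], 0)
  expect_equal(s[2], 0)
  expect_equal(s[3], 0.123 * (1546 - 856.126))   # ~84.85 nM
  expect_equal(s[3], 84.85, tolerance = 1e-4)
  expect_equal(s[4], 0)
  # softplus smoothing approaches the hinge away from the kink
  ss <- osteocyte_stimulus(1546, "osteocyte", 0.123, 856.126, 1, 1,
                          0.404736, 1, 0.465, smooth_ue = 1)
  expect_equal(ss, s[3], tolerance = 1e-8)
})

test_that("assembly reproduces the two-node element and zero row sums", {
  net <- two_cell_net(L = 50)
  D <- diffusivity_um2_day(5.3e-6)
  K <- assemble_stiffness(net, D)
  c_ <- D * 0.025 / 50
  expect_equal(as.matrix(K), matrix(c(c_, -c_, -c_, c_), 2,
                                    dimnames = list(c("oc1", "ob1"),
                                                    c("oc1", "ob1"))))
  # any network: rows sum to zero
  rn <- random_junction_network(40, seed = 4)
  netr <- suppressWarnings(cell_network(rn$cells, rn$edges))
  Kr <- assemble_stiffness(netr, D)
  expect_lt(max(abs(Matrix::rowSums(Kr))), 1e-9 * max(abs(Kr)))
})

test_that("two conductances in series condense through a free junction", {
  cells <- data.frame(id = c("oc1", "j1", "ob1"),
                      kind = c("osteocyte", "junction", "osteoblast"),
                      x_um = c(0, 60, 160), y_um = 0,
                      surface = c(NA, NA, "periosteal"))
  edges <- data.frame(id_a = c("oc1", "j1"), id_b = c("j1", "ob1"))
  net <- cell_network(cells, edges)
  D <- diffusivity_um2_day(5.3e-6)
  sol <- network_fluxes(net, c(oc1 = 40), 5.3e-6)
  c1 <- D * 0.025 / 60; c2 <- D * 0.025 / 100
  c_series <- c1 * c2 / (c1 + c2)
  expect_equal(unname(sol$q_osteoblast_nmol_day),
               -c_series * nM_to_nmol_um3(40), tolerance = 1e-12)
  expect_equal(unname(sol$Q_nmol_day["j1"]), 0, tolerance = 1e-20)
})

test_that("single edge, zero stimulus and sign/conservation invariants hold", {
  net <- two_cell_net(L = 100)
  D <- diffusivity_um2_day(5.3e-6)
  sol <- network_fluxes(net, c(oc1 = 85), 5.3e-6)
  c_ <- D * 0.025 / 100
  expect_equal(unname(sol$q_osteoblast_nmol_day), -c_ * nM_to_nmol_um3(85))
  expect_equal(unname(sol$Q_nmol_day["oc1"]), c_ * nM_to_nmol_um3(85))

  z <- network_fluxes(net, c(oc1 = 0), 5.3e-6)
  expect_equal(unname(z$Q_nmol_day), c(0, 0))

  rn <- random_junction_network(60, seed = 21)
  netr <- suppressWarnings(cell_network(rn$cells, rn$edges))
  solr <- network_fluxes(netr, rn$s_nM, 5.3e-6)
  expect_lt(abs(solr$conservation), 1e-10 * max(abs(solr$Q_nmol_day)))
  expect_true(all(solr$q_osteoblast_nmol_day <= 1e-20))
})

test_that("random junction networks match the dense brute-force oracle", {
  D <- diffusivity_um2_day(5.3e-6)
  for (seed in 1:10) {
    rn <- random_junction_network(sample(10:80, 1), seed = seed)
    net <- suppressWarnings(cell_network(rn$cells, rn$edges))
    got <- network_fluxes(net, rn$s_nM, 5.3e-6)$Q_nmol_day
    want <- oracle_fluxes(net$cells, net$edges, rn$s_nM[net$cells$id], D)
    expect_equal(unname(got), unname(want), tolerance = 1e-10)
  }
})

test_that("fluxes are proportional to h and D and superpose in the stimulus", {
  rn <- random_junction_network(50, seed = 31)
  net <- suppressWarnings(cell_network(rn$cells, rn$edges))
  q1 <- network_fluxes(net, rn$s_nM, 5.3e-6)$Q_nmol_day
  q2 <- network_fluxes(net, 3 * rn$s_nM, 5.3e-6)$Q_nmol_day   # h scaling
  expect_equal(q2, 3 * q1, tolerance = 1e-12)
  qD <- network_fluxes(net, rn$s_nM, 2 * 5.3e-6)$Q_nmol_day
  expect_equal(qD, 2 * q1, tolerance = 1e-12)
  set.seed(99)
  s_b <- rn$s_nM
  s_b[net$cells$kind == "osteocyte"] <- runif(sum(net$cells$kind == "osteocyte"), 0, 50)
  qa <- q1
  qb <- network_fluxes(net, s_b, 5.3e-6)$Q_nmol_day
  qab <- network_fluxes(net, rn$s_nM + s_b, 5.3e-6)$Q_nmol_day
  expect_equal(qab, qa + qb, tolerance = 1e-12)
})

test_that("network validation catches malformed inputs", {
  cells <- data.frame(id = c("a", "b"), kind = c("osteocyte", "osteoblast"),
                      x_um = c(0, 0), y_um = c(0, 0),
                      surface = c(NA, "periosteal"))
  expect_error(cell_network(cells, data.frame(id_a = "a", id_b = "b")),
               "zero-length")
  expect_error(cell_network(cells, data.frame(id_a = "a", id_b = "c")),
               "not found")
  expect_error(cell_network(cells, data.frame(id_a = "a", id_b = "a")),
               "distinct")
  cells$surface <- NA
  expect_error(cell_network(cells,
                            data.frame(id_a = "a", id_b = "b", length_um = 10)),
               "surface")
  # component without a sink is flagged
  c2 <- data.frame(id = c("a", "b", "c"),
                   kind = c("osteocyte", "osteoblast", "osteocyte"),
                   x_um = c(0, 10, 99), y_um = 0,
                   surface = c(NA, "periosteal", NA))
  expect_warning(cell_network(c2, data.frame(id_a = "a", id_b = "b")),
                 "sink")
  # isolated free junction makes the solve singular
  c3 <- data.frame(id = c("a", "b", "j"),
                   kind = c("osteocyte", "osteoblast", "junction"),
                   x_um = c(0, 10, 99), y_um = 0,
                   surface = c(NA, "periosteal", NA))
  net3 <- suppressWarnings(cell_network(c3, data.frame(id_a = "a", id_b = "b")))
  K3 <- assemble_stiffness(net3, 1)
  expect_error(solve_fluxes(K3, c(a = 10, b = 0, j = 0), net3), "j")
})

test_that("parallel duplicate edges accumulate conductance", {
  cells <- data.frame(id = c("oc1", "ob1"), kind = c("osteocyte", "osteoblast"),
                      x_um = c(0, 100), y_um = 0, surface = c(NA, "periosteal"))
  edges <- data.frame(id_a = c("oc1", "oc1"), id_b = c("ob1", "ob1"))
  net <- cell_network(cells, edges)
  K <- assemble_stiffness(net, 1000)
  expect_equal(K[1, 1], 2 * 1000 * 0.025 / 100)
})
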