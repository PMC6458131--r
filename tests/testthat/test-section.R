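# Cross-section properties and beam-theory strain.

test_that("solid rectangle matches the closed forms", {
  w <- 1000; h <- 600
  sq <- cbind(c(-1, 1, 1, -1) * w / 2, c(-1, -1, 1, 1) * h / 2)
  s <- section_properties(sq)
  expect_equal(s$A_um2, w * h)
  expect_equal(s$Ix_um4, w * h^3 / 12)
  expect_equal(s$Iy_um4, h * w^3 / 12)
  expect_equal(s$Ixy_um4, 0)
  expect_equal(unname(s$centroid_um), c(0, 0))
})

test_that("circular annulus matches pi (R^4 - r^4)/4 within 0.5%", {
  th <- 2 * pi * (0:255) / 256
  s <- section_properties(cbind(500 * cos(th), 500 * sin(th)),
                          cbind(300 * cos(th), 300 * sin(th)))
  expect_equal(s$A_um2, pi * (500^2 - 300^2), tolerance = 5e-3)
  expect_equal(s$Ix_um4, pi * (500^4 - 300^4) / 4, tolerance = 5e-3)
  expect_equal(s$Iy_um4, s$Ix_um4, tolerance = 1e-9)
  expect_equal(s$Ixy_um4 / s$Ix_um4, 0, tolerance = 1e-12)
})

test_that("centroidal properties are translation invariant and winding agnostic", {
  th <- 2 * pi * (0:63) / 64
  outer <- cbind(600 * cos(th), 400 * sin(th))
  inner <- cbind(450 * cos(th), 250 * sin(th))
  s0 <- section_properties(outer, inner)
  sh <- section_properties(sweep(outer, 2, c(-123, 456), "+"),
                           sweep(inner, 2, c(-123, 456), "+"))
  expect_equal(sh$A_um2, s0$A_um2)
  expect_equal(sh$Ix_um4, s0$Ix_um4)
  expect_equal(sh$Iy_um4, s0$Iy_um4)
  # Ixy of this symmetric ring is ~0; compare on the Ix scale
  expect_lt(abs(sh$Ixy_um4 - s0$Ixy_um4) / s0$Ix_um4, 1e-12)
  # clockwise input normalized internally
  sw <- section_properties(outer[rev(seq_len(64)), ], inner)
  expect_equal(sw$A_um2, s0$A_um2)
})

test_that("degenerate polygons are rejected", {
  bowtie <- cbind(c(0, 1, 1, 0), c(0, 1, 0, 1)) * 100
  expect_error(section_properties(bowtie), "self-intersecting")
  th <- 2 * pi * (0:31) / 32
  outer <- cbind(300 * cos(th), 300 * sin(th))
  expect_error(section_properties(outer, outer * 2), "inside")
})

test_that("axial force gives uniform strain and pure bending a neutral axis", {
  th <- 2 * pi * (0:63) / 64
  s <- section_properties(cbind(500 * cos(th), 500 * sin(th)),
                          cbind(350 * cos(th), 350 * sin(th)))
  pts <- cbind(runif(20, -500, 500), runif(20, -500, 500))
  ax <- strain_amplitude_at(section_loads(Fz0_N = 10), s, pts)
  expect_equal(ax, rep(10 / (20e9 * s$A_um2 * 1e-12) * 1e6, 20))

  bend <- strain_amplitude_at(section_loads(Mx0_Nmm = 2), s, pts)
  expect_equal(bend, pts[, 2] * 1e-6 * 2e-3 / (20e9 * s$Ix_um4 * 1e-24) * 1e6,
               tolerance = 1e-10)
  expect_equal(strain_amplitude_at(section_loads(Mx0_Nmm = 2), s, c(123, 0)), 0)
  # positive Mx0 -> tension on the anterior (y > 0) side
  expect_gt(strain_amplitude_at(section_loads(Mx0_Nmm = 2), s, c(0, 400)), 0)
})

test_that("mixed bending matches a principal-axis rotation oracle", {
  # asymmetric section: rotated ellipse ring gives nonzero Ixy
  th <- 2 * pi * (0:127) / 128
  rot <- function(p, a) p %*% t(matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2))
  outer <- rot(cbind(600 * cos(th), 380 * sin(th)), 0.5)
  inner <- rot(cbind(430 * cos(th), 240 * sin(th)), 0.5)
  s <- section_properties(outer, inner)
  expect_gt(abs(s$Ixy_um4), 0)

  loads <- section_loads(Fz0_N = -3, Mx0_Nmm = 2.5, My0_Nmm = -1.2)
  set.seed(5)
  pts <- cbind(runif(25, -600, 600), runif(25, -400, 400))
  got <- strain_amplitude_at(loads, s, pts)

  # oracle: rotate geometry to principal axes where Ixy = 0, transform the
  # moment pair with the convention Mx = int(sigma y), My = -int(sigma x)
  f <- function(a) {
    ro <- rot(outer, -a); ri <- rot(inner, -a)
    abs(section_properties(ro, ri)$Ixy_um4)
  }
  ang <- optimize(f, c(-pi / 4, pi / 4), tol = 1e-12)$minimum
  sp <- section_properties(rot(outer, -ang), rot(inner, -ang))
  expect_equal(sp$Ixy_um4 / sp$Ix_um4, 0, tolerance = 1e-6)
  ca <- cos(-ang); sa <- sin(-ang)
  Mxp <- loads$Mx0_Nmm * ca - loads$My0_Nmm * sa
  Myp <- loads$My0_Nmm * ca + loads$Mx0_Nmm * sa
  ptsp <- rot(pts, -ang)
  oracle <- strain_amplitude_at(section_loads(loads$Fz0_N, Mxp, Myp), sp, ptsp)
  expect_equal(got, oracle, tolerance = 1e-6)
})

test_that("strain superposes linearly in the loads", {
  fx <- default_fixture()
  s <- fx$section
  set.seed(11)
  pts <- cbind(runif(10, -500, 500), runif(10, -350, 350))
  l1 <- section_loads(2, -1.5, 0.7)
  l2 <- section_loads(-4, 0.3, 2.1)
  l12 <- section_loads(l1$Fz0_N + l2$Fz0_N, l1$Mx0_Nmm + l2$Mx0_Nmm,
                       l1$My0_Nmm + l2$My0_Nmm)
  expect_equal(strain_amplitude_at(l12, s, pts),
               strain_amplitude_at(l1, s, pts) + strain_amplitude_at(l2, s, pts),
               tolerance = 1e-12)
})

test_that("pure-bending strain vanishes on the neutral axis and peaks periosteally", {
  fx <- default_fixture()
  s <- fx$section
  loads <- section_loads(Mx0_Nmm = 3, My0_Nmm = 1.2)
  # exact zero-strain direction (x, y) ~ (Mx Iy + My Ixy, My Ix + Mx Ixy);
  # the atan2(My, Mx) convention is the field's approximate orientation
  ang <- atan2(loads$My0_Nmm * s$Ix_um4 + loads$Mx0_Nmm * s$Ixy_um4,
               loads$Mx0_Nmm * s$Iy_um4 + loads$My0_Nmm * s$Ixy_um4)
  tline <- seq(-500, 500, length.out = 9)
  axis_pts <- cbind(tline * cos(ang), tline * sin(ang))
  eps_axis <- strain_amplitude_at(loads, s, axis_pts)
  peak <- max(abs(strain_amplitude_at(loads, s, s$periosteal_um)))
  expect_true(all(abs(eps_axis) < 1e-9 * peak))
  # periosteal boundary dominates the endocortical one
  expect_gt(peak, max(abs(strain_amplitude_at(loads, s, s$endocortical_um))))
})

test_that("neutral axis angle follows atan2 and rejects the zero case", {
  expect_equal(neutral_axis_angle(5, 0), 0)
  expect_equal(neutral_axis_angle(5, 5 * tan(3 * pi / 180)), 3)
  expect_equal(neutral_axis_angle(0, 2), 90)
  expect_equal(neutral_axis_angle(-1, 0), 0)   # folded into (-90, 90]
  expect_error(neutral_axis_angle(0, 0), "undefined")
})
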