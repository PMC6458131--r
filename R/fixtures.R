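# Seeded synthetic fixtures: an elliptical-annulus mid-diaphyseal section,
# intracortical osteocytes wired to surface osteoblasts, printed protocol
# presets, and noisy forward-model observations.
#
# The real murine section, cell coordinates and network topology behind
# the calibrated in-vivo constants were never tabulated; these fixtures
# stand in for them (synthetic by construction) with the statistical
# structure the model assumes: a few hundred osteocytes on a jittered
# intracortical lattice, a few dozen osteoblasts equally spaced on each
# surface, processes of ~cortical-thickness length and uniform area A0.

#' Fixture specification
#'
#' @param outer_a_um,outer_b_um periosteal ellipse semi-axes, um
#' @param thickness_um cortical thickness (inner semi-axes are outer minus
#'   thickness); must be smaller than both semi-axes
#' @param n_vertices polygon discretization per boundary
#' @param n_osteocytes intracortical osteocyte count
#' @param n_osteoblasts_periosteal,n_osteoblasts_endocortical surface
#'   osteoblast counts
#' @param network_rule one of `nearest_osteoblast` (each osteocyte wires to
#'   its nearest osteoblast), `k_nearest` (to its `rule_k` nearest
#'   osteoblasts), `delaunay_pruned` (Delaunay triangulation of all cells,
#'   keeping edges with an osteocyte endpoint and length below
#'   `prune_factor` times the median)
#' @param rule_k neighbor count for `k_nearest`
#' @param prune_factor length cutoff multiplier for `delaunay_pruned`
#' @param A0_um2 process cross-sectional area, um^2
#' @param seed fixture seed; identical seeds give identical fixtures
#' @return object of class `fixture_spec`
#' @export
fixture_spec <- function(outer_a_um = 600, outer_b_um = 450,
                         thickness_um = 150, n_vertices = 96,
                         n_osteocytes = 200,
                         n_osteoblasts_periosteal = 40,
                         n_osteoblasts_endocortical = 24,
                         network_rule = c("nearest_osteoblast", "k_nearest",
                                          "delaunay_pruned"),
                         rule_k = 2L, prune_factor = 3, A0_um2 = 0.025,
                         seed = 1L) {
  network_rule <- match.arg(network_rule)
  check_num1(outer_a_um, "outer_a_um", lower = 1)
  check_num1(outer_b_um, "outer_b_um", lower = 1)
  check_num1(thickness_um, "thickness_um", lower = 1)
  if (thickness_um >= min(outer_a_um, outer_b_um))
    stopf("thickness (%g um) must be less than the smaller semi-axis (%g um)",
          thickness_um, min(outer_a_um, outer_b_um))
  check_num1(n_vertices, "n_vertices", lower = 8)
  check_num1(n_osteocytes, "n_osteocytes", lower = 1)
  check_num1(n_osteoblasts_periosteal, "n_osteoblasts_periosteal", lower = 1)
  check_num1(n_osteoblasts_endocortical, "n_osteoblasts_endocortical", lower = 1)
  structure(list(outer_a_um = outer_a_um, outer_b_um = outer_b_um,
                 thickness_um = thickness_um, n_vertices = as.integer(n_vertices),
                 n_osteocytes = as.integer(n_osteocytes),
                 n_osteoblasts_periosteal = as.integer(n_osteoblasts_periosteal),
                 n_osteoblasts_endocortical = as.integer(n_osteoblasts_endocortical),
                 network_rule = network_rule, rule_k = as.integer(rule_k),
                 prune_factor = prune_factor, A0_um2 = A0_um2,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

ellipse_polygon <- function(a, b, n) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(a * cos(th), b * sin(th))
}

#' Synthetic elliptical-annulus cross-section
#'
#' @param spec a [fixture_spec()]
#' @return a [section_properties()] `cross_section`
#' @export
make_section <- function(spec) {
  if (!inherits(spec, "fixture_spec")) stopf("'spec' must be a fixture_spec")
  outer <- ellipse_polygon(spec$outer_a_um, spec$outer_b_um, spec$n_vertices)
  inner <- ellipse_polygon(spec$outer_a_um - spec$thickness_um,
                           spec$outer_b_um - spec$thickness_um,
                           spec$n_vertices)
  section_properties(outer, inner)
}

# O(n^2)-ish Bowyer-Watson Delaunay; returns a 2-column index edge matrix.
# Fine for fixture-sized point sets (a few hundred cells).
delaunay_edges <- function(x, y) {
  n <- length(x)
  # super-triangle enclosing everything
  cx <- mean(range(x)); cy <- mean(range(y))
  span <- max(diff(range(x)), diff(range(y))) * 20 + 1
  px <- c(x, cx - span, cx + span, cx)
  py <- c(y, cy - span, cy - span, cy + span)
  tri <- matrix(c(n + 1L, n + 2L, n + 3L), nrow = 1)
  circum <- function(t) {
    ax <- px[t[1]]; ay <- py[t[1]]; bx <- px[t[2]]; by <- py[t[2]]
    cx_ <- px[t[3]]; cy_ <- py[t[3]]
    dd <- 2 * (ax * (by - cy_) + bx * (cy_ - ay) + cx_ * (ay - by))
    if (abs(dd) < 1e-12) return(c(Inf, Inf, Inf))
    ux <- ((ax^2 + ay^2) * (by - cy_) + (bx^2 + by^2) * (cy_ - ay) +
             (cx_^2 + cy_^2) * (ay - by)) / dd
    uy <- ((ax^2 + ay^2) * (cx_ - bx) + (bx^2 + by^2) * (ax - cx_) +
             (cx_^2 + cy_^2) * (bx - ax)) / dd
    c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
  }
  cc <- matrix(circum(tri[1, ]), nrow = 1)
  for (ip in seq_len(n)) {
    bad <- which((px[ip] - cc[, 1])^2 + (py[ip] - cc[, 2])^2 <= cc[, 3] * (1 + 1e-12))
    if (!length(bad)) bad <- which.min((px[ip] - cc[, 1])^2 + (py[ip] - cc[, 2])^2 - cc[, 3])
    # boundary of the cavity: edges of bad triangles not shared by two
    ed <- do.call(rbind, lapply(bad, function(b) {
      t <- tri[b, ]
      rbind(sort(t[1:2]), sort(t[2:3]), sort(t[c(1, 3)]))
    }))
    key <- paste(ed[, 1], ed[, 2])
    keep <- ed[key %in% names(which(table(key) == 1)), , drop = FALSE]
    tri <- tri[-bad, , drop = FALSE]
    cc <- cc[-bad, , drop = FALSE]
    newtri <- cbind(keep, ip)
    tri <- rbind(tri, newtri)
    cc <- rbind(cc, t(apply(newtri, 1, circum)))
  }
  real <- tri[apply(tri <= n, 1, all), , drop = FALSE]
  if (!nrow(real)) return(matrix(integer(0), ncol = 2))
  e <- rbind(real[, 1:2], real[, 2:3], real[, c(1, 3)])
  e <- t(apply(e, 1, sort))
  unique(e)
}

#' Synthetic cell population and process network
#'
#' Osteocytes sit on a seeded jittered lattice inside the cortex;
#' osteoblasts are equally spaced (in parametric angle) on each surface;
#' edges follow `spec$network_rule` with length = Euclidean distance and
#' area = A0. Errors if any osteocyte ends up disconnected from every
#' osteoblast under the chosen rule, naming the cells.
#'
#' @param section the [make_section()] output for the same spec
#' @param spec a [fixture_spec()]
#' @return a [cell_network()]
#' @export
make_cells_and_network <- function(section, spec) {
  if (!inherits(spec, "fixture_spec")) stopf("'spec' must be a fixture_spec")
  set.seed(spec$seed)
  a <- spec$outer_a_um; b <- spec$outer_b_um; th <- spec$thickness_um

  # osteocytes: jittered lattice, kept strictly inside the cortex
  n_oc <- spec$n_osteocytes
  outer_poly <- section$periosteal_um
  inner_poly <- section$endocortical_um
  pts <- NULL
  spacing <- sqrt(pi * (a * b - (a - th) * (b - th)) / (2.2 * n_oc))
  for (attempt in 1:6) {
    gx <- seq(-a, a, by = spacing)
    gy <- seq(-b, b, by = spacing)
    g <- expand.grid(x = gx, y = gy)
    g$x <- g$x + stats::rnorm(nrow(g), 0, 0.18 * spacing)
    g$y <- g$y + stats::rnorm(nrow(g), 0, 0.18 * spacing)
    # radial margin keeps cells off the surfaces themselves
    shrink <- function(p, f) p * f
    ok <- point_in_polygon(g$x, g$y, shrink(outer_poly, 0.985)) &
      !point_in_polygon(g$x, g$y, shrink(inner_poly, 1.02))
    pts <- g[ok, , drop = FALSE]
    if (nrow(pts) >= n_oc) break
    spacing <- spacing * 0.8
  }
  if (nrow(pts) < n_oc)
    stopf("could not place %d osteocytes in the cortex", n_oc)
  pts <- pts[sample.int(nrow(pts), n_oc), , drop = FALSE]

  peri_n <- spec$n_osteoblasts_periosteal
  endo_n <- spec$n_osteoblasts_endocortical
  tp <- 2 * pi * (seq_len(peri_n) - 1) / peri_n
  te <- 2 * pi * (seq_len(endo_n) - 1) / endo_n

  cells <- data.frame(
    id = c(sprintf("oc%03d", seq_len(n_oc)),
           sprintf("obP%02d", seq_len(peri_n)),
           sprintf("obE%02d", seq_len(endo_n))),
    kind = c(rep("osteocyte", n_oc), rep("osteoblast", peri_n + endo_n)),
    x_um = c(pts$x, a * cos(tp), (a - th) * cos(te)),
    y_um = c(pts$y, b * sin(tp), (b - th) * sin(te)),
    surface = c(rep("intracortical", n_oc), rep("periosteal", peri_n),
                rep("endocortical", endo_n)),
    stringsAsFactors = FALSE)

  oc_i <- which(cells$kind == "osteocyte")
  ob_i <- which(cells$kind == "osteoblast")
  if (spec$network_rule %in% c("nearest_osteoblast", "k_nearest")) {
    k <- if (spec$network_rule == "nearest_osteoblast") 1L else spec$rule_k
    eg <- do.call(rbind, lapply(oc_i, function(i) {
      d2 <- (cells$x_um[ob_i] - cells$x_um[i])^2 +
        (cells$y_um[ob_i] - cells$y_um[i])^2
      nb <- ob_i[order(d2)[seq_len(min(k, length(ob_i)))]]
      cbind(i, nb)
    }))
  } else {
    # tiny deterministic jitter guards the triangulation against the
    # exactly-cocircular surface osteoblasts of a circular section
    jx <- cells$x_um + stats::rnorm(nrow(cells), 0, 1e-3)
    jy <- cells$y_um + stats::rnorm(nrow(cells), 0, 1e-3)
    eg <- delaunay_edges(jx, jy)
    has_oc <- cells$kind[eg[, 1]] == "osteocyte" |
      cells$kind[eg[, 2]] == "osteocyte"
    eg <- eg[has_oc, , drop = FALSE]
    len <- sqrt((cells$x_um[eg[, 1]] - cells$x_um[eg[, 2]])^2 +
                  (cells$y_um[eg[, 1]] - cells$y_um[eg[, 2]])^2)
    eg <- eg[len <= spec$prune_factor * stats::median(len), , drop = FALSE]
  }
  edges <- data.frame(id_a = cells$id[eg[, 1]], id_b = cells$id[eg[, 2]],
                      stringsAsFactors = FALSE)

  net <- withCallingHandlers(
    cell_network(cells, edges, A0_um2 = spec$A0_um2),
    warning = function(w) invokeRestart("muffleWarning"))
  lost <- attr(net, "sinkless_cells")
  lost <- lost[lost %in% cells$id[oc_i]]
  if (length(lost))
    stopf("osteocyte(s) disconnected from every osteoblast under rule '%s': %s",
          spec$network_rule, paste(lost, collapse = ", "))
  net
}

#' Noisy synthetic average-BFR observations
#'
#' Evaluates the forward average model for each protocol at the
#' ground-truth parameters, adds seeded Gaussian noise, and clips negative
#' values to zero (flagged in the `clipped` column).
#'
#' @param ground_truth_params [model_parameters()]
#' @param protocols list of [loading_protocol()] objects
#' @param noise_sd Gaussian noise standard deviation (same units as B)
#' @param seed noise seed
#' @return data.frame with `label`, `B0`, `B_true`, `clipped`
#' @export
make_observations <- function(ground_truth_params, protocols, noise_sd = 0,
                              seed = 1L) {
  check_num1(noise_sd, "noise_sd", lower = 0)
  B <- vapply(protocols, function(pr)
    bfr_forward(ground_truth_params, pr), 0)
  set.seed(seed)
  obs <- B + stats::rnorm(length(B), 0, noise_sd)
  clipped <- obs < 0
  obs[clipped] <- 0
  data.frame(label = vapply(protocols, `[[`, "", "label"),
             B0 = obs, B_true = B, clipped = clipped,
             stringsAsFactors = FALSE)
}

#' Printed loading-protocol presets
#'
#' Named presets carrying the published protocol parameters used to
#' exercise the model: the trapezoidal cantilever series (0.1 s rise,
#' 0.8 s hold, 0.1 s fall, 10 s rest, peak strains 1000/1250/1600 ue,
#' N = 10/50/250, d = 3), the 2 Hz haversine axial protocols (360, 60 and
#' 99 cycles), the 4 Hz triangular protocol with 5 s rest after every 4
#' cycles (216 cycles, d = 5), the 2 Hz sinusoidal four-point protocol
#' (36 cycles, d = 7), and the 0.5 s rectangular pulse with 39.5 s rest
#' (36 cycles).
#'
#' @return named list of [loading_protocol()] objects
#' @export
protocol_presets <- function() {
  trap <- function(rest) make_waveform("trapezoid",
                                       list(rise_s = 0.1, hold_s = 0.8, fall_s = 0.1),
                                       rest_s = rest)
  hav2 <- make_waveform("haversine", list(frequency_hz = 2))
  presets <- list(
    cantilever_1600x50_rest = loading_protocol(
      "cantilever_1600x50_rest", trap(10), 1600, 50, 3, weeks = 3),
    cantilever_1000x250_rest = loading_protocol(
      "cantilever_1000x250_rest", trap(10), 1000, 250, 3, weeks = 3),
    cantilever_1250x10_norest = loading_protocol(
      "cantilever_1250x10_norest", trap(0), 1250, 10, 3, weeks = 3),
    axial_weatherholt = loading_protocol(
      "axial_weatherholt", hav2, 1833, 360, 3, weeks = 4),
    axial_mahaffey = loading_protocol(
      "axial_mahaffey", hav2, 1200, 60, 3, weeks = 2),
    axial_willie = loading_protocol(
      "axial_willie",
      make_waveform("triangle", list(frequency_hz = 4), rest_s = 5,
                    n_group = 4L),
      1695, 216, 5, weeks = 2),
    fourpt_turner_1404 = loading_protocol(
      "fourpt_turner_1404",
      make_waveform("sine", list(frequency_hz = 2)), 1404, 36, 7, weeks = 2),
    fourpt_kuruvilla = loading_protocol(
      "fourpt_kuruvilla", hav2, 2000, 99, 3, weeks = 3),
    threept_sakai = loading_protocol(
      "threept_sakai",
      make_waveform("rect_pulse", list(duration_s = 0.5), rest_s = 39.5),
      2100, 36, 3, weeks = 1)
  )
  presets
}

#' A ten-protocol trapezoidal calibration fixture
#'
#' The strain-by-cycle grid (1000/1250/1600 ue x 10/50/250 cycles, 10 s
#' rest, d = 3) plus one back-to-back (no rest) protocol, mirroring the
#' structure of the published cantilever calibration set whose exact
#' composition was never tabulated.
#'
#' @return list of 10 [loading_protocol()] objects
#' @export
calibration_protocols <- function() {
  trap <- function(rest) make_waveform("trapezoid",
                                       list(rise_s = 0.1, hold_s = 0.8, fall_s = 0.1),
                                       rest_s = rest)
  grid <- expand.grid(eps = c(1000, 1250, 1600), N = c(10, 50, 250))
  out <- lapply(seq_len(nrow(grid)), function(i)
    loading_protocol(sprintf("trap_rest_%dx%d", grid$eps[i], grid$N[i]),
                     trap(10), grid$eps[i], grid$N[i], 3, weeks = 3))
  out[[10]] <- loading_protocol("trap_norest_1600x50", trap(0), 1600, 50, 3,
                                weeks = 3)
  names(out) <- vapply(out, `[[`, "", "label")
  out
}
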