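# Bone cross-section geometry and beam-theory normal strain.
#
# The section is an annular region between a periosteal (outer) and an
# endocortical (inner) simple polygon, in centroidal coordinates with x
# along the lateral and y along the anterior anatomical direction. Loads
# are amplitudes of a normal force Fz0 (N) and bending moments Mx0, My0
# (N mm) that all scale the same unit waveform u(t). Sign convention
# (documented, the field has no universal one): Mx0 = integral(sigma y dA),
# My0 = -integral(sigma x dA), so positive Mx0 puts the anterior side
# (y > 0) in tension and positive My0 puts the lateral side (x > 0) in
# compression.

# Signed-area polygon properties about the origin (Green's theorem).
polygon_raw_props <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  A <- sum(cr) / 2
  Sx <- sum((x + x2) * cr) / 6          # A * centroid_x
  Sy <- sum((y + y2) * cr) / 6
  Ix <- sum((y^2 + y * y2 + y2^2) * cr) / 12          # about origin
  Iy <- sum((x^2 + x * x2 + x2^2) * cr) / 12
  Ixy <- sum((x * y2 + 2 * x * y + 2 * x2 * y2 + x2 * y) * cr) / 24
  list(A = A, Sx = Sx, Sy = Sy, Ix = Ix, Iy = Iy, Ixy = Ixy)
}

seg_intersects <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

polygon_is_simple <- function(xy) {
  n <- nrow(xy)
  if (n < 3L) return(FALSE)
  idx <- rbind(cbind(seq_len(n), c(seq_len(n)[-1], 1L)))
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next       # shares a vertex with the closing edge
      if (seg_intersects(xy[idx[i, 1], ], xy[idx[i, 2], ],
                         xy[idx[j, 1], ], xy[idx[j, 2], ])) return(FALSE)
    }
  }
  TRUE
}

point_in_polygon <- function(px, py, xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- length(x)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  inside <- logical(length(px))
  for (k in seq_along(px)) {
    crosses <- (y > py[k]) != (y2 > py[k])
    xin <- x[crosses] + (py[k] - y[crosses]) * (x2[crosses] - x[crosses]) /
      (y2[crosses] - y[crosses])
    inside[k] <- (sum(xin > px[k]) %% 2L) == 1L
  }
  inside
}

as_polygon <- function(p, name) {
  p <- as.matrix(p)
  if (ncol(p) != 2L || nrow(p) < 3L || !all(is.finite(p)))
    stopf("'%s' must be a matrix of >= 3 finite (x, y) vertices", name)
  colnames(p) <- c("x_um", "y_um")
  p
}

#' Cross-section properties from boundary polygons
#'
#' Computes area, centroid, second moments of area Ix, Iy and product
#' moment Ixy (about the centroid) of the annular region between the
#' periosteal and endocortical boundary polygons via Green's-theorem
#' polygon formulas. Winding of each polygon is normalized internally;
#' self-intersecting polygons are rejected, as is an endocortical polygon
#' not strictly inside the periosteal one.
#'
#' @param periosteal_polygon outer boundary, matrix of (x, y) vertices in um
#' @param endocortical_polygon inner boundary (optional: omit for a solid
#'   section), same format
#' @return object of class `cross_section` with fields `A_um2`, `centroid_um`,
#'   `Ix_um4`, `Iy_um4`, `Ixy_um4` and the (centroid-shifted) polygons
#' @export
#' @examples
#' sq <- cbind(c(-1, 1, 1, -1) * 500, c(-1, -1, 1, 1) * 300)
#' section_properties(sq)$Ix_um4  # w h^3 / 12 with w = 1000, h = 600
section_properties <- function(periosteal_polygon, endocortical_polygon = NULL) {
  outer <- as_polygon(periosteal_polygon, "periosteal_polygon")
  if (!polygon_is_simple(outer)) stopf("periosteal polygon is self-intersecting")
  po <- polygon_raw_props(outer)
  if (po$A < 0) {                      # normalize to CCW
    outer <- outer[rev(seq_len(nrow(outer))), , drop = FALSE]
    po <- polygon_raw_props(outer)
  }

  inner <- NULL
  if (!is.null(endocortical_polygon)) {
    inner <- as_polygon(endocortical_polygon, "endocortical_polygon")
    if (!polygon_is_simple(inner)) stopf("endocortical polygon is self-intersecting")
    pi_ <- polygon_raw_props(inner)
    if (pi_$A < 0) {
      inner <- inner[rev(seq_len(nrow(inner))), , drop = FALSE]
      pi_ <- polygon_raw_props(inner)
    }
    if (!all(point_in_polygon(inner[, 1], inner[, 2], outer)))
      stopf("endocortical polygon must lie strictly inside the periosteal polygon")
    A <- po$A - pi_$A
    Sx <- po$Sx - pi_$Sx; Sy <- po$Sy - pi_$Sy
    Ix0 <- po$Ix - pi_$Ix; Iy0 <- po$Iy - pi_$Iy; Ixy0 <- po$Ixy - pi_$Ixy
  } else {
    A <- po$A; Sx <- po$Sx; Sy <- po$Sy
    Ix0 <- po$Ix; Iy0 <- po$Iy; Ixy0 <- po$Ixy
  }
  if (A <= 0) stopf("section area must be positive")

  cx <- Sx / A; cy <- Sy / A
  Ix <- Ix0 - A * cy^2
  Iy <- Iy0 - A * cx^2
  Ixy <- Ixy0 - A * cx * cy
  if (Ix * Iy - Ixy^2 <= 0)
    stopf("degenerate section: Ix*Iy - Ixy^2 must be positive")

  shift <- function(p) if (is.null(p)) NULL else sweep(p, 2, c(cx, cy))
  structure(list(A_um2 = A, centroid_um = c(x = cx, y = cy),
                 Ix_um4 = Ix, Iy_um4 = Iy, Ixy_um4 = Ixy,
                 periosteal_um = shift(outer), endocortical_um = shift(inner)),
            class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("cross_section: A %.4g um^2, Ix %.4g, Iy %.4g, Ixy %.4g um^4\n",
              x$A_um2, x$Ix_um4, x$Iy_um4, x$Ixy_um4))
  invisible(x)
}

#' Sectional load amplitudes
#'
#' @param Fz0_N normal force amplitude, N
#' @param Mx0_Nmm bending moment about the medial-lateral (x) axis, N mm
#' @param My0_Nmm bending moment about the anterior-posterior (y) axis, N mm
#' @return object of class `section_loads`
#' @export
section_loads <- function(Fz0_N = 0, Mx0_Nmm = 0, My0_Nmm = 0) {
  check_num1(Fz0_N, "Fz0_N"); check_num1(Mx0_Nmm, "Mx0_Nmm")
  check_num1(My0_Nmm, "My0_Nmm")
  structure(list(Fz0_N = Fz0_N, Mx0_Nmm = Mx0_Nmm, My0_Nmm = My0_Nmm),
            class = "section_loads")
}

#' Beam-theory normal strain amplitude at in-plane points
#'
#' Unsymmetric-bending strain at centroidal coordinates (x, y):
#' `eps = Fz0/(E A) + [(Mx0 Iy + My0 Ixy) y - (My0 Ix + Mx0 Ixy) x] /
#' (E (Ix Iy - Ixy^2))`, converted to microstrain. Positive Mx0 produces
#' tension at y > 0.
#'
#' @param loads a [section_loads()] object
#' @param section a [section_properties()] object
#' @param points matrix (or length-2 vector) of (x, y) centroidal
#'   coordinates, um
#' @param E_GPa Young's modulus, GPa (default 20 for cortical bone)
#' @return strain amplitudes in microstrain, one per point
#' @export
strain_amplitude_at <- function(loads, section, points, E_GPa = 20) {
  if (!inherits(loads, "section_loads")) stopf("'loads' must be section_loads")
  if (!inherits(section, "cross_section")) stopf("'section' must be a cross_section")
  check_num1(E_GPa, "E_GPa", lower = .Machine$double.xmin)
  if (is.null(dim(points))) points <- matrix(points, ncol = 2, byrow = TRUE)
  points <- as.matrix(points)

  E_Pa <- E_GPa * 1e9
  A_m2 <- section$A_um2 * 1e-12
  Ix <- section$Ix_um4 * 1e-24; Iy <- section$Iy_um4 * 1e-24
  Ixy <- section$Ixy_um4 * 1e-24
  det <- Ix * Iy - Ixy^2
  if (det <= 0) stopf("degenerate section moments")
  Mx <- loads$Mx0_Nmm * 1e-3; My <- loads$My0_Nmm * 1e-3   # N m
  x <- points[, 1] * 1e-6; y <- points[, 2] * 1e-6          # m

  eps <- loads$Fz0_N / (E_Pa * A_m2) +
    ((Mx * Iy + My * Ixy) * y - (My * Ix + Mx * Ixy) * x) / (E_Pa * det)
  eps * 1e6
}

#' Neutral-axis orientation for pure bending
#'
#' Angle `atan2(My0, Mx0)` of the neutral axis to the medial-lateral (x)
#' direction, folded into (-90, 90] degrees.
#'
#' @param Mx0_Nmm,My0_Nmm bending moment amplitudes, N mm (not both zero)
#' @return angle in degrees
#' @export
neutral_axis_angle <- function(Mx0_Nmm, My0_Nmm) {
  check_num1(Mx0_Nmm, "Mx0_Nmm"); check_num1(My0_Nmm, "My0_Nmm")
  if (Mx0_Nmm == 0 && My0_Nmm == 0)
    stopf("neutral axis undefined: Mx0 and My0 are both zero")
  ang <- atan2(My0_Nmm, Mx0_Nmm) * 180 / pi
  while (ang > 90) ang <- ang - 180
  while (ang <= -90) ang <- ang + 180
  ang
}
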