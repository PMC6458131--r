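# Osteocyte-osteoblast network, per-osteocyte stimulus, and the
# steady-state diffusion solve.
#
# Osteocytes above the strain threshold hold a calcium-like stimulus
# concentration s_i; osteoblasts are perfect sinks (concentration 0); the
# stimulus flows through 1-D cell processes by Fickian steady-state
# diffusion. Each process of length L_j and area A_j contributes the
# two-node conductance element (D A_j/L_j) [[1, -1], [-1, 1]]; the nodal
# flow rates are Q = K Psi. Junction ("virtual") nodes where processes
# branch carry no prescription and are solved from zero net flow.

#' Build an osteocyte-osteoblast cell network
#'
#' @param cells data.frame with columns `id`, `kind` (one of `osteocyte`,
#'   `osteoblast`, `junction`), `x_um`, `y_um`, and optionally `surface`
#'   (`periosteal`/`endocortical` for osteoblasts, `intracortical` filled
#'   for osteocytes)
#' @param edges data.frame with columns `id_a`, `id_b` and optionally
#'   `length_um` (default: Euclidean distance) and `area_um2`
#'   (default `A0_um2`)
#' @param A0_um2 default process cross-sectional area, um^2
#' @return object of class `cell_network`
#' @export
cell_network <- function(cells, edges, A0_um2 = 0.025) {
  if (!is.data.frame(cells) ||
      !all(c("id", "kind", "x_um", "y_um") %in% names(cells)))
    stopf("'cells' needs columns id, kind, x_um, y_um")
  cells$id <- as.character(cells$id)
  if (anyDuplicated(cells$id)) stopf("duplicate cell ids")
  if (!all(cells$kind %in% c("osteocyte", "osteoblast", "junction")))
    stopf("cell kind must be osteocyte, osteoblast or junction")
  if (is.null(cells$surface)) cells$surface <- NA_character_
  ob <- cells$kind == "osteoblast"
  if (any(ob & !cells$surface %in% c("periosteal", "endocortical")))
    stopf("osteoblasts must carry surface 'periosteal' or 'endocortical'")
  cells$surface[cells$kind == "osteocyte"] <- "intracortical"

  if (!is.data.frame(edges) || !all(c("id_a", "id_b") %in% names(edges)))
    stopf("'edges' needs columns id_a, id_b")
  edges$id_a <- as.character(edges$id_a)
  edges$id_b <- as.character(edges$id_b)
  ia <- match(edges$id_a, cells$id); ib <- match(edges$id_b, cells$id)
  if (anyNA(ia) || anyNA(ib)) stopf("edge endpoint not found among cell ids")
  if (any(ia == ib)) stopf("edge endpoints must be distinct cells")
  if (is.null(edges$length_um)) edges$length_um <- NA_real_
  dflt <- is.na(edges$length_um)
  edges$length_um[dflt] <- sqrt((cells$x_um[ia] - cells$x_um[ib])^2 +
                                (cells$y_um[ia] - cells$y_um[ib])^2)[dflt]
  if (any(edges$length_um <= 0)) stopf("zero-length process edge")
  if (is.null(edges$area_um2)) edges$area_um2 <- A0_um2
  edges$area_um2[is.na(edges$area_um2)] <- A0_um2
  if (any(edges$area_um2 <= 0)) stopf("process area must be positive")

  net <- structure(list(cells = cells, edges = edges, A0_um2 = A0_um2),
                   class = "cell_network")
  # every connected component needs a sink, else prescribed stimulus has
  # nowhere to flow
  comp <- network_components(net)
  sinkless <- tapply(cells$kind == "osteoblast", comp, any)
  if (!all(sinkless)) {
    bad <- cells$id[comp %in% names(sinkless)[!sinkless]]
    attr(net, "sinkless_cells") <- bad
    warnf("%d cell(s) in component(s) without an osteoblast sink (e.g. %s)",
          length(bad), bad[1])
  }
  net
}

#' @export
print.cell_network <- function(x, ...) {
  k <- table(factor(x$cells$kind, c("osteocyte", "osteoblast", "junction")))
  cat(sprintf("cell_network: %d osteocytes, %d osteoblasts, %d junctions; %d process edges\n",
              k[1], k[2], k[3], nrow(x$edges)))
  invisible(x)
}

# connected-component labels via repeated relabeling (small graphs)
network_components <- function(network) {
  n <- nrow(network$cells)
  lab <- seq_len(n)
  ia <- match(network$edges$id_a, network$cells$id)
  ib <- match(network$edges$id_b, network$cells$id)
  if (!length(ia)) return(lab)
  repeat {
    ends <- c(ia, ib)
    other <- c(lab[ib], lab[ia])
    mins <- tapply(other, ends, min)
    new <- lab
    nodes <- as.integer(names(mins))
    new[nodes] <- pmin(new[nodes], mins)
    if (identical(new, lab)) break
    lab <- new
  }
  lab
}

#' Per-cell osteogenic stimulus
#'
#' `s_i = h (eps_peak_i - eps_thres) xi N^q d^beta` for a supra-threshold
#' osteocyte; exactly 0 for sub-threshold osteocytes and for every
#' osteoblast or junction node.
#'
#' @param eps_peak_ue per-cell peak strain magnitudes, ue
#' @param kind per-cell kind vector (`osteocyte`/`osteoblast`/`junction`)
#' @param h stimulus gain, nM/ue
#' @param eps_thres threshold strain, ue
#' @param xi oscillation ratio
#' @param N cycles per bout
#' @param q_exp cycle exponent
#' @param d days per week
#' @param beta days exponent
#' @param smooth_ue optional softplus half-width, ue: replaces the hard
#'   threshold hinge by `w log(1 + exp((eps - thres)/w))` to keep the
#'   stimulus differentiable for gradient-based inversion (0 = exact hinge,
#'   the model's definition)
#' @return stimulus concentrations, nM
#' @export
#' @examples
#' osteocyte_stimulus(1546, "osteocyte", h = 0.123, eps_thres = 856.126,
#'                    xi = 1, N = 1, q_exp = 0.404736, d = 1, beta = 0.465)
osteocyte_stimulus <- function(eps_peak_ue, kind, h, eps_thres, xi, N,
                               q_exp, d, beta, smooth_ue = 0) {
  check_num1(h, "h", lower = 0); check_num1(eps_thres, "eps_thres", lower = 0)
  check_num1(xi, "xi", lower = 0); check_num1(N, "N", lower = 0)
  check_num1(d, "d", lower = 0); check_num1(smooth_ue, "smooth_ue", lower = 0)
  excess <- if (smooth_ue > 0) {
    z <- (eps_peak_ue - eps_thres) / smooth_ue
    smooth_ue * ifelse(z > 30, z, log1p(exp(pmin(z, 30))))
  } else {
    pmax(eps_peak_ue - eps_thres, 0)
  }
  s <- h * excess * xi * N^q_exp * d^beta
  s[kind != "osteocyte"] <- 0
  s
}

#' Assemble the diffusion conductance matrix
#'
#' Standard finite-element assembly of the per-process elements
#' `(D A_j/L_j) [[1, -1], [-1, 1]]` into a sparse symmetric matrix with
#' zero row sums. Parallel (duplicated) edges accumulate conductance.
#'
#' @param network a [cell_network()]
#' @param D_um2_day diffusivity in um^2/day (see [diffusivity_um2_day()])
#' @return a sparse symmetric `Matrix` with dimnames = cell ids;
#'   units um^3/day (conductance)
#' @export
assemble_stiffness <- function(network, D_um2_day) {
  if (!inherits(network, "cell_network")) stopf("'network' must be a cell_network")
  check_num1(D_um2_day, "D_um2_day", lower = 0)
  ids <- network$cells$id
  n <- length(ids)
  ia <- match(network$edges$id_a, ids)
  ib <- match(network$edges$id_b, ids)
  cj <- D_um2_day * network$edges$area_um2 / network$edges$length_um
  K <- Matrix::sparseMatrix(i = c(ia, ib, ia, ib), j = c(ia, ib, ib, ia),
                            x = c(cj, cj, -cj, -cj), dims = c(n, n),
                            dimnames = list(ids, ids))
  K
}

#' Solve the steady-state diffusion system for stimulus flow rates
#'
#' Osteocyte nodes carry the prescribed concentration `s_i`, osteoblasts
#' are held at zero, junction nodes are free unknowns solved from zero net
#' flow. Flow rates are `Q = K Psi` (nmol/day); at osteoblasts `q_i <= 0`
#' for non-negative stimuli (they are sinks). A dense solve is used below
#' 500 nodes, a sparse Cholesky-backed solve above.
#'
#' @param K conductance matrix from [assemble_stiffness()], um^3/day
#' @param stimulus_nM named per-cell stimulus concentrations, nM
#'   (values at osteoblast/junction nodes are ignored)
#' @param network the [cell_network()]
#' @return object of class `diffusion_solution`: `Psi_nmol_um3`,
#'   `Q_nmol_day` (all nodes, named), `q_osteoblast_nmol_day` (named subset),
#'   `conservation` (sum of Q, should be ~0)
#' @export
solve_fluxes <- function(K, stimulus_nM, network) {
  if (!inherits(network, "cell_network")) stopf("'network' must be a cell_network")
  ids <- network$cells$id
  n <- length(ids)
  if (is.null(names(stimulus_nM))) {
    if (length(stimulus_nM) != n) stopf("unnamed stimulus must cover all cells")
    names(stimulus_nM) <- ids
  }
  kind <- network$cells$kind
  psi <- rep(NA_real_, n)
  oc <- kind == "osteocyte"
  psi[oc] <- nM_to_nmol_um3(stimulus_nM[ids[oc]])
  psi[kind == "osteoblast"] <- 0
  if (anyNA(psi[oc])) stopf("missing stimulus for some osteocyte(s)")
  if (any(psi[oc] < 0)) stopf("stimulus concentrations must be >= 0")

  free <- is.na(psi)
  if (any(free)) {
    Kff <- K[free, free, drop = FALSE]
    dg <- Matrix::diag(Kff)
    if (any(dg == 0))
      stopf("singular system: free node(s) %s have no connections",
            paste(ids[free][dg == 0], collapse = ", "))
    rhs <- -K[free, !free, drop = FALSE] %*% psi[!free]
    sol <- if (n < 500) {
      tryCatch(solve(as.matrix(Kff), as.numeric(rhs)),
               error = function(e) stopf("singular free-node system: %s",
                                         conditionMessage(e)))
    } else {
      tryCatch(as.numeric(Matrix::solve(Kff, rhs)),
               error = function(e) stopf("singular free-node system: %s",
                                         conditionMessage(e)))
    }
    psi[free] <- sol
  }

  Q <- as.numeric(K %*% psi)
  names(Q) <- ids
  names(psi) <- ids
  ob <- kind == "osteoblast"
  structure(list(Psi_nmol_um3 = psi, Q_nmol_day = Q,
                 q_osteoblast_nmol_day = Q[ob],
                 conservation = sum(Q)),
            class = "diffusion_solution")
}

#' @export
print.diffusion_solution <- function(x, ...) {
  cat(sprintf("diffusion_solution: %d nodes, %d osteoblast sinks, sum(Q) = %.3g nmol/day\n",
              length(x$Q_nmol_day), length(x$q_osteoblast_nmol_day),
              x$conservation))
  invisible(x)
}

#' One-call network flux solve from per-osteocyte stimuli
#'
#' Convenience wrapper: converts D, assembles K, builds the prescription
#' vector and calls [solve_fluxes()].
#'
#' @param network a [cell_network()]
#' @param stimulus_nM named stimulus at osteocytes (nM); osteoblasts and
#'   junctions are filled automatically
#' @param D_cm2_s diffusivity at the interface, cm^2/s
#' @return a `diffusion_solution`
#' @export
network_fluxes <- function(network, stimulus_nM, D_cm2_s = 5.3e-6) {
  ids <- network$cells$id
  s <- stats::setNames(rep(0, length(ids)), ids)
  s[names(stimulus_nM)] <- stimulus_nM
  K <- assemble_stiffness(network, diffusivity_um2_day(D_cm2_s))
  solve_fluxes(K, s, network)
}
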