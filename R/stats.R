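# Comparison statistics: one-sample two-tailed t-test for BFR/BS and
# Watson's U2 circular goodness-of-fit between MAR-weighted perimeter
# distributions.
#
# A MAR map is turned into a circular probability distribution by placing
# each osteoblast at its perimeter angle about the section centroid with
# mass proportional to its MAR. These weighted point masses are not i.i.d.
# samples, so the classical two-sample U2 null is only approximate here;
# the permutation test (default) draws its null from relabeling the
# pooled (angle, weight) entries, and the analytic mode treats the
# osteoblast counts as effective sample sizes in Stephens' asymptotic
# tail approximation.

#' One-sample two-tailed t-test of a model value against a sample
#'
#' @param model_value model prediction (the hypothesized mean)
#' @param sample_mean observed sample mean
#' @param sample_se standard error of the sample mean
#' @param n sample size (df = n - 1); required
#' @return list with `t`, `df`, `p_value`
#' @export
#' @examples
#' one_sample_t(0.436, 0.377, 0.084, n = 8)
one_sample_t <- function(model_value, sample_mean, sample_se, n) {
  check_num1(model_value, "model_value")
  check_num1(sample_mean, "sample_mean")
  check_num1(sample_se, "sample_se", lower = .Machine$double.xmin)
  if (missing(n) || is.null(n)) stopf("'n' is required (df = n - 1)")
  check_num1(n, "n", lower = 2)
  t <- (sample_mean - model_value) / sample_se
  df <- n - 1
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Circular MAR distribution
#'
#' @param angles_rad angular positions on the perimeter, radians (reduced
#'   modulo 2 pi); duplicated angles have their weights summed
#' @param weights non-negative MAR weights, at least one positive
#' @return object of class `circular_mar`: sorted `angles_rad`, raw
#'   `weights`, normalized `pdf`
#' @export
circular_mar_distribution <- function(angles_rad, weights) {
  if (length(angles_rad) != length(weights)) stopf("angles and weights lengths differ")
  if (length(angles_rad) < 1L) stopf("empty distribution")
  if (any(!is.finite(angles_rad)) || any(!is.finite(weights)))
    stopf("angles and weights must be finite")
  if (any(weights < 0)) stopf("weights must be >= 0")
  if (sum(weights) == 0) stopf("all weights zero: distribution undefined")
  a <- angles_rad %% (2 * pi)
  o <- order(a)
  a <- a[o]; w <- weights[o]
  if (anyDuplicated(a)) {
    w <- as.numeric(tapply(w, a, sum))
    a <- sort(unique(a))
  }
  structure(list(angles_rad = a, weights = w, pdf = w / sum(w)),
            class = "circular_mar")
}

#' Build a circular MAR distribution from osteoblast coordinates
#'
#' Angles are `atan2(y - cy, x - cx)` about the section centroid (the
#' origin for centroidal coordinates).
#'
#' @param x_um,y_um osteoblast coordinates, um (centroidal)
#' @param mar_um_day MAR weights, um/day
#' @param center optional (cx, cy) if coordinates are not centroidal
#' @return a [circular_mar_distribution()]
#' @export
mar_to_circular <- function(x_um, y_um, mar_um_day, center = c(0, 0)) {
  circular_mar_distribution(atan2(y_um - center[2], x_um - center[1]),
                            mar_um_day)
}

# U2 core for two weighted circular distributions on a merged support.
# d_k is the CDF difference at merged support points; the pooled measure
# weights the squared difference; subtracting the pooled-mean difference
# is Watson's origin correction (it minimizes over the arbitrary origin).
watson_u2_stat <- function(a_ang, a_w, b_ang, b_w, n1, n2) {
  grid <- sort(unique(c(a_ang, b_ang)))
  am <- numeric(length(grid)); bm <- numeric(length(grid))
  am[match(a_ang, grid)] <- a_w / sum(a_w)
  bm[match(b_ang, grid)] <- b_w / sum(b_w)
  dA <- cumsum(am); dB <- cumsum(bm)
  d <- dA - dB
  w <- (n1 * am + n2 * bm) / (n1 + n2)
  dbar <- sum(w * d)
  (n1 * n2 / (n1 + n2)) * sum(w * (d - dbar)^2)
}

stephens_p <- function(u2, terms = 100L) {
  if (u2 <= 0) return(1)
  m <- seq_len(terms)
  p <- 2 * sum((-1)^(m - 1) * exp(-2 * m^2 * pi^2 * u2))
  min(max(p, 0), 1)
}

#' Watson's U2 test between two circular MAR distributions
#'
#' The statistic integrates the squared difference of the two normalized
#' cumulative distributions around the circle against the pooled measure,
#' after subtracting the mean difference (Watson's correction, equivalent
#' to minimizing over the arbitrary origin), scaled by
#' `n1 n2 / (n1 + n2)` with the effective sample sizes.
#'
#' @param dist_a,dist_b [circular_mar_distribution()] objects (>= 3
#'   support points each)
#' @param mode `permutation` (default: relabel pooled (angle, weight)
#'   entries) or `analytic` (Stephens' asymptotic tail approximation)
#' @param n_perm permutation count
#' @param seed seed for the permutation draw
#' @param n_eff_a,n_eff_b effective sample sizes; default the support sizes
#' @return list with `statistic` (U2), `p_value`, `mode`, `n_perm`
#' @export
#' @examples
#' a <- circular_mar_distribution(c(0, pi / 2, pi), c(1, 2, 1))
#' watson_u2(a, a)$statistic  # identical distributions: 0
watson_u2 <- function(dist_a, dist_b, mode = c("permutation", "analytic"),
                      n_perm = 999L, seed = 1L,
                      n_eff_a = NULL, n_eff_b = NULL) {
  mode <- match.arg(mode)
  if (!inherits(dist_a, "circular_mar") || !inherits(dist_b, "circular_mar"))
    stopf("both distributions must be circular_mar objects")
  if (length(dist_a$angles_rad) < 3L || length(dist_b$angles_rad) < 3L)
    stopf("need at least 3 support points in each distribution")
  n1 <- n_eff_a %||% length(dist_a$angles_rad)
  n2 <- n_eff_b %||% length(dist_b$angles_rad)

  u2 <- watson_u2_stat(dist_a$angles_rad, dist_a$weights,
                       dist_b$angles_rad, dist_b$weights, n1, n2)

  if (mode == "analytic") {
    p <- stephens_p(u2)
  } else {
    pool_ang <- c(dist_a$angles_rad, dist_b$angles_rad)
    pool_w <- c(dist_a$weights, dist_b$weights)
    na <- length(dist_a$angles_rad)
    ntot <- length(pool_ang)
    set.seed(seed)
    geq <- 0L
    valid <- 0L
    for (b in seq_len(n_perm)) {
      pick <- sample.int(ntot, na)
      wa <- pool_w[pick]; wb <- pool_w[-pick]
      if (sum(wa) == 0 || sum(wb) == 0) next    # degenerate relabeling
      valid <- valid + 1L
      u2b <- watson_u2_stat(pool_ang[pick], wa, pool_ang[-pick], wb, n1, n2)
      if (u2b >= u2 - 1e-12) geq <- geq + 1L
    }
    p <- (1 + geq) / (1 + valid)
  }
  list(statistic = u2, p_value = p, mode = mode,
       n_perm = if (mode == "permutation") n_perm else NA_integer_)
}
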