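# ADP similarity metrics. An anisotropic displacement parameter is a 3x3
# symmetric positive-definite Cartesian tensor U (A^2) defining a
# zero-mean trivariate Gaussian PDF of the atomic displacement u:
#   p(u) = (2 pi)^{-3/2} det(U)^{-1/2} exp(-u' U^{-1} u / 2).
# The overlapping coefficient OC = int min(p1, p2) d^3u is evaluated per
# angular direction: along each ray the two zero-mean Gaussians cross at
# most once for r > 0, so the radial part is a closed-form erf/exponential
# expression and only the angular part is done numerically.

.erf <- function(x) 2 * stats::pnorm(sqrt(2) * x) - 1

.check_spd <- function(U, name = "U") {
  U <- as.matrix(U)
  .assert(all(dim(U) == c(3, 3)) && max(abs(U - t(U))) < 1e-12,
          "invalid_parameter", sprintf("%s must be symmetric 3 x 3", name))
  ev <- eigen(U, symmetric = TRUE, only.values = TRUE)$values
  .assert(min(ev) > 0, "invalid_parameter",
          sprintf("%s must be positive definite (eigenvalues %s)", name,
                  paste(signif(ev, 4), collapse = ", ")))
  U
}

#' Gaussian displacement PDF of an ADP tensor
#'
#' @param U 3 x 3 SPD Cartesian tensor (A^2).
#' @param u A 3-vector or n x 3 matrix of displacements (Angstrom).
#' @return Probability density values (A^-3).
#' @export
adp_pdf <- function(U, u) {
  U <- .check_spd(U)
  if (is.null(dim(u))) u <- matrix(u, 1, 3)
  Uinv <- solve(U)
  q <- rowSums((u %*% Uinv) * u)
  (2 * pi)^(-1.5) / sqrt(det(U)) * exp(-q / 2)
}

# int_0^R r^2 exp(-a r^2) dr, closed form (a > 0; R scalar Inf or vector)
.radial_moment <- function(a, R = Inf) {
  n <- max(length(a), length(R))
  a <- rep_len(a, n); R <- rep_len(R, n)
  out <- sqrt(pi) / (4 * a^1.5)
  fin <- is.finite(R)
  if (any(fin)) {
    af <- a[fin]; Rf <- R[fin]
    out[fin] <- sqrt(pi) * .erf(sqrt(af) * Rf) / (4 * af^1.5) -
      Rf * exp(-af * Rf^2) / (2 * af)
  }
  out
}

#' Overlapping coefficient of two ADP Gaussians
#'
#' \eqn{OC = \int \min(p_1, p_2)\, d^3u \in (0, 1]}. Along each direction
#' \eqn{\hat u} of the angular grid, with \eqn{q_i = \hat u^T U_i^{-1}
#' \hat u} and prefactors \eqn{c_i}, the two ray profiles
#' \eqn{c_i e^{-q_i r^2/2}} cross at \eqn{r_c^2 = 2\ln(c_1/c_2)/(q_1 -
#' q_2)} when that is positive; the two radial pieces are closed-form erf
#' integrals and the angular sum runs over the quadrature grid. Equal-q
#' rays take the smaller prefactor throughout; with no positive crossing
#' the minimum at r to 0+ (smaller prefactor, then larger q) decides.
#'
#' @param U1,U2 3 x 3 SPD Cartesian tensors (A^2).
#' @param n_ang Angular grid size (one of [lebedev_sizes()]); the default
#'   5810 is effectively exact for these smooth integrands.
#' @return OC in (0, 1].
#' @export
overlap_coefficient <- function(U1, U2, n_ang = 5810L) {
  U1 <- .check_spd(U1, "U1"); U2 <- .check_spd(U2, "U2")
  c1 <- (2 * pi)^(-1.5) / sqrt(det(U1))
  c2 <- (2 * pi)^(-1.5) / sqrt(det(U2))
  I1 <- solve(U1); I2 <- solve(U2)
  g <- lebedev_angular(n_ang)
  u <- g$directions
  q1 <- rowSums((u %*% I1) * u)
  q2 <- rowSums((u %*% I2) * u)
  a1 <- q1 / 2; a2 <- q2 / 2
  # default: no crossing; integrate whichever profile is the minimum.
  # at r -> 0+ the smaller prefactor wins; for equal prefactors the
  # faster-decaying (larger q) profile is the minimum.
  first_is_min <- c1 < c2 | (c1 == c2 & q1 >= q2)
  radial <- ifelse(first_is_min, c1 * .radial_moment(a1),
                   c2 * .radial_moment(a2))
  dq <- q1 - q2
  rc2 <- ifelse(abs(dq) > 0, 2 * log(c1 / c2) / dq, -1)
  cross <- is.finite(rc2) & rc2 > 0
  if (any(cross)) {
    rc <- sqrt(rc2[cross])
    # inner piece: the profile that is the minimum near the origin
    inner_c <- ifelse(first_is_min[cross], c1, c2)
    inner_a <- ifelse(first_is_min[cross], a1[cross], a2[cross])
    outer_c <- ifelse(first_is_min[cross], c2, c1)
    outer_a <- ifelse(first_is_min[cross], a2[cross], a1[cross])
    radial[cross] <- inner_c * .radial_moment(inner_a, rc) +
      outer_c * (.radial_moment(outer_a) - .radial_moment(outer_a, rc))
  }
  sum(g$weights * radial)
}

#' Rescaled overlapping coefficient (percentage PDF difference)
#'
#' \eqn{\eta_r = 100 (1 - OC)}, equivalently 50 times the L1 distance of
#' the two PDFs.
#'
#' @inheritParams overlap_coefficient
#' @return Percentage in \[0, 100).
#' @export
eta_r <- function(U1, U2, n_ang = 5810L) {
  100 * (1 - overlap_coefficient(U1, U2, n_ang = n_ang))
}

#' Whitten-Spackman S12 similarity index
#'
#' Overlap of the square-rooted Gaussian PDFs in closed form:
#' \deqn{R_{12} = 2^{3/2}\,[\det(U_1^{-1})\det(U_2^{-1})]^{1/4} /
#' \det(U_1^{-1}+U_2^{-1})^{1/2}, \quad S_{12} = 100\,(1 - R_{12}).}
#' Zero iff the tensors are equal; invariant under a common rotation and
#' under swapping the arguments. For any SPD U, comparing U against 2U
#' gives the U-independent value \eqn{100(1 - 2^{9/4}/3^{3/2})}.
#'
#' @param U1,U2 3 x 3 SPD Cartesian tensors (A^2).
#' @return Index in \[0, 100).
#' @export
s12 <- function(U1, U2) {
  U1 <- .check_spd(U1, "U1"); U2 <- .check_spd(U2, "U2")
  I1 <- solve(U1); I2 <- solve(U2)
  r12 <- 2^1.5 * (det(I1) * det(I2))^0.25 / sqrt(det(I1 + I2))
  100 * (1 - r12)
}
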