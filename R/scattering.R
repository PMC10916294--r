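# Form factors. Two routes:
#   direct:    f(S) = sum_p w_p rho(r_p) exp(2 pi i S.r_p)   (grid sum)
#   multipole: f(S) = sum_lm 4 pi i^l h_lm(s) y_lm(S/s)
# where h_lm(s) = int rho_lm(r) j_l(2 pi s r) r^2 dr is a Hankel
# (Fourier-Bessel) transform evaluated on the radial quadrature. The i^l
# factor is accumulated as complex with even-l terms real and odd-l terms
# imaginary. Transfer onto a structure evaluates f at the rotated vector
# M S, M being the atom's local-frame matrix (rows = axes).

#' Spherical Bessel function j_l
#'
#' Stable evaluation via `besselJ(x, l + 1/2)` with a series expansion
#' \eqn{j_l(x) \approx x^l/(2l+1)!!\,(1 - x^2/(2(2l+3)))} near the origin
#' to avoid the 0/0 limit for l >= 1.
#'
#' @param l Non-negative integer order.
#' @param x Non-negative numeric vector.
#' @return j_l(x), same length as x.
#' @export
sph_bessel_j <- function(l, x) {
  x <- as.numeric(x)
  out <- numeric(length(x))
  small <- x < 1e-3
  if (any(small)) {
    dfact <- prod(seq(1, 2 * l + 1, by = 2))
    xs <- x[small]
    out[small] <- xs^l / dfact * (1 - xs^2 / (2 * (2 * l + 3)))
  }
  if (any(!small)) {
    xb <- x[!small]
    out[!small] <- sqrt(pi / (2 * xb)) * besselJ(xb, l + 0.5)
  }
  out
}

#' Direct grid-summation form factor
#'
#' \eqn{f(S) = \sum_p w_p \rho(r_p) e^{2\pi i S\cdot r_p}} over the atomic
#' grid points (atom-centred coordinates, so the phase origin is the atom).
#'
#' @param sampled A `tham_sampled_density`.
#' @param S A 3-vector or n x 3 matrix of scattering vectors (A^-1), in the
#'   same frame as the sampled grid.
#' @return Complex form-factor values (electrons).
#' @export
form_factor_direct <- function(sampled, S) {
  if (is.null(dim(S))) S <- matrix(S, 1, 3)
  phase <- sampled$grid$points %*% t(S)       # n_pts x n_S
  wv <- sampled$grid$weights * sampled$values
  as.vector(t(exp(2i * pi * phase)) %*% wv)
}

#' Hankel (Fourier-Bessel) transform of multipole radial rows
#'
#' \eqn{h_{lm}(s) = \sum_i w_i r_i^2 \rho_{lm}(r_i) j_l(2\pi s r_i)} for
#' every m of degree l.
#'
#' @param md A `tham_multipole_density`.
#' @param l Degree, `0 <= l <= md$L_max`.
#' @param s Scalar magnitude |S| (A^-1).
#' @return Numeric vector of length `2l + 1`, m from -l to l.
#' @export
hankel_transform <- function(md, l, s) {
  .assert(l >= 0 && l <= md$L_max, "invalid_parameter",
          "l must satisfy 0 <= l <= L_max")
  rg <- md$radial_grid
  jl <- sph_bessel_j(l, 2 * pi * s * rg$nodes)
  rows <- (l^2 + 1):((l + 1)^2)
  as.vector(md$coefficients[rows, , drop = FALSE] %*%
              (rg$weights * rg$nodes^2 * jl))
}

# all Hankel transforms for a vector of magnitudes: nlm x n_s matrix
.hankel_matrix <- function(md, s, L_max) {
  rg <- md$radial_grid
  wr2 <- rg$weights * rg$nodes^2
  H <- matrix(0, (L_max + 1L)^2, length(s))
  for (l in 0:L_max) {
    J <- vapply(s, function(ss) sph_bessel_j(l, 2 * pi * ss * rg$nodes),
                numeric(length(rg$nodes)))              # n_rad x n_s
    J <- matrix(J, nrow = length(rg$nodes))
    rows <- (l^2 + 1):((l + 1)^2)
    H[rows, ] <- md$coefficients[rows, , drop = FALSE] %*% (wr2 * J)
  }
  H
}

#' Form factor from the multipole representation
#'
#' \eqn{f(S) = \sum_{l \le L_{max}} \sum_m 4\pi\, i^l h_{lm}(s)
#' y_{lm}(\hat S)}. At s = 0 only the monopole contributes (the direction
#' is irrelevant there).
#'
#' @param md A `tham_multipole_density`.
#' @param S A 3-vector or n x 3 matrix of scattering vectors (A^-1), in the
#'   frame in which `md` is stored.
#' @param L_max Truncation degree (defaults to `md$L_max`; must not exceed
#'   it).
#' @return Complex form-factor values (electrons).
#' @export
form_factor_multipole <- function(md, S, L_max = md$L_max) {
  .assert(L_max <= md$L_max, "invalid_parameter",
          "L_max must not exceed the stored expansion degree")
  if (is.null(dim(S))) S <- matrix(S, 1, 3)
  s <- sqrt(rowSums(S^2))
  units <- S / pmax(s, .Machine$double.xmin)
  units[s == 0, ] <- rep(c(0, 0, 1), each = sum(s == 0))
  Y <- harmonic_table(L_max, units)          # nlm x n_S
  H <- .hankel_matrix(md, s, L_max)          # nlm x n_S
  idx <- harmonic_index(L_max)
  il <- (1i)^idx$l
  as.vector(colSums((4 * pi * il) * (H * Y)))
}

#' Rotate a scattering vector into a local frame
#'
#' @param S A 3-vector or n x 3 matrix (A^-1).
#' @param M 3 x 3 orthonormal matrix (rows = local axes).
#' @return Rotated vector(s) `S %*% t(M)` (i.e. M S per vector), same
#'   magnitude.
#' @export
rotate_scattering <- function(S, M) {
  .assert(max(abs(M %*% t(M) - diag(3))) < 1e-9, "invalid_parameter",
          "M must be orthonormal")
  drop_out <- is.null(dim(S))
  if (drop_out) S <- matrix(S, 1, 3)
  out <- S %*% t(M)
  if (drop_out) out <- as.vector(out)
  out
}
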