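# Real (tesseral) spherical harmonics, orthonormal over the unit sphere,
# WITHOUT the Condon-Shortley phase:
#   y_l0  = N_l0 P_l(cos th)
#   y_lm  = sqrt(2) N_lm P_l^m(cos th) cos(m phi),  m > 0
#   y_l-m = sqrt(2) N_lm P_l^m(cos th) sin(m phi),  m > 0
# with N_lm = sqrt((2l+1)/(4 pi) (l-m)!/(l+m)!). Evaluation uses the fully
# normalised associated-Legendre recurrences (stable for all l used here).

#' Canonical (l, m) index order
#'
#' Enumerates harmonic indices as l ascending, m from -l to l; the databank
#' file and [harmonic_table()] rows share this order.
#'
#' @param L_max Maximum degree (non-negative integer).
#' @return Data frame with integer columns `l` and `m`, `(L_max+1)^2` rows.
#' @export
harmonic_index <- function(L_max) {
  .assert(L_max >= 0, "invalid_parameter", "L_max must be >= 0")
  l <- unlist(lapply(0:L_max, function(li) rep(li, 2L * li + 1L)))
  m <- unlist(lapply(0:L_max, function(li) seq(-li, li)))
  data.frame(l = as.integer(l), m = as.integer(m))
}

# Core evaluator: units is an n x 3 matrix of unit vectors. Returns the
# ((L_max+1)^2) x n matrix of y_lm values in canonical row order.
.sph_harm_matrix <- function(L_max, units) {
  n <- nrow(units)
  x <- units[, 1]; y <- units[, 2]; z <- units[, 3]
  st <- sqrt(pmax(0, x^2 + y^2))
  # azimuth factors; direction at the pole is irrelevant (harmonics with
  # m != 0 carry a st^m factor that vanishes there)
  safe <- st > 0
  cp <- ifelse(safe, x / pmax(st, .Machine$double.xmin), 1)
  sp <- ifelse(safe, y / pmax(st, .Machine$double.xmin), 0)
  L <- as.integer(L_max)
  nlm <- (L + 1L)^2L
  out <- matrix(0, nlm, n)
  row_of <- function(l, m) l * (l + 1L) + m + 1L
  # Pbar[m+1, ] holds the fully normalised P-bar_l^m for the current l,
  # where P-bar_l^m = sqrt((2l+1)/(4pi) (l-m)!/(l+m)!) P_l^m(cos th)
  # cos(m phi), sin(m phi) by Chebyshev-style recurrence
  cosm <- matrix(0, L + 1L, n); sinm <- matrix(0, L + 1L, n)
  cosm[1, ] <- 1; sinm[1, ] <- 0
  if (L >= 1) {
    cosm[2, ] <- cp; sinm[2, ] <- sp
    if (L >= 2) for (m in 2:L) {
      cosm[m + 1, ] <- cp * cosm[m, ] - sp * sinm[m, ]
      sinm[m + 1, ] <- sp * cosm[m, ] + cp * sinm[m, ]
    }
  }
  pmm <- sqrt(1 / (4 * pi)) # P-bar_0^0
  Pprev <- matrix(0, L + 1L, n)  # l-1 block
  Pcurr <- matrix(0, L + 1L, n)  # l block
  for (l in 0:L) {
    Pnew <- matrix(0, L + 1L, n)
    if (l == 0) {
      Pnew[1, ] <- pmm
    } else {
      # diagonal term P-bar_l^l
      pmm <- pmm * sqrt((2 * l + 1) / (2 * l))
      Pnew[l + 1L, ] <- pmm * st^l
      # sub-diagonal P-bar_l^{l-1} from the previous diagonal
      Pnew[l, ] <- sqrt(2 * l + 1) * z * Pcurr[l, ]
      # general recurrence for m = 0 .. l-2
      if (l >= 2) for (m in 0:(l - 2)) {
        alm <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
        blm <- sqrt(((l - 1)^2 - m^2) / (4 * (l - 1)^2 - 1))
        Pnew[m + 1L, ] <- alm * (z * Pcurr[m + 1L, ] - blm * Pprev[m + 1L, ])
      }
    }
    # emit rows for this l
    out[row_of(l, 0L), ] <- Pnew[1, ]
    if (l >= 1) for (m in 1:l) {
      out[row_of(l, m), ] <- sqrt(2) * Pnew[m + 1L, ] * cosm[m + 1L, ]
      out[row_of(l, -m), ] <- sqrt(2) * Pnew[m + 1L, ] * sinm[m + 1L, ]
    }
    Pprev <- Pcurr
    Pcurr <- Pnew
  }
  out
}

#' Real spherical harmonic at a unit vector
#'
#' @param l Degree (non-negative integer).
#' @param m Order, `-l <= m <= l`.
#' @param u Unit 3-vector (must have norm 1 within 1e-9; callers normalise
#'   explicitly).
#' @return The orthonormal real harmonic value \eqn{y_{lm}(u)}.
#' @examples
#' real_sph_harm(0, 0, c(0, 0, 1))  # 1/sqrt(4*pi)
#' @export
real_sph_harm <- function(l, m, u) {
  .assert(abs(m) <= l, "invalid_parameter", "|m| must be <= l")
  .assert(abs(sqrt(sum(u^2)) - 1) < 1e-9, "invalid_parameter",
          "u must be a unit vector (normalise before calling)")
  Y <- .sph_harm_matrix(l, matrix(u, 1, 3))
  Y[l * (l + 1L) + m + 1L, 1]
}

#' Table of harmonics on an angular grid
#'
#' Precomputes \eqn{y_{lm}(u_p)} for all `(l, m)` up to `L_max` (canonical
#' row order) and every grid direction, for use in multipole projection and
#' reconstruction.
#'
#' @param L_max Maximum degree.
#' @param angular A `tham_angular_grid`, or an n x 3 matrix of unit vectors.
#' @return `(L_max+1)^2` x n numeric matrix.
#' @export
harmonic_table <- function(L_max, angular) {
  units <- if (inherits(angular, "tham_angular_grid")) angular$directions
           else as.matrix(angular)
  .assert(ncol(units) == 3, "invalid_parameter",
          "angular must provide n x 3 unit vectors")
  .sph_harm_matrix(L_max, units)
}
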