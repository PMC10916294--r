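#' Mura-Knowles radial quadrature grid
#'
#' Radial nodes and weights for integrals of the form
#' \eqn{\int_0^\infty g(r) r^2 dr \approx \sum_i w_i r_i^2 g(r_i)}.
#' Uses the "log3" mapping \eqn{r(x) = -\alpha \log(1 - x^3)} with uniform
#' abscissae \eqn{x_i = i/(n+1)}; weights carry the Jacobian
#' \eqn{dr/dx = 3\alpha x^2/(1-x^3)} and the uniform spacing
#' \eqn{\Delta x = 1/(n+1)}.
#'
#' @param n_points Number of radial nodes (at least 10).
#' @param scale Mapping scale \eqn{\alpha} in Angstrom (positive); larger
#'   values spread nodes to larger radii.
#' @return An object of class `tham_radial_grid` with fields `nodes`
#'   (strictly increasing radii, Angstrom), `weights` (positive, Angstrom)
#'   and `scale`.
#' @examples
#' g <- mura_knowles_radial(75, 5)
#' sum(g$weights * g$nodes^2 * exp(-g$nodes^2))  # ~ sqrt(pi)/4
#' @export
mura_knowles_radial <- function(n_points, scale = 5.0) {
  .assert(is.numeric(n_points) && length(n_points) == 1L && n_points >= 10,
          "invalid_parameter", "n_points must be a single integer >= 10")
  .assert(is.numeric(scale) && length(scale) == 1L && scale > 0,
          "invalid_parameter", "scale must be a single positive number")
  n <- as.integer(n_points)
  x <- seq_len(n) / (n + 1)
  nodes <- -scale * log1p(-x^3)
  jac <- 3 * scale * x^2 / (1 - x^3)
  weights <- jac / (n + 1)
  structure(list(nodes = nodes, weights = weights, scale = scale),
            class = "tham_radial_grid")
}

#' Default radial scale for an element
#'
#' Scales the 5 Angstrom carbon reference by the ratio of covalent radii,
#' clamped to \[2.5, 7.5\] Angstrom, so that compact (H) and diffuse atoms
#' are both well resolved by the same node count.
#'
#' @param element Element symbol.
#' @return Scale in Angstrom.
#' @export
default_radial_scale <- function(element) {
  s <- 5.0 * .covalent_radius(element) / .covalent_radius("C")
  min(max(s, 2.5), 7.5)
}

# Expand one octahedral symmetry orbit into unit vectors.
.gen_oh <- function(code, a = NA_real_, b = NA_real_) {
  if (code == 1L) {
    p <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else if (code == 2L) {
    q <- 1 / sqrt(2)
    p <- NULL
    for (i in 1:2) for (j in (i + 1):3) {
      if (j > 3) next
      for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
        v <- c(0, 0, 0); v[i] <- s1 * q; v[j] <- s2 * q
        p <- rbind(p, v)
      }
    }
  } else if (code == 3L) {
    q <- 1 / sqrt(3)
    p <- as.matrix(expand.grid(c(q, -q), c(q, -q), c(q, -q)))
  } else if (code == 4L) {
    bb <- sqrt(1 - 2 * a^2)
    p <- NULL
    for (posb in 1:3) {
      base <- c(a, a, a); base[posb] <- bb
      sg <- as.matrix(expand.grid(c(1, -1), c(1, -1), c(1, -1)))
      p <- rbind(p, sweep(sg, 2, base, `*`))
    }
  } else if (code == 5L) {
    bb <- sqrt(1 - a^2)
    p <- NULL
    for (pair in list(c(a, bb), c(bb, a))) {
      for (pos in list(c(1, 2), c(1, 3), c(2, 3))) {
        for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
          v <- c(0, 0, 0)
          v[pos[1]] <- s1 * pair[1]; v[pos[2]] <- s2 * pair[2]
          p <- rbind(p, v)
        }
      }
    }
  } else if (code == 6L) {
    cc <- sqrt(1 - a^2 - b^2)
    perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                  c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
    abc <- c(a, b, cc)
    p <- NULL
    sg <- as.matrix(expand.grid(c(1, -1), c(1, -1), c(1, -1)))
    for (pr in perms) p <- rbind(p, sweep(sg, 2, abc[pr], `*`))
  } else {
    .tham_error("internal", sprintf("unknown orbit code %d", code))
  }
  dimnames(p) <- NULL
  p
}

.lebedev_from_orbits <- function(orbits) {
  pts <- NULL
  w <- NULL
  for (o in orbits) {
    p <- .gen_oh(o$code, if (!is.null(o$a)) o$a else NA_real_,
                 if (!is.null(o$b)) o$b else NA_real_)
    pts <- rbind(pts, p)
    w <- c(w, rep(o$v, nrow(p)))
  }
  list(directions = pts, weights = 4 * pi * w)
}

# 5810-point product rule: Gauss-Legendre (70 nodes in cos(theta)) times a
# uniform 83-point azimuthal rule. Octahedral Lebedev constants for this
# size are not tabulated here; the product rule matches the point count,
# has positive weights summing to 4*pi, and integrates spherical-harmonic
# products exactly up to degree 82.
.product_rule_5810 <- function() {
  gl <- pracma::gaussLegendre(70, -1, 1)
  nphi <- 83L
  phi <- 2 * pi * (seq_len(nphi) - 1) / nphi
  ct <- rep(gl$x, each = nphi)
  st <- sqrt(pmax(0, 1 - ct^2))
  cp <- rep(cos(phi), times = 70)
  sp <- rep(sin(phi), times = 70)
  dirs <- cbind(st * cp, st * sp, ct)
  w <- rep(gl$w, each = nphi) * (2 * pi / nphi)
  list(directions = dirs, weights = w, degree = 82L)
}

#' Supported angular grid sizes
#'
#' @return Integer vector of point counts accepted by [lebedev_angular()].
#' @export
lebedev_sizes <- function() {
  c(as.integer(names(.lebedev_orbit_tables)), 5810L)
}

#' Angular quadrature grid on the unit sphere
#'
#' Sizes 6, 26, 110, 302 and 590 are the classical Lebedev-Laikov rules
#' (octahedrally symmetric, exact for spherical harmonics up to degree 3,
#' 7, 17, 29 and 41 respectively). Size 5810 is a Gauss-Legendre x uniform
#' azimuth product rule of the same point count, exact up to degree 82.
#' Weights sum to \eqn{4\pi}, so angular averages read as plain weighted
#' sums divided by \eqn{4\pi}.
#'
#' @param n_points One of [lebedev_sizes()].
#' @return An object of class `tham_angular_grid` with fields `directions`
#'   (n x 3 matrix of unit vectors), `weights` (summing to \eqn{4\pi}) and
#'   `degree` (polynomial exactness degree).
#' @examples
#' g <- lebedev_angular(302)
#' sum(g$weights)  # 4*pi
#' @export
lebedev_angular <- function(n_points) {
  n <- as.integer(n_points)
  key <- as.character(n)
  if (!is.null(.lebedev_orbit_tables[[key]])) {
    tab <- .lebedev_orbit_tables[[key]]
    g <- .lebedev_from_orbits(tab$orbits)
    deg <- tab$degree
  } else if (n == 5810L) {
    pr <- .product_rule_5810()
    g <- list(directions = pr$directions, weights = pr$weights)
    deg <- pr$degree
  } else {
    .tham_error("invalid_parameter",
                sprintf("unsupported angular grid size %d; supported: %s",
                        n, paste(lebedev_sizes(), collapse = ", ")))
  }
  structure(list(directions = g$directions, weights = g$weights,
                 degree = deg),
            class = "tham_angular_grid")
}

#' Product atomic integration grid
#'
#' Combines a radial and an angular grid into atom-centred 3D points
#' \eqn{r_i u_j} with weights \eqn{w_i r_i^2 w_j} so that
#' \eqn{\int \rho\, d^3r \approx \sum_p w_p \rho(r_p)}. Point ordering is
#' radial-major: point `(i-1)*n_ang + j` is node i along direction j.
#'
#' @param radial A `tham_radial_grid`.
#' @param angular A `tham_angular_grid`.
#' @return An object of class `tham_atomic_grid` with `points` (n x 3,
#'   Angstrom), `weights` (Angstrom^3), `n_rad`, `n_ang`, and the two
#'   parent grids.
#' @examples
#' g <- atomic_grid(mura_knowles_radial(75, 5), lebedev_angular(110))
#' sum(g$weights * exp(-rowSums(g$points^2)) / pi^1.5)  # ~ 1
#' @export
atomic_grid <- function(radial, angular) {
  .assert(inherits(radial, "tham_radial_grid"), "invalid_parameter",
          "radial must be a tham_radial_grid")
  .assert(inherits(angular, "tham_angular_grid"), "invalid_parameter",
          "angular must be a tham_angular_grid")
  n_rad <- length(radial$nodes)
  n_ang <- nrow(angular$directions)
  r <- rep(radial$nodes, each = n_ang)
  pts <- angular$directions[rep(seq_len(n_ang), times = n_rad), , drop = FALSE] * r
  w <- rep(radial$weights * radial$nodes^2, each = n_ang) *
    rep(angular$weights, times = n_rad)
  structure(list(points = pts, weights = w, n_rad = n_rad, n_ang = n_ang,
                 radial = radial, angular = angular),
            class = "tham_atomic_grid")
}
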