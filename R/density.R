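# Analytic model electron densities: spherical reference atoms written as
# sums of Gaussians plus bond-centred Gaussian deformation lobes. Every
# term has a closed-form Fourier transform, which makes each downstream
# stage (partition, projection, Hankel transform, transfer) exactly
# testable against the analytic molecular transform.
#
# Units: Angstrom for lengths, Angstrom^-2 for Gaussian exponents,
# e * Angstrom^-3 for densities, Angstrom^-1 for |S|. Fourier convention
# F(S) = integral rho(r) exp(+2 pi i S.r) d^3r throughout the package.

# run code with a private RNG stream, leaving the caller's RNG untouched
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Synthetic spherical reference atoms (not fits to any tabulated
# wavefunction): soft-core pseudoatoms. Shell exponents keep core and
# valence length scales element-ordered while staying soft enough that a
# 75-node radial grid resolves every shell and valence/deformation
# features are not numerically swamped by a near-singular core; the total
# integrates exactly to the neutral electron count.
.atom_shells <- list(
  H = data.frame(frac = c(0.40, 0.60),        alpha = c(6.0, 1.2)),
  C = data.frame(frac = c(2, 2, 2) / 6,       alpha = c(14, 5.0, 1.5)),
  N = data.frame(frac = c(2, 2.5, 2.5) / 7,   alpha = c(13, 5.0, 1.65)),
  O = data.frame(frac = c(2, 3, 3) / 8,       alpha = c(12, 5.0, 1.8))
)

#' Spherical reference atom density
#'
#' Returns the Gaussian expansion \eqn{\rho(r) = \sum_k c_k e^{-\alpha_k r^2}}
#' of the synthetic neutral spherical atom used both as promolecule
#' reference for Hirshfeld weights and as the spherical part of fixture
#' densities. Coefficients satisfy
#' \eqn{\sum_k c_k (\pi/\alpha_k)^{3/2} = Z} exactly.
#'
#' @param element Element symbol.
#' @return List with `element`, `terms` (data frame `c`, `alpha`) and
#'   `electron_count`.
#' @export
spherical_atom <- function(element) {
  z <- .atomic_number(element)
  sh <- .atom_shells[[element]]
  if (is.null(sh)) {
    # generic three-shell fallback scaled by covalent radius
    sc <- (.covalent_radius("C") / .covalent_radius(element))^2
    sh <- data.frame(frac = c(0.3, 0.35, 0.35), alpha = c(45, 8, 1.6) * sc)
  }
  cc <- sh$frac * z * (sh$alpha / pi)^1.5
  terms <- data.frame(c = cc, alpha = sh$alpha)
  list(element = element, terms = terms,
       electron_count = sum(terms$c * (pi / terms$alpha)^1.5))
}

#' Assemble a density specification
#'
#' @param elements Character vector of element symbols.
#' @param positions n x 3 matrix of Cartesian coordinates (Angstrom).
#' @param deformations Data frame with columns `cx`, `cy`, `cz` (centre,
#'   Angstrom), `amplitude` (e/A^3, may be negative) and `exponent`
#'   (A^-2, positive); or NULL.
#' @param cell Optional cell parameters `c(a, b, c, alpha, beta, gamma)`.
#' @param name Optional identifier.
#' @return Object of class `tham_density_spec`.
#' @export
density_spec <- function(elements, positions, deformations = NULL,
                         cell = NULL, name = "spec") {
  positions <- as.matrix(positions)
  .assert(nrow(positions) == length(elements) && ncol(positions) == 3,
          "invalid_parameter", "positions must be length(elements) x 3")
  atoms <- lapply(seq_along(elements), function(i) {
    sa <- spherical_atom(elements[i])
    list(element = elements[i], position = positions[i, ], terms = sa$terms,
         electron_count = sa$electron_count)
  })
  if (is.null(deformations)) {
    deformations <- data.frame(cx = numeric(0), cy = numeric(0),
                               cz = numeric(0), amplitude = numeric(0),
                               exponent = numeric(0))
  }
  .assert(all(deformations$exponent > 0), "invalid_parameter",
          "deformation exponents must be positive")
  structure(list(name = name, atoms = atoms, deformations = deformations,
                 cell = cell),
            class = "tham_density_spec")
}

#' Total electron count of a spec
#'
#' Sum of atomic electron counts and deformation-lobe integrals (each lobe
#' integrates to \eqn{A (\pi/\beta)^{3/2}}).
#' @param spec A `tham_density_spec`.
#' @return Electron count (may be non-integer; lobes carry charge).
#' @export
total_electron_count <- function(spec) {
  sum(vapply(spec$atoms, `[[`, 0, "electron_count")) +
    sum(spec$deformations$amplitude * (pi / spec$deformations$exponent)^1.5)
}

# positions as n x 3 matrix
.spec_positions <- function(spec) {
  do.call(rbind, lapply(spec$atoms, `[[`, "position"))
}

#' @export
print.tham_density_spec <- function(x, ...) {
  cat(sprintf("tham density spec '%s': %d atoms (%s), %d deformation lobes, %.4f e total\n",
              x$name, length(x$atoms),
              paste(vapply(x$atoms, `[[`, "", "element"), collapse = " "),
              nrow(x$deformations), total_electron_count(x)))
  invisible(x)
}

# spherical density of one atom at a matrix of points
.atom_density_at <- function(atom, points) {
  d2 <- rowSums(sweep(points, 2, atom$position)^2)
  v <- 0
  for (k in seq_len(nrow(atom$terms)))
    v <- v + atom$terms$c[k] * exp(-atom$terms$alpha[k] * d2)
  v
}

#' Evaluate the total model density
#'
#' @param spec A `tham_density_spec`.
#' @param points A 3-vector or n x 3 matrix of Cartesian points (Angstrom).
#' @return Density values, e/A^3 (vector of length n).
#' @export
evaluate_total_density <- function(spec, points) {
  if (is.null(dim(points))) points <- matrix(points, 1, 3)
  v <- 0
  for (atom in spec$atoms) v <- v + .atom_density_at(atom, points)
  df <- spec$deformations
  for (k in seq_len(nrow(df))) {
    d2 <- rowSums(sweep(points, 2, c(df$cx[k], df$cy[k], df$cz[k]))^2)
    v <- v + df$amplitude[k] * exp(-df$exponent[k] * d2)
  }
  v
}

# promolecule per-atom spherical densities: n_points x n_atoms matrix
.promolecule_matrix <- function(spec, points) {
  m <- vapply(spec$atoms, .atom_density_at, numeric(nrow(points)),
              points = points)
  matrix(m, nrow = nrow(points))
}

#' Hirshfeld stockholder weight of one atom
#'
#' Weight \eqn{w_a(r) = \rho_a^{sph}(r - R_a) / \sum_b \rho_b^{sph}(r - R_b)}
#' built from the spherical atomic terms only; deformation lobes belong to
#' the partitioned total density, not to the promolecule reference.
#' Where the promolecule vanishes (numerically zero) the weight is 0.
#'
#' @param spec A `tham_density_spec`.
#' @param atom_index 1-based atom index.
#' @param points A 3-vector or n x 3 matrix (Angstrom).
#' @return Weights in \[0, 1\].
#' @export
hirshfeld_weight <- function(spec, atom_index, points) {
  if (is.null(dim(points))) points <- matrix(points, 1, 3)
  pm <- .promolecule_matrix(spec, points)
  tot <- rowSums(pm)
  w <- ifelse(tot > 0, pm[, atom_index] / pmax(tot, .Machine$double.xmin), 0)
  w
}

#' Hirshfeld atomic density sampled on an oriented atomic grid
#'
#' Evaluates \eqn{w_a(r)\,\rho_{tot}(r)} at grid points expressed in the
#' atom's local frame: a local grid point p corresponds to the global point
#' \eqn{R_a + M^T p} where the rows of `frame` are the local axes. The
#' weighted sum over the grid is the Hirshfeld electron population.
#'
#' @param spec A `tham_density_spec`.
#' @param atom_index 1-based atom index.
#' @param grid A `tham_atomic_grid`.
#' @param frame 3 x 3 orthonormal matrix (rows = local axes); identity by
#'   default.
#' @return Object of class `tham_sampled_density`: `values` at grid points,
#'   the `grid`, `frame`, `element`, and `population` (weighted sum).
#' @export
atomic_density_on_grid <- function(spec, atom_index, grid,
                                   frame = diag(3)) {
  .assert(max(abs(frame %*% t(frame) - diag(3))) < 1e-9, "invalid_parameter",
          "frame must be orthonormal")
  ra <- spec$atoms[[atom_index]]$position
  global <- sweep(grid$points %*% frame, 2, ra, `+`)
  vals <- hirshfeld_weight(spec, atom_index, global) *
    evaluate_total_density(spec, global)
  structure(list(values = vals, grid = grid, frame = frame,
                 element = spec$atoms[[atom_index]]$element,
                 atom_index = atom_index,
                 population = sum(grid$weights * vals)),
            class = "tham_sampled_density")
}

#' Closed-form molecular structure factor of a spec
#'
#' Every density term is a Gaussian, so
#' \eqn{F(S) = \sum_t c_t (\pi/\alpha_t)^{3/2} e^{-\pi^2 s^2/\alpha_t}
#' e^{2\pi i S\cdot r_t}} exactly (convention
#' \eqn{F(S)=\int \rho\, e^{2\pi i S\cdot r} d^3r}).
#'
#' @param spec A `tham_density_spec`.
#' @param S A 3-vector or n x 3 matrix of scattering vectors (A^-1).
#' @return Complex vector of structure-factor values (electrons).
#' @export
analytic_molecular_ff <- function(spec, S) {
  if (is.null(dim(S))) S <- matrix(S, 1, 3)
  s2 <- rowSums(S^2)
  F <- complex(real = rep(0, nrow(S)))
  add_term <- function(F, cc, alpha, centre) {
    F + cc * (pi / alpha)^1.5 * exp(-pi^2 * s2 / alpha) *
      exp(2i * pi * as.vector(S %*% centre))
  }
  for (atom in spec$atoms)
    for (k in seq_len(nrow(atom$terms)))
      F <- add_term(F, atom$terms$c[k], atom$terms$alpha[k], atom$position)
  df <- spec$deformations
  for (k in seq_len(nrow(df)))
    F <- add_term(F, df$amplitude[k], df$exponent[k],
                  c(df$cx[k], df$cy[k], df$cz[k]))
  F
}
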