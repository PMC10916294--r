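# Packaged synthetic molecular fixtures. These stand in for the molecular
# electron densities that a quantum-chemistry program would provide: toy
# water / ethanol / urea topologies with chemically sensible geometries,
# spherical reference atoms, and bond-centred Gaussian deformation lobes
# that make the Hirshfeld atoms genuinely aspherical. All amplitudes are
# drawn deterministically from the seed; geometry is fixed.

.fixture_geometries <- list(
  "water-like" = list(
    # exactly C2v-symmetric: O-H 0.9572 A, H-O-H 104.52 degrees
    elements = c("O", "H", "H"),
    positions = rbind(c(0, 0, 0),
                      0.9572 * c(cos(52.26 * pi / 180),
                                 sin(52.26 * pi / 180), 0),
                      0.9572 * c(cos(52.26 * pi / 180),
                                 -sin(52.26 * pi / 180), 0))
  ),
  "ethanol-like" = list(
    elements = c("C", "C", "O", "H", "H", "H", "H", "H", "H"),
    positions = rbind(c(0.000, 0.000, 0.000),    # C1
                      c(1.520, 0.000, 0.000),    # C2
                      c(2.030, 1.330, 0.000),    # O
                      c(2.980, 1.360, 0.000),    # H-O
                      c(-0.363, 1.028, 0.000),   # H-C1
                      c(-0.363, -0.514, 0.890),  # H-C1
                      c(-0.363, -0.514, -0.890), # H-C1
                      c(1.883, -0.514, 0.890),   # H-C2
                      c(1.883, -0.514, -0.890))  # H-C2
  ),
  "urea-like" = list(
    elements = c("C", "O", "N", "N", "H", "H", "H", "H"),
    positions = rbind(c(0, 0, 0),
                      c(0, 1.220, 0),
                      c(1.160, -0.660, 0),
                      c(-1.160, -0.660, 0),
                      c(2.110, -0.250, 0),
                      c(1.200, -1.670, 0),
                      c(-2.110, -0.250, 0),
                      c(-1.200, -1.670, 0))
  )
)

#' Names of the packaged fixtures
#' @return Character vector of identifiers accepted by [make_fixture()].
#' @export
fixture_names <- function() names(.fixture_geometries)

#' Build a synthetic molecular density fixture
#'
#' Deterministic for a given `(name, seed)` pair: atoms sit at a fixed toy
#' geometry; every detected bond receives a Gaussian deformation lobe at
#' its midpoint with exponent 3 A^-2 and an amplitude equal to a common
#' per-fixture fraction (drawn uniformly from 5-15 percent) of the local
#' promolecule density there -- the scale at which real bonding
#' deformation densities sit. A single shared fraction keeps
#' symmetry-equivalent bonds equivalent, so the molecular point symmetry
#' of the toy geometries survives in the deformation density. Lobes are
#' positive, so the total density is positive everywhere by construction
#' (still validated on the atomic grids at build time).
#'
#' @param name One of [fixture_names()].
#' @param seed Integer seed controlling lobe amplitudes.
#' @return A `tham_density_spec`.
#' @examples
#' spec <- make_fixture("water-like", 0)
#' total_electron_count(spec)
#' @export
make_fixture <- function(name, seed = 0L) {
  geo <- .fixture_geometries[[name]]
  if (is.null(geo)) {
    .tham_error("invalid_parameter",
                sprintf("unknown fixture '%s'; available: %s", name,
                        paste(fixture_names(), collapse = ", ")))
  }
  bonds <- .bonds_from_coords(geo$elements, geo$positions)
  lobes <- .with_seed(as.integer(seed) * 997L + 13L, {
    if (nrow(bonds) == 0) NULL else {
      bare <- density_spec(geo$elements, geo$positions, name = name)
      frac <- runif(1, 0.05, 0.15)
      do.call(rbind, lapply(seq_len(nrow(bonds)), function(k) {
        i <- bonds$i[k]; j <- bonds$j[k]
        mid <- (geo$positions[i, ] + geo$positions[j, ]) / 2
        promol <- evaluate_total_density(bare, mid)
        data.frame(cx = mid[1], cy = mid[2], cz = mid[3],
                   amplitude = frac * promol,
                   exponent = 3.0)
      }))
    }
  })
  spec <- density_spec(geo$elements, geo$positions, deformations = lobes,
                       name = name)
  .validate_spec_positivity(spec)
  spec
}

# total density must be non-negative on every atom's default grid
.validate_spec_positivity <- function(spec) {
  ang <- lebedev_angular(110)
  for (i in seq_along(spec$atoms)) {
    el <- spec$atoms[[i]]$element
    g <- atomic_grid(mura_knowles_radial(40, default_radial_scale(el)), ang)
    pts <- sweep(g$points, 2, spec$atoms[[i]]$position, `+`)
    .assert(min(evaluate_total_density(spec, pts)) >= 0,
            "invalid_density",
            sprintf("total density of '%s' is negative near atom %d",
                    spec$name, i))
  }
  invisible(spec)
}

#' Write / read a density spec as JSON
#'
#' Plain-text serialisation so tests and command-line demos can share
#' inputs. Schema: `name`, `elements`, `positions` (n x 3), `deformations`
#' (records with `cx, cy, cz, amplitude, exponent`), optional `cell`.
#'
#' @param spec A `tham_density_spec`.
#' @param path Output file.
#' @return `read_density_spec` returns a `tham_density_spec`;
#'   `write_density_spec` returns `path` invisibly.
#' @export
write_density_spec <- function(spec, path) {
  obj <- list(name = spec$name,
              elements = vapply(spec$atoms, `[[`, "", "element"),
              positions = .spec_positions(spec),
              deformations = spec$deformations,
              cell = spec$cell)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_density_spec
#' @export
read_density_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  density_spec(obj$elements, matrix(unlist(obj$positions), ncol = 3),
               deformations = if (length(obj$deformations))
                 as.data.frame(obj$deformations) else NULL,
               cell = obj$cell, name = obj$name)
}
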