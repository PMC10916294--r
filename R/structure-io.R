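# Minimal crystal-structure container and text I/O. Supported inputs: a
# small CIF subset (cell, P1 symmetry, atom_site loop with fractional
# coordinates, optional aniso U loop) and XYZ files with a cell on the
# comment line. Orthogonalisation convention: a along x, b in the xy
# plane; the same matrix is used for ADP conversion.

#' Crystal structure container
#'
#' @param cell Numeric `c(a, b, c, alpha, beta, gamma)` (Angstrom, degrees).
#' @param labels Unique atom labels.
#' @param elements Element symbols.
#' @param frac n x 3 matrix of fractional coordinates.
#' @param u_aniso Optional named list of 3 x 3 crystallographic U tensors
#'   (keys = labels).
#' @return Object of class `tham_structure` (spacegroup fixed at P1).
#' @export
crystal_structure <- function(cell, labels, elements, frac, u_aniso = NULL) {
  .assert(length(cell) == 6 && all(is.finite(cell)), "invalid_parameter",
          "cell must be c(a, b, c, alpha, beta, gamma)")
  .assert(!anyDuplicated(labels), "invalid_parameter",
          "atom labels must be unique")
  frac <- as.matrix(frac)
  .assert(all(is.finite(frac)) && ncol(frac) == 3, "invalid_parameter",
          "fractional coordinates must be a finite n x 3 matrix")
  for (el in elements) element_info(el)  # errors on unknown symbols
  st <- structure(list(cell = as.numeric(cell), labels = as.character(labels),
                       elements = as.character(elements), frac = frac,
                       u_aniso = u_aniso, spacegroup = "P 1"),
                  class = "tham_structure")
  .assert(cell_volume(st) > 0, "invalid_parameter", "cell volume must be > 0")
  st
}

#' Orthogonalisation matrix (fractional to Cartesian)
#'
#' Columns are the cell vectors in Cartesian coordinates with a along x
#' and b in the xy plane; `cart = frac %*% t(M)`.
#'
#' @param cell `c(a, b, c, alpha, beta, gamma)` or a `tham_structure`.
#' @return 3 x 3 matrix.
#' @export
orthogonalization_matrix <- function(cell) {
  if (inherits(cell, "tham_structure")) cell <- cell$cell
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  cx <- cc * cos(be)
  cy <- cc * (cos(al) - cos(be) * cos(ga)) / sin(ga)
  cz <- sqrt(pmax(0, cc^2 - cx^2 - cy^2))
  cbind(c(a, 0, 0),
        c(b * cos(ga), b * sin(ga), 0),
        c(cx, cy, cz))
}

#' Cell volume
#' @param x Cell parameters or a `tham_structure`.
#' @return Volume in Angstrom^3.
#' @export
cell_volume <- function(x) det(orthogonalization_matrix(x))

#' Cartesian coordinates of a structure
#' @param st A `tham_structure`.
#' @return n x 3 matrix (Angstrom).
#' @export
cartesian_coords <- function(st) {
  st$frac %*% t(orthogonalization_matrix(st))
}

#' Reciprocal cell vectors
#' @param cell Cell parameters or a `tham_structure`.
#' @return 3 x 3 matrix whose rows are a*, b*, c* (A^-1);
#'   `S = h a* + k b* + l c*`.
#' @export
reciprocal_matrix <- function(cell) {
  t(solve(orthogonalization_matrix(cell)))
}

#' Convert a crystallographic aniso U tensor to Cartesian
#'
#' \eqn{U_{cart} = A N U_{cif} N A^T} with A the orthogonalisation matrix
#' and \eqn{N = diag(a^*, b^*, c^*)} (the standard convention for
#' `_atom_site_aniso_U` tensors).
#'
#' @param u_cif Symmetric 3 x 3 tensor in the crystallographic basis.
#' @param cell Cell parameters or a `tham_structure`.
#' @return 3 x 3 Cartesian tensor (A^2).
#' @export
u_cif_to_cart <- function(u_cif, cell) {
  A <- orthogonalization_matrix(cell)
  rec <- reciprocal_matrix(cell)
  N <- diag(sqrt(rowSums(rec^2)))
  M <- A %*% N
  M %*% u_cif %*% t(M)
}

# ---- CIF ----

.cif_loop <- function(lines, i) {
  # parse a loop_ starting at line i; returns list(headers, rows, next_i)
  stopifnot(grepl("^\\s*loop_", lines[i]))
  i <- i + 1
  headers <- character(0)
  while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
    headers <- c(headers, trimws(lines[i]))
    i <- i + 1
  }
  rows <- list()
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || grepl("^(_|loop_|#|data_)", ln)) break
    rows[[length(rows) + 1L]] <- scan(text = ln, what = "", quiet = TRUE)
    i <- i + 1
  }
  list(headers = headers, rows = rows, next_i = i)
}

#' Read a structure from CIF or XYZ+cell
#'
#' CIF support is deliberately minimal: cell parameters, P1 symmetry (any
#' other `_symmetry_space_group_name` is an error), an `atom_site` loop
#' with `label`, `type_symbol` and fractional coordinates, and an optional
#' `atom_site_aniso` loop with the six `U_ij` components. XYZ files must
#' carry `cell: a b c alpha beta gamma` on the comment line; coordinates
#' are Cartesian Angstrom.
#'
#' @param path Input file; format chosen by extension (`.cif` or `.xyz`).
#' @return A `tham_structure`.
#' @export
read_structure <- function(path) {
  .assert(file.exists(path), "io", sprintf("file not found: %s", path))
  if (grepl("\\.xyz$", path, ignore.case = TRUE)) return(.read_xyz_cell(path))
  lines <- readLines(path, warn = FALSE)
  num <- function(pat) {
    ln <- grep(pat, lines, value = TRUE)
    if (!length(ln)) return(NA_real_)
    as.numeric(sub("^\\S+\\s+", "", trimws(ln[1])))
  }
  cell <- c(num("^\\s*_cell_length_a\\b"), num("^\\s*_cell_length_b\\b"),
            num("^\\s*_cell_length_c\\b"), num("^\\s*_cell_angle_alpha\\b"),
            num("^\\s*_cell_angle_beta\\b"), num("^\\s*_cell_angle_gamma\\b"))
  .assert(all(is.finite(cell)), "io", "CIF is missing cell parameters")
  sg <- grep("_symmetry_space_group_name|_space_group_name", lines,
             value = TRUE)
  if (length(sg)) {
    val <- gsub("['\"]", "", sub("^\\s*\\S+\\s+", "", sg[1]))
    .assert(gsub("\\s", "", val) == "P1", "io",
            sprintf("only P1 symmetry is supported (got '%s')", trimws(val)))
  }
  labels <- elements <- character(0)
  frac <- NULL
  u_aniso <- NULL
  i <- 1
  while (i <= length(lines)) {
    if (grepl("^\\s*loop_", lines[i])) {
      lp <- .cif_loop(lines, i)
      hs <- lp$headers
      if (any(grepl("^_atom_site_fract_x", hs))) {
        cols <- match(c("_atom_site_label", "_atom_site_type_symbol",
                        "_atom_site_fract_x", "_atom_site_fract_y",
                        "_atom_site_fract_z"), hs)
        .assert(!any(is.na(cols)), "io",
                "atom_site loop must contain label, type_symbol and fract_x/y/z")
        for (r in lp$rows) {
          labels <- c(labels, r[cols[1]])
          elements <- c(elements, r[cols[2]])
          frac <- rbind(frac, as.numeric(r[cols[3:5]]))
        }
      } else if (any(grepl("^_atom_site_aniso_label", hs))) {
        cols <- match(c("_atom_site_aniso_label",
                        "_atom_site_aniso_U_11", "_atom_site_aniso_U_22",
                        "_atom_site_aniso_U_33", "_atom_site_aniso_U_12",
                        "_atom_site_aniso_U_13", "_atom_site_aniso_U_23"), hs)
        .assert(!any(is.na(cols)), "io",
                "aniso loop must contain label and U_11..U_23")
        u_aniso <- list()
        for (r in lp$rows) {
          u <- as.numeric(r[cols[2:7]])
          u_aniso[[r[cols[1]]]] <- matrix(c(u[1], u[4], u[5],
                                            u[4], u[2], u[6],
                                            u[5], u[6], u[3]), 3, 3)
        }
      }
      i <- lp$next_i
    } else i <- i + 1
  }
  .assert(length(labels) > 0, "io", "CIF contains no atom_site loop")
  if (!is.null(u_aniso)) {
    orphan <- setdiff(names(u_aniso), labels)
    .assert(length(orphan) == 0, "io",
            sprintf("aniso labels with no matching atom_site: %s",
                    paste(orphan, collapse = ", ")))
  }
  crystal_structure(cell, labels, elements, frac, u_aniso)
}

.read_xyz_cell <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[1]))
  m <- regmatches(lines[2], regexec(
    "cell:\\s*([-0-9.eE ]+)", lines[2]))[[1]]
  .assert(length(m) == 2, "io",
          "XYZ comment line must contain 'cell: a b c alpha beta gamma'")
  cell <- as.numeric(scan(text = m[2], what = "", quiet = TRUE))
  .assert(length(cell) == 6, "io", "cell: needs six numbers")
  elements <- character(n); cart <- matrix(0, n, 3)
  for (k in seq_len(n)) {
    f <- scan(text = lines[2 + k], what = "", quiet = TRUE)
    elements[k] <- f[1]; cart[k, ] <- as.numeric(f[2:4])
  }
  frac <- cart %*% t(solve(orthogonalization_matrix(cell)))
  crystal_structure(cell, paste0(elements, seq_len(n)), elements, frac)
}

#' Write a structure to a minimal CIF
#'
#' @param st A `tham_structure`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cif <- function(st, path) {
  out <- c("data_tham",
           sprintf("_cell_length_a  %.6f", st$cell[1]),
           sprintf("_cell_length_b  %.6f", st$cell[2]),
           sprintf("_cell_length_c  %.6f", st$cell[3]),
           sprintf("_cell_angle_alpha  %.6f", st$cell[4]),
           sprintf("_cell_angle_beta   %.6f", st$cell[5]),
           sprintf("_cell_angle_gamma  %.6f", st$cell[6]),
           "_symmetry_space_group_name_H-M  'P 1'",
           "loop_",
           "_atom_site_label",
           "_atom_site_type_symbol",
           "_atom_site_fract_x",
           "_atom_site_fract_y",
           "_atom_site_fract_z",
           sprintf("%s %s %.9f %.9f %.9f", st$labels, st$elements,
                   st$frac[, 1], st$frac[, 2], st$frac[, 3]))
  if (!is.null(st$u_aniso) && length(st$u_aniso)) {
    rows <- vapply(names(st$u_aniso), function(lb) {
      u <- st$u_aniso[[lb]]
      sprintf("%s %.9f %.9f %.9f %.9f %.9f %.9f", lb,
              u[1, 1], u[2, 2], u[3, 3], u[1, 2], u[1, 3], u[2, 3])
    }, "")
    out <- c(out, "loop_",
             "_atom_site_aniso_label",
             "_atom_site_aniso_U_11", "_atom_site_aniso_U_22",
             "_atom_site_aniso_U_33", "_atom_site_aniso_U_12",
             "_atom_site_aniso_U_13", "_atom_site_aniso_U_23",
             rows)
  }
  writeLines(out, path)
  invisible(path)
}

#' Embed a density spec in a P1 box
#'
#' Gives a fixture a crystal-structure carrier: the molecule is placed in
#' an orthorhombic P1 cell (bounding box plus `margin` on each side) so
#' reflection lists and tsc tables can be generated for it.
#'
#' @param spec A `tham_density_spec`.
#' @param margin Padding around the bounding box (Angstrom).
#' @return A `tham_structure` whose Cartesian coordinates equal the spec's.
#' @export
spec_structure <- function(spec, margin = 6) {
  pos <- .spec_positions(spec)
  lo <- apply(pos, 2, min) - margin
  span <- apply(pos, 2, max) - lo + margin
  cell <- c(span, 90, 90, 90)
  frac <- sweep(pos, 2, lo) %*% diag(1 / span)
  elements <- vapply(spec$atoms, `[[`, "", "element")
  crystal_structure(cell, paste0(elements, seq_along(elements)),
                    elements, frac)
}

#' Generate a reflection list to a resolution cutoff
#'
#' All integer (h, k, l) with \eqn{|S| \le 1/d_{min}} where
#' `S = h a* + k b* + l c*`; the origin (0,0,0) is excluded. The full
#' sphere is returned unless `friedel = TRUE`, which keeps one member of
#' each Friedel pair (f(-S) is the conjugate of f(S)).
#'
#' @param cell Cell parameters or a `tham_structure`.
#' @param d_min Resolution cutoff (Angstrom, > 0).
#' @param friedel Keep only one hemisphere.
#' @return Object of class `tham_reflections`: data frame `hkl` and n x 3
#'   matrix `S` (A^-1).
#' @export
generate_hkl <- function(cell, d_min, friedel = FALSE) {
  .assert(is.numeric(d_min) && d_min > 0, "invalid_parameter",
          "d_min must be positive")
  rec <- reciprocal_matrix(cell)
  A <- orthogonalization_matrix(if (inherits(cell, "tham_structure"))
    cell$cell else cell)
  smax <- 1 / d_min
  # |h| = |S . a| <= smax * a, likewise for k, l
  lims <- ceiling(smax * sqrt(colSums(A^2)))
  .assert(prod(2 * lims + 1) <= 1e7, "invalid_parameter",
          sprintf("d_min = %g generates over 1e7 candidate reflections; use a coarser cutoff",
                  d_min))
  g <- as.matrix(expand.grid(h = -lims[1]:lims[1], k = -lims[2]:lims[2],
                             l = -lims[3]:lims[3]))
  S <- g %*% rec
  keep <- rowSums(S^2) <= smax^2 + 1e-12
  keep[rowSums(abs(g)) == 0] <- FALSE
  if (friedel) {
    pos <- g[, 1] > 0 | (g[, 1] == 0 & g[, 2] > 0) |
      (g[, 1] == 0 & g[, 2] == 0 & g[, 3] > 0)
    keep <- keep & pos
  }
  hkl <- as.data.frame(g[keep, , drop = FALSE])
  rownames(hkl) <- NULL
  structure(list(hkl = hkl, S = S[keep, , drop = FALSE]),
            class = "tham_reflections")
}
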