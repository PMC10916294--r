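# Atom typing, local coordinate frames, per-type averaging and the text
# databank. Typing is intentionally simple: element plus the sorted
# multiset of bonded-neighbour elements (bonds from covalent radii x 1.3).
# Each type carries a local-frame definition made of two element
# selectors; frames are built from bonded (then second-shell) neighbours,
# so they rotate rigidly with the molecule and the stored density can be
# transferred as f(M S).

# Accept a tham_structure or a tham_density_spec anywhere a molecule is
# needed: elements + Cartesian coordinates + labels.
.as_molecule <- function(x) {
  if (inherits(x, "tham_density_spec")) {
    elements <- vapply(x$atoms, `[[`, "", "element")
    list(elements = elements, cart = .spec_positions(x),
         labels = paste0(elements, seq_along(elements)))
  } else if (inherits(x, "tham_structure")) {
    list(elements = x$elements, cart = cartesian_coords(x),
         labels = x$labels)
  } else {
    .tham_error("invalid_parameter",
                "expected a tham_structure or tham_density_spec")
  }
}

.bonds_from_coords <- function(elements, cart) {
  n <- length(elements)
  out <- data.frame(i = integer(0), j = integer(0), d = numeric(0))
  if (n < 2) return(out)
  rc <- vapply(elements, .covalent_radius, 0)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((cart[i, ] - cart[j, ])^2))
    .assert(d > 0.4, "invalid_geometry",
            sprintf("atoms %d and %d are only %.3f A apart", i, j, d))
    if (d < 1.3 * (rc[i] + rc[j])) {
      out <- rbind(out, data.frame(i = i, j = j, d = d))
    }
  }
  out
}

#' Detect covalent bonds
#'
#' Two atoms are bonded when their distance is below 1.3 times the sum of
#' their covalent radii. Distances under 0.4 Angstrom are rejected as
#' overlapping atoms.
#'
#' @param x A `tham_structure` or `tham_density_spec`.
#' @return Adjacency list: for each atom, the integer indices of its
#'   bonded neighbours.
#' @export
detect_bonds <- function(x) {
  mol <- .as_molecule(x)
  b <- .bonds_from_coords(mol$elements, mol$cart)
  adj <- rep(list(integer(0)), length(mol$elements))
  for (k in seq_len(nrow(b))) {
    adj[[b$i[k]]] <- c(adj[[b$i[k]]], b$j[k])
    adj[[b$j[k]]] <- c(adj[[b$j[k]]], b$i[k])
  }
  lapply(adj, sort)
}

.neighbor_signature <- function(elements, adj, i) {
  paste(sort(elements[adj[[i]]]), collapse = ",")
}

#' Construct an atom type
#'
#' @param label Unique identifier within a bank.
#' @param element Central element symbol.
#' @param signature Sorted comma-separated bonded-neighbour elements
#'   (e.g. `"H,H"` for water oxygen).
#' @param z_sel,xz_sel Element selectors for the local frame: Z points from
#'   the atom to the matched `z_sel` atom; the `xz_sel` atom fixes the XZ
#'   plane. Selectors match bonded neighbours first, then second-shell
#'   atoms (nearest first).
#' @return Object of class `tham_atom_type`.
#' @export
atom_type <- function(label, element, signature, z_sel, xz_sel) {
  structure(list(label = label, element = element, signature = signature,
                 frame = list(z = z_sel, xz = xz_sel)),
            class = "tham_atom_type")
}

# deterministic, rotation-invariant frame selectors for a derived type:
# heaviest neighbour element for Z, then the next entry of the sorted
# neighbour list (or, for terminal atoms, the heaviest second-shell
# element) for the XZ reference.
.derive_frame_selectors <- function(elements, adj, i) {
  nb <- adj[[i]]
  .assert(length(nb) >= 1, "invalid_parameter",
          "cannot derive a local frame for an unbonded atom")
  zs <- vapply(elements[nb], .atomic_number, 0L)
  ord <- order(-zs, elements[nb])
  z_sel <- elements[nb][ord[1]]
  if (length(nb) >= 2) {
    xz_sel <- elements[nb][ord[2]]
  } else {
    second <- setdiff(adj[[nb[1]]], i)
    .assert(length(second) >= 1, "invalid_parameter",
            "cannot derive an XZ reference: atom has a single neighbour with no further bonds")
    zs2 <- vapply(elements[second], .atomic_number, 0L)
    xz_sel <- elements[second][order(-zs2, elements[second])[1]]
  }
  list(z = z_sel, xz = xz_sel)
}

#' Derive atom types from a set of molecules
#'
#' One type per distinct (element, neighbour-signature) pair found in the
#' inputs, labelled `element_signature` with frame selectors chosen
#' deterministically (heaviest-neighbour conventions).
#'
#' @param specs A list of `tham_density_spec` / `tham_structure` objects
#'   (or a single one).
#' @return List of `tham_atom_type`.
#' @export
derive_atom_types <- function(specs) {
  if (!is.list(specs) || inherits(specs, c("tham_density_spec",
                                           "tham_structure")))
    specs <- list(specs)
  types <- list()
  for (sp in specs) {
    mol <- .as_molecule(sp)
    adj <- detect_bonds(sp)
    for (i in seq_along(mol$elements)) {
      sig <- .neighbor_signature(mol$elements, adj, i)
      lbl <- paste0(mol$elements[i], "_", gsub(",", "", sig))
      if (is.null(types[[lbl]])) {
        fr <- .derive_frame_selectors(mol$elements, adj, i)
        types[[lbl]] <- atom_type(lbl, mol$elements[i], sig, fr$z, fr$xz)
      }
    }
  }
  unname(types)
}

#' Assign databank atom types to a structure
#'
#' Matches each atom's (element, neighbour-signature) pair against the
#' bank's types. Unmatched atoms get `NA` (the transfer policy decides
#' whether that is an error). Two bank types with the same signature are a
#' bank-validation error.
#'
#' @param x A `tham_structure` or `tham_density_spec`.
#' @param types List of `tham_atom_type` (or a bank from [build_bank()]).
#' @return Character vector of type labels (NA where untyped).
#' @export
assign_atom_types <- function(x, types) {
  if (inherits(types, "tham_databank")) types <- lapply(types$entries,
                                                        `[[`, "type")
  keys <- vapply(types, function(t) paste(t$element, t$signature, sep = "|"),
                 "")
  .assert(!anyDuplicated(keys), "bank_validation",
          sprintf("ambiguous bank: duplicated type signature(s): %s",
                  paste(keys[duplicated(keys)], collapse = "; ")))
  mol <- .as_molecule(x)
  adj <- detect_bonds(x)
  vapply(seq_along(mol$elements), function(i) {
    key <- paste(mol$elements[i],
                 .neighbor_signature(mol$elements, adj, i), sep = "|")
    hit <- match(key, keys)
    if (is.na(hit)) NA_character_ else types[[hit]]$label
  }, "")
}

# resolve an element selector to an atom index: bonded neighbours first,
# then second shell; nearest matching atom wins, excluding already-used
# references.
.resolve_selector <- function(mol, adj, i, sel, exclude = integer(0)) {
  cand <- setdiff(adj[[i]], exclude)
  cand <- cand[mol$elements[cand] == sel]
  if (!length(cand)) {
    shell2 <- setdiff(unique(unlist(adj[adj[[i]]])), c(i, exclude))
    cand <- shell2[mol$elements[shell2] == sel]
  }
  .assert(length(cand) >= 1, "frame_error",
          sprintf("no atom of element %s found near atom %d for the local frame",
                  sel, i))
  d <- sqrt(rowSums(sweep(mol$cart[cand, , drop = FALSE], 2,
                          mol$cart[i, ])^2))
  cand[order(d, cand)][1]
}

#' Local coordinate frame of an atom
#'
#' Z points from the atom towards the resolved `z` reference; Y is the
#' unit component of the `xz` reference direction orthogonal to Z; X = Y
#' cross Z. Rows of the returned matrix are the X, Y, Z axes, so the
#' matrix has determinant +1 and maps global vectors to local ones.
#'
#' @param x A `tham_structure` or `tham_density_spec`.
#' @param atom_index 1-based index.
#' @param frame_def List with element selectors `z` and `xz` (as in
#'   [atom_type()]), or a `tham_atom_type`.
#' @return 3 x 3 orthonormal matrix with det +1.
#' @export
local_frame <- function(x, atom_index, frame_def) {
  if (inherits(frame_def, "tham_atom_type")) frame_def <- frame_def$frame
  mol <- .as_molecule(x)
  adj <- detect_bonds(x)
  iz <- .resolve_selector(mol, adj, atom_index, frame_def$z)
  ixz <- .resolve_selector(mol, adj, atom_index, frame_def$xz,
                           exclude = iz)
  vz <- mol$cart[iz, ] - mol$cart[atom_index, ]
  z <- vz / sqrt(sum(vz^2))
  vx <- mol$cart[ixz, ] - mol$cart[atom_index, ]
  sine <- sqrt(sum(pracma::cross(vx / sqrt(sum(vx^2)), z)^2))
  .assert(sine > sin(pi / 180), "frame_error",
          sprintf("frame references for atom %d (atoms %d, %d) are collinear",
                  atom_index, iz, ixz))
  y <- vx - sum(vx * z) * z
  y <- y / sqrt(sum(y^2))
  xx <- pracma::cross(y, z)
  rbind(xx, y, z, deparse.level = 0)
}

#' Build a databank from density specs
#'
#' For every requested type, each instance's Hirshfeld density is sampled
#' on a grid oriented by its own local frame, projected onto multipoles,
#' resampled to the element's canonical radial grid, and averaged
#' coefficient-wise (plain arithmetic mean). Fewer than 3 instances of a
#' type triggers a warning (transferability rests on averaging over
#' several environments).
#'
#' @param specs List of `tham_density_spec` (or a single one).
#' @param types List of `tham_atom_type`; derived from `specs` if NULL.
#' @param L_max Expansion degree stored in the bank.
#' @param n_rad,n_ang Grid sizes used for projection.
#' @return Object of class `tham_databank` with `entries`, each holding
#'   `type`, `density` (a `tham_multipole_density` in the type's local
#'   frame), `n_instances` and `provenance`.
#' @export
build_bank <- function(specs, types = NULL, L_max = 7L, n_rad = 75L,
                       n_ang = 590L) {
  if (inherits(specs, "tham_density_spec")) specs <- list(specs)
  if (is.null(types)) types <- derive_atom_types(specs)
  ang <- lebedev_angular(n_ang)
  acc <- setNames(vector("list", length(types)),
                  vapply(types, `[[`, "", "label"))
  for (sp in specs) {
    labels <- assign_atom_types(sp, types)
    for (i in seq_along(labels)) {
      if (is.na(labels[i])) next
      el <- .as_molecule(sp)$elements[i]
      rad <- mura_knowles_radial(n_rad, default_radial_scale(el))
      M <- local_frame(sp, i, types[[match(labels[i],
                                           names(acc))]]$frame)
      sampled <- atomic_density_on_grid(sp, i, atomic_grid(rad, ang), M)
      md <- project_multipoles(sampled, L_max)
      md <- resample_radial(md, mura_knowles_radial(n_rad,
                                                    default_radial_scale(el)))
      acc[[labels[i]]] <- c(acc[[labels[i]]], list(md))
    }
  }
  entries <- list()
  for (k in seq_along(types)) {
    lbl <- types[[k]]$label
    inst <- acc[[lbl]]
    .assert(length(inst) >= 1, "bank_validation",
            sprintf("no instance of type '%s' found in the supplied specs",
                    lbl))
    if (length(inst) < 3) {
      warning(sprintf("type '%s': only %d instance(s) averaged; transfer quality improves with >= 3",
                      lbl, length(inst)))
    }
    coef <- Reduce(`+`, lapply(inst, `[[`, "coefficients")) / length(inst)
    md <- .multipole_density(coef, inst[[1]]$radial_grid, inst[[1]]$L_max)
    pop <- multipole_population(md)
    z <- .atomic_number(types[[k]]$element)
    .assert(pop > 0.2 * z && pop < 1.8 * z, "bank_validation",
            sprintf("type '%s': averaged population %.3f outside [0.2, 1.8] x Z = %d",
                    lbl, pop, z))
    entries[[lbl]] <- list(type = types[[k]], density = md,
                           n_instances = length(inst),
                           provenance = sprintf("averaged from %d instance(s)",
                                                length(inst)))
  }
  structure(list(entries = entries, L_max = as.integer(L_max)),
            class = "tham_databank")
}

#' @export
print.tham_databank <- function(x, ...) {
  cat(sprintf("tham databank: %d atom types, L_max = %d\n",
              length(x$entries), x$L_max))
  for (e in x$entries) {
    cat(sprintf("  %-12s %-2s (%s)  n=%d  pop=%.4f\n", e$type$label,
                e$type$element, e$type$signature, e$n_instances,
                multipole_population(e$density)))
  }
  invisible(x)
}

#' Write / read the plain-text databank
#'
#' Format: header `THAM-BANK v1`, then per entry a block
#' ```
#' TYPE <label>
#' ELEMENT <symbol>
#' SIGNATURE <comma-separated neighbours>
#' FRAME z=<sel> xz=<sel>
#' NINST <count>
#' LMAX <L>
#' NRAD <n> SCALE <alpha>
#' (l m) c_1 c_2 ... c_nrad
#' ```
#' with coefficients at 17 significant digits; `#` starts a comment. The
#' round trip reproduces labels, frames, grids and coefficients exactly at
#' stored precision.
#'
#' @param bank A `tham_databank`.
#' @param path File path.
#' @return `read_bank` returns a `tham_databank`; `write_bank` returns
#'   `path` invisibly.
#' @export
write_bank <- function(bank, path) {
  con <- file(path, "wb")  # LF line endings on every platform
  out <- c("THAM-BANK v1",
           sprintf("# %d atom types", length(bank$entries)))
  for (e in bank$entries) {
    md <- e$density
    rg <- md$radial_grid
    out <- c(out,
             sprintf("TYPE %s", e$type$label),
             sprintf("ELEMENT %s", e$type$element),
             sprintf("SIGNATURE %s", e$type$signature),
             sprintf("FRAME z=%s xz=%s", e$type$frame$z, e$type$frame$xz),
             sprintf("NINST %d", e$n_instances),
             sprintf("LMAX %d", md$L_max),
             sprintf("NRAD %d SCALE %.17g", length(rg$nodes), rg$scale))
    idx <- harmonic_index(md$L_max)
    for (k in seq_len(nrow(idx))) {
      out <- c(out, paste0("(", idx$l[k], " ", idx$m[k], ") ",
                           paste(sprintf("%.17g", md$coefficients[k, ]),
                                 collapse = " ")))
    }
  }
  writeLines(out, con, sep = "\n")
  close(con)
  invisible(path)
}

#' @rdname write_bank
#' @export
read_bank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  .assert(length(lines) >= 1 && trimws(lines[1]) == "THAM-BANK v1", "io",
          sprintf("%s: not a THAM-BANK v1 file (bad or missing header)",
                  path))
  entries <- list()
  i <- 2
  parse_fail <- function(i, what) {
    .tham_error("io", sprintf("%s:%d: expected %s, got '%s'", path, i,
                              what, if (i <= length(lines)) lines[i] else "<eof>"))
  }
  skip_blank <- function(i) {
    while (i <= length(lines) &&
           (trimws(lines[i]) == "" || startsWith(trimws(lines[i]), "#")))
      i <- i + 1
    i
  }
  field <- function(i, key) {
    ln <- trimws(lines[i])
    if (!startsWith(ln, paste0(key, " "))) parse_fail(i, key)
    sub(paste0("^", key, "\\s+"), "", ln)
  }
  i <- skip_blank(i)
  while (i <= length(lines)) {
    lbl <- field(i, "TYPE"); i <- skip_blank(i + 1)
    el <- field(i, "ELEMENT"); i <- skip_blank(i + 1)
    sig <- field(i, "SIGNATURE"); i <- skip_blank(i + 1)
    fr <- field(i, "FRAME"); i <- skip_blank(i + 1)
    fm <- regmatches(fr, regexec("z=(\\S+)\\s+xz=(\\S+)", fr))[[1]]
    if (length(fm) != 3) parse_fail(i - 1, "FRAME z=<sel> xz=<sel>")
    ninst <- as.integer(field(i, "NINST")); i <- skip_blank(i + 1)
    lmax <- as.integer(field(i, "LMAX")); i <- skip_blank(i + 1)
    gr <- field(i, "NRAD"); i <- skip_blank(i + 1)
    gm <- regmatches(gr, regexec("^(\\d+)\\s+SCALE\\s+(\\S+)", gr))[[1]]
    if (length(gm) != 3) parse_fail(i - 1, "NRAD <n> SCALE <alpha>")
    n_rad <- as.integer(gm[2]); scale <- as.numeric(gm[3])
    nlm <- (lmax + 1L)^2
    coef <- matrix(NA_real_, nlm, n_rad)
    idx <- harmonic_index(lmax)
    for (k in seq_len(nlm)) {
      if (i > length(lines)) parse_fail(i, "coefficient row")
      ln <- trimws(lines[i])
      m <- regmatches(ln, regexec("^\\((-?\\d+)\\s+(-?\\d+)\\)\\s+(.*)$",
                                  ln))[[1]]
      if (length(m) != 4 || as.integer(m[2]) != idx$l[k] ||
          as.integer(m[3]) != idx$m[k]) {
        parse_fail(i, sprintf("coefficient row (%d %d)", idx$l[k], idx$m[k]))
      }
      vals <- as.numeric(scan(text = m[4], what = "", quiet = TRUE))
      if (length(vals) != n_rad || anyNA(vals)) {
        parse_fail(i, sprintf("%d numeric coefficients", n_rad))
      }
      coef[k, ] <- vals
      i <- i + 1
    }
    i <- skip_blank(i)
    md <- .multipole_density(coef, mura_knowles_radial(n_rad, scale), lmax)
    entries[[lbl]] <- list(type = atom_type(lbl, el, sig, fm[2], fm[3]),
                           density = md, n_instances = ninst,
                           provenance = sprintf("read from %s", path))
  }
  .assert(length(entries) >= 1, "io",
          sprintf("%s: bank contains no entries", path))
  structure(list(entries = entries,
                 L_max = max(vapply(entries, function(e) e$density$L_max,
                                    0L))),
            class = "tham_databank")
}

#' Transfer databank densities onto a structure
#'
#' Each typed atom receives its type's multipole density plus its own
#' local-frame matrix M; the atom's form factor at scattering vector S is
#' then `form_factor_multipole(entry, M S)`.
#'
#' @param bank A `tham_databank`.
#' @param x A `tham_structure` or `tham_density_spec`.
#' @param policy `"strict"` (untyped atom is an error) or `"skip"` (atom
#'   dropped with a warning).
#' @return List per transferred atom: `atom_index`, `label`, `type_label`,
#'   `density`, `frame`.
#' @export
transfer <- function(bank, x, policy = c("strict", "skip")) {
  policy <- match.arg(policy)
  mol <- .as_molecule(x)
  labels <- assign_atom_types(x, bank)
  if (anyNA(labels)) {
    msg <- sprintf("untyped atom(s): %s",
                   paste(mol$labels[is.na(labels)], collapse = ", "))
    if (policy == "strict") .tham_error("untyped_atom", msg)
    warning(paste0(msg, " (skipped)"))
  }
  out <- list()
  for (i in seq_along(labels)) {
    if (is.na(labels[i])) next
    entry <- bank$entries[[labels[i]]]
    M <- local_frame(x, i, entry$type)
    out[[length(out) + 1L]] <- list(atom_index = i, label = mol$labels[i],
                                    type_label = labels[i],
                                    density = entry$density, frame = M)
  }
  out
}
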