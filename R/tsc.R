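# tsc form-factor tables: per reflection (h k l), one complex form factor
# per scatterer, atoms in structure order. Static form factors only --
# thermal smearing is the refinement program's job.

#' Compute a tsc form-factor table
#'
#' For every reflection S and every typed atom a, evaluates the
#' transferred form factor `form_factor_multipole(entry_a, M_a S)`.
#'
#' @param x A `tham_structure` or `tham_density_spec`.
#' @param bank A `tham_databank`.
#' @param reflections A `tham_reflections` from [generate_hkl()].
#' @param policy Untyped-atom policy passed to [transfer()].
#' @return Object of class `tham_tsc`: `header` (title, symmetry note,
#'   scatterer labels), `hkl` data frame and complex matrix `ff`
#'   (reflections x scatterers).
#' @export
compute_tsc <- function(x, bank, reflections, policy = "strict") {
  .assert(inherits(reflections, "tham_reflections"), "invalid_parameter",
          "reflections must come from generate_hkl()")
  tr <- transfer(bank, x, policy = policy)
  nref <- nrow(reflections$S)
  ff <- matrix(complex(real = 0), nref, length(tr))
  for (k in seq_along(tr)) {
    Sloc <- rotate_scattering(reflections$S, tr[[k]]$frame)
    if (nref > 0) ff[, k] <- form_factor_multipole(tr[[k]]$density, Sloc)
  }
  labels <- vapply(tr, `[[`, "", "label")
  structure(list(header = list(title = "tham form factors",
                               symm = "expanded",
                               scatterers = labels),
                 hkl = reflections$hkl, ff = ff),
            class = "tham_tsc")
}

#' Write / read a tsc table
#'
#' Text dialect: `TITLE:`, `SYMM: expanded`, `SCATTERERS:` (space
#' separated labels), `DATA:`, then one row per reflection
#' `h k l re,im re,im ...` with 9 significant digits and no space inside a
#' complex field.
#'
#' @param tsc A `tham_tsc`.
#' @param path File path.
#' @return `read_tsc` returns a `tham_tsc`; `write_tsc` returns `path`
#'   invisibly.
#' @export
write_tsc <- function(tsc, path) {
  con <- file(path, "wb")
  rows <- character(nrow(tsc$hkl))
  for (r in seq_along(rows)) {
    z <- tsc$ff[r, ]
    rows[r] <- paste(tsc$hkl$h[r], tsc$hkl$k[r], tsc$hkl$l[r],
                     paste(sprintf("%.9g,%.9g", Re(z), Im(z)),
                           collapse = " "))
  }
  writeLines(c(paste0("TITLE: ", tsc$header$title),
               paste0("SYMM: ", tsc$header$symm),
               paste0("SCATTERERS: ",
                      paste(tsc$header$scatterers, collapse = " ")),
               "DATA:",
               rows), con, sep = "\n")
  close(con)
  invisible(path)
}

#' @rdname write_tsc
#' @export
read_tsc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  need <- function(k, key) {
    .assert(k <= length(lines) && startsWith(lines[k], key), "io",
            sprintf("%s:%d: expected a '%s' line", path, k, key))
    sub(paste0("^", key, "\\s*"), "", lines[k])
  }
  title <- need(1, "TITLE:")
  symm <- need(2, "SYMM:")
  scat <- scan(text = need(3, "SCATTERERS:"), what = "", quiet = TRUE)
  need(4, "DATA:")
  n <- length(lines) - 4L
  hkl <- data.frame(h = integer(n), k = integer(n), l = integer(n))
  ff <- matrix(complex(real = 0), n, length(scat))
  for (r in seq_len(n)) {
    f <- scan(text = lines[4 + r], what = "", quiet = TRUE)
    .assert(length(f) == 3 + length(scat), "io",
            sprintf("%s:%d: expected %d fields, got %d", path, 4 + r,
                    3 + length(scat), length(f)))
    hkl[r, ] <- as.integer(f[1:3])
    for (k in seq_along(scat)) {
      parts <- as.numeric(strsplit(f[3 + k], ",", fixed = TRUE)[[1]])
      .assert(length(parts) == 2 && all(is.finite(parts)), "io",
              sprintf("%s:%d: malformed complex field '%s'", path, 4 + r,
                      f[3 + k]))
      ff[r, k] <- complex(real = parts[1], imaginary = parts[2])
    }
  }
  structure(list(header = list(title = title, symm = symm,
                               scatterers = scat),
                 hkl = hkl, ff = ff),
            class = "tham_tsc")
}
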