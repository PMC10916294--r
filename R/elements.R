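# Element data used for promolecule references, bond detection and grid
# scales. Covalent radii follow the widely used single-bond compilation of
# Cordero et al. (2008); only elements plausible in small organic and
# bio-organic molecules are listed.

.element_table <- local({
  sym <- c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
           "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
           "Br", "I")
  z   <- c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L,
           11L, 12L, 13L, 14L, 15L, 16L, 17L, 18L, 19L, 20L,
           35L, 53L)
  rcov <- c(0.31, 0.28, 1.28, 0.96, 0.84, 0.76, 0.71, 0.66, 0.57, 0.58,
            1.66, 1.41, 1.21, 1.11, 1.07, 1.05, 1.02, 1.06, 2.03, 1.76,
            1.20, 1.39)
  data.frame(symbol = sym, z = z, r_cov = rcov, stringsAsFactors = FALSE)
})

#' Look up element properties
#'
#' @param element Element symbol (case sensitive, e.g. `"O"`).
#' @return A list with `symbol`, `z` (atomic number) and `r_cov`
#'   (covalent radius, Angstrom).
#' @examples
#' element_info("C")$r_cov
#' @export
element_info <- function(element) {
  i <- match(element, .element_table$symbol)
  .assert(length(i) == 1L && !is.na(i), "unknown_element",
          sprintf("unknown element symbol '%s'", element))
  as.list(.element_table[i, ])
}

.covalent_radius <- function(element) element_info(element)$r_cov
.atomic_number <- function(element) element_info(element)$z
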