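Package: tham
Title: Transferable Hirshfeld Atom Model Form Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An engine for aspherical atomic X-ray form factors built on
    Hirshfeld stockholder partitioning of analytic model electron densities.
    Atomic densities are expanded in real spherical harmonics on Mura-Knowles
    radial and Lebedev-Laikov angular quadrature grids, converted to form
    factors through Hankel (Fourier-Bessel) transforms, stored per atom type
    in a plain-text databank, and transferred onto target structures through
    per-atom local coordinate frames. Includes anisotropic displacement
    parameter (ADP) similarity metrics: the Gaussian overlapping coefficient,
    its rescaled percentage form, and the Whitten-Spackman S12 index. Reads a
    minimal CIF subset and XYZ+cell files, generates reflection lists to a
    resolution cutoff, and writes tsc form-factor tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
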