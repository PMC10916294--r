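# Direct and multipole/Hankel form-factor routes.

test_that("spherical Bessel evaluation is accurate near and far from 0", {
  # against the closed forms j_0 = sin(x)/x, j_1, j_2
  x <- c(1e-8, 1e-4, 0.01, 0.5, 2, 10, 40)
  j0 <- ifelse(x < 1e-6, 1 - x^2 / 6, sin(x) / x)
  expect_equal(sph_bessel_j(0, x), j0, tolerance = 1e-12)
  x2 <- c(0.5, 2, 10)
  expect_equal(sph_bessel_j(1, x2), sin(x2) / x2^2 - cos(x2) / x2,
               tolerance = 1e-12)
  expect_equal(sph_bessel_j(2, x2),
               (3 / x2^3 - 1 / x2) * sin(x2) - 3 * cos(x2) / x2^2,
               tolerance = 1e-12)
  # series limit: j_l(x) ~ x^l/(2l+1)!!
  expect_equal(sph_bessel_j(3, 1e-4), 1e-12 / 105, tolerance = 1e-8)
})

test_that("direct form factor matches Gaussian closed forms", {
  g <- atomic_grid(mura_knowles_radial(75, 5), lebedev_angular(302))
  sd <- structure(list(values = exp(-rowSums(g$points^2)), grid = g,
                       frame = diag(3), element = "X", atom_index = 1L,
                       population = NA_real_),
                  class = "tham_sampled_density")
  f0 <- form_factor_direct(sd, c(0, 0, 0))
  expect_equal(f0, pi^1.5 + 0i, tolerance = 1e-8)
  f <- form_factor_direct(sd, c(0.5, 0, 0))
  expect_equal(f, pi^1.5 * exp(-pi^2 * 0.25) + 0i, tolerance = 1e-8)
  # centrosymmetric density: purely real
  set.seed(2)
  S <- random_S(20)
  expect_lt(max(abs(Im(form_factor_direct(sd, S)))), 1e-10)
})

test_that("zero-angle form factor equals the electron population", {
  sd <- fixture_sampled("water-like", 2)
  expect_equal(form_factor_direct(sd, c(0, 0, 0)),
               sd$population + 0i, tolerance = 1e-10)
  md <- project_multipoles(sd, 7)
  expect_equal(form_factor_multipole(md, c(0, 0, 0)),
               sd$population + 0i, tolerance = 1e-6)
})

test_that("Hankel transform obeys closed forms and decay", {
  g <- atomic_grid(mura_knowles_radial(75, 5), lebedev_angular(302))
  sd <- structure(list(values = exp(-rowSums(g$points^2)), grid = g,
                       frame = diag(3), element = "X", atom_index = 1L,
                       population = NA_real_),
                  class = "tham_sampled_density")
  md <- project_multipoles(sd, 4)
  expect_error(hankel_transform(md, 9, 0.1), class = "tham_invalid_parameter")
  # l = 0, s = 0: sqrt(4 pi) * integral r^2 exp(-r^2) dr
  expect_equal(hankel_transform(md, 0, 0), sqrt(4 * pi) * sqrt(pi) / 4,
               tolerance = 1e-8)
  # higher-l rows of a pure monopole vanish
  expect_lt(max(abs(hankel_transform(md, 2, 0.3))), 1e-12)
  # Riemann-Lebesgue decay at s = 20; the radial grid must resolve the
  # ~0.05 A oscillation of j_l(2 pi s r), so use a dense one
  gf <- atomic_grid(mura_knowles_radial(500, 5), lebedev_angular(110))
  sdf <- structure(list(values = exp(-rowSums(gf$points^2)), grid = gf,
                        frame = diag(3), element = "X", atom_index = 1L,
                        population = NA_real_),
                   class = "tham_sampled_density")
  mdf <- project_multipoles(sdf, 4)
  for (l in 0:4) expect_lt(max(abs(hankel_transform(mdf, l, 20))), 1e-6)
})

test_that("multipole route reproduces the direct route", {
  # spherical atom: exact at L_max = 0 already
  lone <- density_spec("C", rbind(c(0, 0, 0)))
  g <- grid_for_element("C")
  sd <- atomic_density_on_grid(lone, 1, g)
  md <- project_multipoles(sd, 0)
  set.seed(3)
  S <- random_S(20)
  expect_equal(form_factor_multipole(md, S), form_factor_direct(sd, S),
               tolerance = 1e-8)
  # aspherical fixture O atom at L_max = 7: relative error < 1e-3,
  # non-increasing through L = 3, 5, 7, 9
  sdo <- fixture_sampled("water-like", 1)
  set.seed(4)
  S <- random_S(50)
  fd <- form_factor_direct(sdo, S)
  md9 <- project_multipoles(sdo, 9)
  errs <- vapply(c(3, 5, 7, 9), function(L)
    max(abs(form_factor_multipole(md9, S, L_max = L) - fd)) / sdo$population,
    0)
  expect_lt(errs[3], 1e-3)
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("scattering vectors rotate isometrically and covariantly", {
  expect_equal(rotate_scattering(c(1, 2, 3), diag(3)), c(1, 2, 3))
  expect_error(rotate_scattering(c(1, 0, 0), matrix(1, 3, 3)),
               class = "tham_invalid_parameter")
  set.seed(6)
  for (k in 1:10) {
    R <- random_rotation()
    S <- rnorm(3)
    expect_equal(sqrt(sum(rotate_scattering(S, R)^2)), sqrt(sum(S^2)),
                 tolerance = 1e-12)
  }
  # rotating the density is the same as counter-rotating the argument:
  # project the water O atom in a rotated frame and compare with the
  # direct form factor of the physically rotated molecule
  spec <- fixture_spec("water-like")
  R <- random_rotation()
  spec_rot <- rigid_transform_spec(spec, R)
  g <- grid_for_element("O")
  md_local <- project_multipoles(atomic_density_on_grid(spec, 1, g), 7)
  sd_rot <- atomic_density_on_grid(spec_rot, 1, g)
  set.seed(8)
  S <- random_S(25)
  f_transfer <- form_factor_multipole(md_local, rotate_scattering(S, t(R)))
  f_direct <- form_factor_direct(sd_rot, S)
  expect_lt(max(abs(f_transfer - f_direct)) / sd_rot$population, 1e-3)
  # and against the rotated atom's own multipoles at the same L: tight
  f_rot_mp <- form_factor_multipole(project_multipoles(sd_rot, 7), S)
  expect_lt(max(abs(f_transfer - f_rot_mp)) / sd_rot$population, 1e-6)
})

test_that("Friedel symmetry holds on both routes", {
  sd <- fixture_sampled("water-like", 3)
  md <- project_multipoles(sd, 7)
  set.seed(9)
  S <- random_S(20)
  expect_lt(max(abs(form_factor_direct(sd, -S) -
                      Conj(form_factor_direct(sd, S)))), 1e-12)
  expect_lt(max(abs(form_factor_multipole(md, -S) -
                      Conj(form_factor_multipole(md, S)))), 1e-12)
})

test_that("atomic form factors assemble into the molecular transform", {
  for (nm in fixture_names()) {
    spec <- fixture_spec(nm)
    set.seed(10)
    S <- random_S(40)
    Fsum <- 0
    for (a in seq_along(spec$atoms)) {
      sda <- fixture_sampled(nm, a)
      Fsum <- Fsum + form_factor_direct(sda, S) *
        exp(2i * pi * as.vector(S %*% spec$atoms[[a]]$position))
    }
    Fex <- analytic_molecular_ff(spec, S)
    expect_lt(max(abs(Fsum - Fex) / abs(Fex)), 1e-4)
    # zero-angle sum rule
    f0 <- sum(vapply(seq_along(spec$atoms), function(a)
      fixture_sampled(nm, a)$population, 0))
    expect_equal(f0, total_electron_count(spec),
                 tolerance = 1e-5 * total_electron_count(spec))
  }
})
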