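# Shared helpers: random generators and a per-session cache for the
# expensive fixture objects (banks, sampled densities) so test files can
# reuse them.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# random SPD ADP tensor with eigenvalues in [lo, hi] (A^2)
random_spd <- function(lo = 0.005, hi = 0.08) {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  ev <- runif(3, lo, hi)
  U <- q %*% diag(ev) %*% t(q)
  (U + t(U)) / 2
}

# n random scattering vectors with magnitudes in [smin, smax] (A^-1)
random_S <- function(n, smin = 0.05, smax = 1.5) {
  d <- matrix(rnorm(3 * n), ncol = 3)
  d <- d / sqrt(rowSums(d^2))
  d * runif(n, smin, smax)
}

# random proper rotation matrix
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# rigidly transform a density spec (rotation R, then translation t)
rigid_transform_spec <- function(spec, R, t = c(0, 0, 0)) {
  pos <- do.call(rbind, lapply(spec$atoms, `[[`, "position")) %*% t(R)
  pos <- sweep(pos, 2, t, `+`)
  d <- spec$deformations
  defo <- NULL
  if (nrow(d)) {
    m <- sweep(as.matrix(d[, c("cx", "cy", "cz")]) %*% t(R), 2, t, `+`)
    defo <- data.frame(cx = m[, 1], cy = m[, 2], cz = m[, 3],
                       amplitude = d$amplitude, exponent = d$exponent)
  }
  density_spec(vapply(spec$atoms, `[[`, "", "element"), pos,
               deformations = defo, name = paste0(spec$name, "-moved"))
}

# standard grids (cached)
grid_for_element <- function(el, n_rad = 75, n_ang = 590) {
  cached(sprintf("grid-%s-%d-%d", el, n_rad, n_ang),
         atomic_grid(mura_knowles_radial(n_rad, default_radial_scale(el)),
                     lebedev_angular(n_ang)))
}

fixture_spec <- function(name, seed = 0) {
  cached(sprintf("spec-%s-%d", name, seed), make_fixture(name, seed))
}

# sampled Hirshfeld density of one fixture atom, identity frame
fixture_sampled <- function(name, atom, seed = 0) {
  cached(sprintf("sampled-%s-%d-%d", name, atom, seed), {
    spec <- fixture_spec(name, seed)
    g <- grid_for_element(spec$atoms[[atom]]$element)
    atomic_density_on_grid(spec, atom, g)
  })
}

water_bank <- function() {
  cached("bank-water", suppressWarnings(build_bank(fixture_spec("water-like"))))
}
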