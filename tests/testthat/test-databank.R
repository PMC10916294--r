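# Typing, local frames, averaging, bank I/O and transfer.

test_that("bond detection follows covalent radii", {
  spec <- fixture_spec("water-like")
  adj <- detect_bonds(spec)
  expect_identical(adj[[1]], c(2L, 3L))   # O-H, O-H
  expect_identical(adj[[2]], 1L)          # no H-H bond
  expect_identical(adj[[3]], 1L)
  lone <- density_spec("C", rbind(c(0, 0, 0)))
  expect_identical(detect_bonds(lone), list(integer(0)))
  far <- density_spec(c("C", "C"), rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_identical(detect_bonds(far), list(integer(0), integer(0)))
  clash <- density_spec(c("C", "C"), rbind(c(0, 0, 0), c(0.2, 0, 0)))
  expect_error(detect_bonds(clash), class = "tham_invalid_geometry")
})

test_that("atom types assign by element and neighbour signature", {
  spec <- fixture_spec("water-like")
  types <- derive_atom_types(spec)
  expect_setequal(vapply(types, `[[`, "", "label"), c("O_HH", "H_O"))
  expect_identical(assign_atom_types(spec, types), c("O_HH", "H_O", "H_O"))
  # methane-like C against a bank lacking its type is flagged
  ch4 <- density_spec(c("C", "H", "H", "H", "H"),
                      rbind(c(0, 0, 0), c(0.63, 0.63, 0.63),
                            c(-0.63, -0.63, 0.63), c(-0.63, 0.63, -0.63),
                            c(0.63, -0.63, -0.63)))
  lb <- assign_atom_types(ch4, types)
  expect_true(is.na(lb[1]))
  expect_identical(lb[-1], rep(NA_character_, 4))  # H_C is not in the bank
  # ambiguous bank rejected
  dup <- c(types, list(atom_type("H_O2", "H", "O", "O", "H")))
  expect_error(assign_atom_types(spec, dup), class = "tham_bank_validation")
})

test_that("type assignment is invariant under atom relabelling", {
  spec <- fixture_spec("ethanol-like")
  types <- derive_atom_types(spec)
  lb <- assign_atom_types(spec, types)
  perm <- c(3, 1, 2, 9, 5, 4, 8, 6, 7)
  elements <- vapply(spec$atoms, `[[`, "", "element")[perm]
  pos <- do.call(rbind, lapply(spec$atoms, `[[`, "position"))[perm, ]
  spec_p <- density_spec(elements, pos, spec$deformations)
  expect_identical(assign_atom_types(spec_p, types), lb[perm])
})

test_that("local frames are right-handed, aligned and covariant", {
  # H atom with O along +z and a second-shell C off-axis
  st <- density_spec(c("H", "O", "C"),
                     rbind(c(0, 0, 0), c(0, 0, 1), c(1.2, 0, 1.6)))
  M <- local_frame(st, 1, list(z = "O", xz = "C"))
  expect_equal(M[3, ], c(0, 0, 1))
  expect_equal(det(M), 1)
  expect_lt(max(abs(M %*% t(M) - diag(3))), 1e-12)
  # covariance under rigid rotation: M_new = M_old R^T
  set.seed(13)
  for (k in 1:25) {
    R <- random_rotation()
    st_r <- rigid_transform_spec(st, R, t = rnorm(3))
    Mr <- local_frame(st_r, 1, list(z = "O", xz = "C"))
    expect_lt(max(abs(Mr - M %*% t(R))), 1e-10)
    expect_equal(det(Mr), 1, tolerance = 1e-12)
  }
  # random valid geometries keep det +1
  for (k in 1:75) {
    repeat {
      pos <- rbind(c(0, 0, 0), rnorm(3), rnorm(3))
      d2 <- sqrt(sum(pos[2, ]^2)); d3 <- sqrt(sum(pos[3, ]^2))
      cosang <- sum(pos[2, ] * pos[3, ]) / (d2 * d3)
      if (d2 > 0.5 && d3 > 0.5 && abs(cosang) < 0.95) break
    }
    stk <- density_spec(c("H", "O", "C"), pos)
    Mk <- tryCatch(local_frame(stk, 1, list(z = "O", xz = "C")),
                   error = function(e) NULL)
    if (!is.null(Mk)) expect_equal(det(Mk), 1, tolerance = 1e-12)
  }
  # collinear references are refused
  bad <- density_spec(c("H", "O", "C"),
                      rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2.4)))
  expect_error(local_frame(bad, 1, list(z = "O", xz = "C")),
               class = "tham_frame_error")
})

test_that("bank averaging is linear, idempotent and rotation covariant", {
  spec <- fixture_spec("water-like")
  types <- derive_atom_types(spec)
  bank1 <- suppressWarnings(build_bank(spec, types))
  # single O instance: entry equals that instance's projection
  g <- grid_for_element("O")
  M <- local_frame(spec, 1, types[[1]]$frame)
  md <- project_multipoles(atomic_density_on_grid(spec, 1, g, M), 7)
  expect_equal(bank1$entries[["O_HH"]]$density$coefficients,
               md$coefficients, tolerance = 1e-12)
  # a rigidly rotated copy averages to the same entry
  R <- random_rotation()
  bank2 <- suppressWarnings(build_bank(list(spec,
                                            rigid_transform_spec(spec, R)),
                                       types))
  expect_identical(bank2$entries[["O_HH"]]$n_instances, 2L)
  expect_lt(max(abs(bank2$entries[["O_HH"]]$density$coefficients -
                      md$coefficients)), 1e-8)
  # genuinely different instances: population is the mean
  bank_u <- suppressWarnings(build_bank(fixture_spec("urea-like")))
  spec_u <- fixture_spec("urea-like")
  types_u <- derive_atom_types(spec_u)
  hn <- which(vapply(types_u, `[[`, "", "label") == "H_N")
  labels <- assign_atom_types(spec_u, types_u)
  pops <- vapply(which(labels == "H_N"), function(i) {
    Mi <- local_frame(spec_u, i, types_u[[hn]]$frame)
    gi <- grid_for_element("H")
    multipole_population(
      project_multipoles(atomic_density_on_grid(spec_u, i, gi, Mi), 7))
  }, 0)
  expect_equal(multipole_population(bank_u$entries[["H_N"]]$density),
               mean(pops), tolerance = 1e-10)
  # averaging over identical copies changes nothing
  bank3 <- suppressWarnings(build_bank(list(spec, spec, spec), types))
  expect_lt(max(abs(bank3$entries[["H_O"]]$density$coefficients -
                      bank1$entries[["H_O"]]$density$coefficients)), 1e-12)
  # a type with no instance errors
  expect_error(suppressWarnings(
    build_bank(spec, c(types, list(atom_type("C_HHHH", "C", "H,H,H,H",
                                             "H", "H"))))),
    class = "tham_bank_validation")
})

test_that("bank text files round-trip exactly and reject corruption", {
  bank <- water_bank()
  path <- withr::local_tempfile(fileext = ".txt")
  write_bank(bank, path)
  back <- read_bank(path)
  expect_identical(names(back$entries), names(bank$entries))
  for (lbl in names(bank$entries)) {
    expect_identical(back$entries[[lbl]]$density$coefficients,
                     bank$entries[[lbl]]$density$coefficients)
    expect_identical(back$entries[[lbl]]$type$frame,
                     bank$entries[[lbl]]$type$frame)
    expect_equal(back$entries[[lbl]]$density$radial_grid$nodes,
                 bank$entries[[lbl]]$density$radial_grid$nodes)
  }
  # truncated coefficient block: parse error naming the line
  lines <- readLines(path)
  first_coef <- grep("^\\(0 0\\)", lines)[1]
  writeLines(lines[seq_len(first_coef - 1)], path)
  expect_error(read_bank(path), "expected coefficient row")
  # bad header
  writeLines(c("SOMETHING ELSE", lines[-1]), path)
  expect_error(read_bank(path), class = "tham_io")
})

test_that("a 52-type bank loads and validates", {
  bank <- water_bank()
  entry <- bank$entries[[1]]
  big <- bank
  big$entries <- setNames(lapply(1:52, function(k) {
    e <- entry
    e$type$label <- sprintf("T%02d", k)
    e
  }), sprintf("T%02d", 1:52))
  path <- withr::local_tempfile(fileext = ".txt")
  write_bank(big, path)
  back <- read_bank(path)
  expect_length(back$entries, 52)
  expect_identical(back$entries[["T52"]]$density$coefficients,
                   entry$density$coefficients)
})

test_that("transfer reproduces its source and rotated copies", {
  spec <- fixture_spec("water-like")
  bank <- water_bank()
  tr <- transfer(bank, spec)
  expect_length(tr, 3)
  set.seed(17)
  S <- random_S(100)
  # self-transfer: multipole form factors at the same L agree to 1e-6
  # (deviations normalised by f(0), the convention used throughout for
  # form-factor errors; pointwise ratios are ill-conditioned where f -> 0)
  for (t in tr) {
    g <- grid_for_element(spec$atoms[[t$atom_index]]$element)
    md <- project_multipoles(atomic_density_on_grid(spec, t$atom_index, g),
                             bank$L_max)
    f_ref <- form_factor_multipole(md, S)
    f_tr <- form_factor_multipole(t$density,
                                  rotate_scattering(S, t$frame))
    expect_lt(max(abs(f_tr - f_ref)) / multipole_population(md), 1e-6)
  }
  # the two equivalent H atoms share the entry but not the frame
  expect_identical(tr[[2]]$density, tr[[3]]$density)
  expect_gt(max(abs(tr[[2]]$frame - tr[[3]]$frame)), 0.1)
  # rigidly rotated copy: same mechanism, same tolerance
  R <- random_rotation()
  spec_r <- rigid_transform_spec(spec, R, t = c(1, -2, 0.5))
  tr_r <- transfer(bank, spec_r)
  for (t in tr_r) {
    g <- grid_for_element(spec_r$atoms[[t$atom_index]]$element)
    md <- project_multipoles(atomic_density_on_grid(spec_r, t$atom_index,
                                                    g), bank$L_max)
    f_ref <- form_factor_multipole(md, S)
    f_tr <- form_factor_multipole(t$density,
                                  rotate_scattering(S, t$frame))
    expect_lt(max(abs(f_tr - f_ref)) / multipole_population(md), 1e-6)
  }
  # amplitude-perturbed copy: deviation finite and larger than self-transfer
  spec_p <- spec
  spec_p$deformations$amplitude <- spec$deformations$amplitude * 1.2
  spec_p <- density_spec(c("O", "H", "H"),
                         do.call(rbind, lapply(spec$atoms, `[[`, "position")),
                         spec_p$deformations, name = "perturbed")
  tr_p <- transfer(bank, spec_p)
  dev_p <- 0
  for (t in tr_p) {
    g <- grid_for_element(spec_p$atoms[[t$atom_index]]$element)
    md <- project_multipoles(atomic_density_on_grid(spec_p, t$atom_index,
                                                    g), bank$L_max)
    dev_p <- max(dev_p,
                 max(abs(form_factor_multipole(t$density,
                                               rotate_scattering(S, t$frame)) -
                           form_factor_multipole(md, S))) /
                   multipole_population(md))
  }
  expect_true(is.finite(dev_p))
  expect_gt(dev_p, 1e-6)
})

test_that("untyped atoms follow the strict/skip policy", {
  bank <- water_bank()
  ch4 <- density_spec(c("C", "H", "H", "H", "H"),
                      rbind(c(0, 0, 0), c(0.63, 0.63, 0.63),
                            c(-0.63, -0.63, 0.63), c(-0.63, 0.63, -0.63),
                            c(0.63, -0.63, -0.63)))
  expect_error(transfer(bank, ch4), class = "tham_untyped_atom")
  expect_warning(tr <- transfer(bank, ch4, policy = "skip"), "skipped")
  expect_length(tr, 0)
})
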