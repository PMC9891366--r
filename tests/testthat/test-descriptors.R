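test_that("descriptors are invariant to rotation, translation and reordering", {
  cfg <- tiny_soap()
  w <- water_molecule()
  d0 <- compute_descriptors(w, cfg)

  rot <- rotation_matrix(c(1, 2, 3), 1.234)
  moved <- transform_structure(w, rot = rot, shift = c(5, -3, 2))
  expect_lt(max(abs(compute_descriptors(moved, cfg)$X - d0$X)), 1e-8)

  perm <- c(2, 3, 1)
  permuted <- atomic_structure(w$atoms[perm, ], id = "perm")
  dp <- compute_descriptors(permuted, cfg)
  expect_lt(max(abs(dp$X - d0$X[perm, ])), 1e-8)
})

test_that("descriptors are local and consistent across periodic embedding", {
  cfg <- tiny_soap()
  w <- water_molecule()
  d0 <- compute_descriptors(w, cfg)

  # an atom beyond r_cut changes nothing
  plus <- atomic_structure(
    dplyr::bind_rows(
      w$atoms,
      tibble::tibble(element = "O", x = 50, y = 0, z = 0)
    ),
    id = "plus_far"
  )
  dplus <- compute_descriptors(plus, cfg)
  expect_lt(max(abs(dplus$X[1:3, ] - d0$X)), 1e-12)

  # same molecule in a huge empty periodic box: identical rows
  boxed <- atomic_structure(w$atoms, cell = diag(3) * 40, pbc = TRUE, id = "boxed")
  expect_lt(max(abs(compute_descriptors(boxed, cfg)$X - d0$X)), 1e-10)

  # two isolated atoms of one element share the zero-neighborhood vector
  lone2 <- atomic_structure(
    tibble::tibble(element = c("O", "O"), x = c(0, 30), y = 0, z = 0),
    id = "lones"
  )
  dl <- compute_descriptors(lone2, cfg)
  expect_lt(max(abs(dl$X[1, ] - dl$X[2, ])), 1e-14)
  expect_gt(sum(dl$X[1, ]^2), 0)

  # species outside the configured list are refused
  bad <- atomic_structure(tibble::tibble(element = "S", x = 0, y = 0, z = 0))
  expect_error(compute_descriptors(bad, cfg), "species")
})


test_that("the power spectrum matches a 3-D quadrature oracle on an O-H dimer", {
  cfg <- soap_config(
    r_cut = 3, n_max = 2, l_max = 2, sigma_atom = 0.4,
    species = c("O", "H"), normalize = FALSE, n_quad = 100
  )
  s <- atomic_structure(
    tibble::tibble(element = c("O", "H"), x = c(0, 1), y = 0, z = 0),
    id = "oh"
  )
  impl <- compute_descriptors(s, cfg)$X[1, ]
  ora <- oracle_power_spectrum(s, cfg, center_atom = 1)
  sel <- abs(ora) > 1e-6 * max(abs(ora))
  expect_lt(max(abs(impl[sel] - ora[sel]) / abs(ora[sel])), 1e-4)
})

test_that("collection averages obey the averaging identities", {
  cfg <- tiny_soap()
  s <- micro$two_waters_cell
  d <- compute_descriptors(s, cfg)

  expect_equal(average_descriptor(d, c(1, 2))$x, colMeans(d$X[1:2, ]))
  expect_equal(average_descriptor(d, 3)$x, d$X[3, ])
  expect_error(average_descriptor(d, integer(0)), "empty")
  expect_error(average_descriptor(d, 99), "range")

  # crystal average equals the molecule-count-weighted molecular average
  comps <- extract_molecules(s)
  full <- average_descriptor(d)$x
  weighted <- Reduce(`+`, lapply(comps, function(cm) {
    length(cm$index_map) * average_descriptor(d, cm$index_map)$x
  })) / n_atoms(s)
  expect_lt(max(abs(full - weighted)), 1e-14)
})

test_that("remnant descriptors vanish without intermolecular neighbors and commute with averaging", {
  cfg <- tiny_soap()
  # two waters far apart (beyond r_cut): solid == gas environment
  w <- water_molecule()
  atoms <- dplyr::bind_rows(
    dplyr::mutate(w$atoms, x = x + 3, y = y + 3, z = z + 3),
    dplyr::mutate(w$atoms, x = x + 12, y = y + 12, z = z + 12)
  )
  s <- atomic_structure(atoms, cell = diag(3) * 18, pbc = TRUE, id = "sparse")
  rec <- assemble_crystal_record(s, list(w, w), -560, c(-280, -280))
  ds_s <- compute_descriptors(s, cfg)
  ds_g <- lapply(rec$molecules, function(m) compute_descriptors(m$gas_structure, cfg))
  rem <- remnant_descriptor(rec, ds_s, ds_g)
  expect_lt(max(abs(rem$per_atom)), 1e-8)

  # differencing commutes with averaging
  dense <- micro$two_waters_cell
  rec2 <- assemble_crystal_record(dense, list(w, w), -560, c(-280, -280))
  ds_s2 <- compute_descriptors(dense, cfg)
  ds_g2 <- lapply(rec2$molecules, function(m) compute_descriptors(m$gas_structure, cfg))
  rem2 <- remnant_descriptor(rec2, ds_s2, ds_g2)
  expect_lt(max(abs(rem2$collection$x - colMeans(rem2$per_atom))), 1e-14)
  expect_gt(sqrt(sum(rem2$collection$x^2)), 0)

  # shrinking r_cut below the closest intermolecular contact kills the remnant
  contacts <- pair_dist_between_molecules(dense)
  cfg_small <- soap_config(
    r_cut = 0.9 * min(contacts), n_max = 2, l_max = 2,
    sigma_atom = 0.4, species = c("O", "H"), n_quad = 60
  )
  ds_s3 <- compute_descriptors(dense, cfg_small)
  ds_g3 <- lapply(rec2$molecules, function(m) compute_descriptors(m$gas_structure, cfg_small))
  rem3 <- remnant_descriptor(rec2, ds_s3, ds_g3)
  expect_lt(max(abs(rem3$per_atom)), 1e-10)

  # configuration mismatch between phases is an error
  expect_error(remnant_descriptor(rec2, ds_s3, ds_g2), "mismatch")
})

test_that("concatenation stacks features and doubles the squared norm of equal blocks", {
  a <- structure(
    list(x = c(1, 2), n = 3L, scope = "crystal", config_hash = "h1"),
    class = "collection_descriptor"
  )
  b <- structure(
    list(x = c(3), n = 3L, scope = "crystal", config_hash = "h2"),
    class = "collection_descriptor"
  )
  expect_equal(concatenate_descriptors(a, b)$x, c(1, 2, 3))
  same <- concatenate_descriptors(a, a)
  expect_equal(sum(same$x^2), 2 * sum(a$x^2))
  expect_identical(attr(same, "blocks"), c(2L, 2L))
  b$scope <- "motif"
  expect_error(concatenate_descriptors(a, b), "scope")
})

test_that("descriptor matrices round-trip through the CSV + sidecar format", {
  cfg <- tiny_soap()
  d <- compute_descriptors(water_molecule(), cfg)
  phase(d) <- "g"
  stem <- withr::local_tempfile()
  write_descriptors(d, stem, cfg)
  back <- read_descriptors(stem)
  expect_equal(back$X, d$X, tolerance = 1e-12)
  expect_identical(back$phase, "g")
  expect_identical(back$config_hash, d$config_hash)
})
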