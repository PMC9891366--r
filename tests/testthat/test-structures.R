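test_that("extended XYZ round-trips species, positions, cell and pbc", {
  s <- micro$two_waters_cell
  s$tags <- list(energy = -123.456)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_extxyz(s, path)
  back <- read_extxyz(path)
  expect_length(back, 1)
  b <- back[[1]]
  expect_identical(species(b), species(s))
  expect_lt(max(abs(positions(b) - positions(s))), 1e-8)
  expect_equal(b$cell, s$cell)
  expect_identical(b$pbc, c(TRUE, TRUE, TRUE))
  expect_equal(b$tags$energy, -123.456)

  # a frame without a lattice is molecular
  w <- water_molecule()
  write_extxyz(w, path)
  b2 <- read_extxyz(path)[[1]]
  expect_identical(b2$pbc, c(FALSE, FALSE, FALSE))
  expect_null(b2$cell)
})

test_that("malformed XYZ and unknown elements are rejected with location info", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "comment", "O 0 0 0"), path)
  expect_error(read_extxyz(path), "truncated")
  writeLines(c("1", "comment", "Xx 0 0 0"), path)
  expect_error(read_extxyz(path), "unknown element")
})

test_that("CIF with symmetry operators expands to P1 matching a hand expansion", {
  # toy 2-operator cell: inversion doubles the asymmetric unit, except
  # for sites fixed under inversion
  cif <- c(
    "data_toy",
    "_cell_length_a 6.0",
    "_cell_length_b 6.0",
    "_cell_length_c 6.0",
    "_cell_angle_alpha 90",
    "_cell_angle_beta 90",
    "_cell_angle_gamma 90",
    "loop_",
    "_symmetry_equiv_pos_as_xyz",
    "'x, y, z'",
    "'-x, -y, -z'",
    "loop_",
    "_atom_site_label",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    "O1 0.10 0.20 0.30",
    "C1 0.00 0.00 0.00"
  )
  path <- withr::local_tempfile(fileext = ".cif")
  writeLines(cif, path)
  s <- read_cif(path)
  # hand expansion: O at (.1,.2,.3) and (-.1,-.2,-.3) mod 1 = (.9,.8,.7);
  # C at origin is its own image -> 3 atoms total
  expect_equal(n_atoms(s), 3)
  expect_identical(sort(species(s)), c("C", "O", "O"))
  frac <- positions(s) %*% solve(s$cell)
  o_sites <- frac[species(s) == "O", ]
  expected <- rbind(c(0.1, 0.2, 0.3), c(0.9, 0.8, 0.7))
  ord <- order(o_sites[, 1])
  expect_lt(max(abs(o_sites[ord, ] - expected)), 1e-8)
  expect_true(all(s$pbc))
})

test_that("bond perception follows covalent radii and minimum images", {
  # O-H at covalent distance: one bond
  oh <- atomic_structure(
    tibble::tibble(element = c("O", "H"), x = c(0, 0.97), y = 0, z = 0)
  )
  expect_equal(nrow(build_bond_graph(oh)), 1)

  # two far atoms: no bond
  far <- atomic_structure(
    tibble::tibble(element = c("O", "O"), x = c(0, 5), y = 0, z = 0)
  )
  expect_equal(nrow(build_bond_graph(far)), 0)

  # bond through the periodic boundary: H at 0.1, O at 9.2 in a 10 A box
  # -> direct distance 9.1, image distance 0.9 via shift (-1, 0, 0)
  per <- atomic_structure(
    tibble::tibble(element = c("H", "O"), x = c(0.1, 9.2), y = 0, z = 0),
    cell = diag(3) * 10, pbc = TRUE
  )
  g <- build_bond_graph(per)
  expect_equal(nrow(g), 1)
  expect_equal(g$d, 0.9, tolerance = 1e-12)
  shift <- if (g$i == 1) c(g$sa, g$sb, g$sc) else -c(g$sa, g$sb, g$sc)
  expect_identical(as.integer(shift), c(-1L, 0L, 0L))
})

test_that("molecule extraction finds components, unwraps, and flags polymers", {
  s <- micro$two_waters_cell
  comps <- extract_molecules(s)
  expect_length(comps, 2)
  expect_identical(
    sort(vapply(comps, function(cm) n_atoms(cm$structure), integer(1))),
    c(3L, 3L)
  )
  # index maps partition the atoms
  idx <- sort(unlist(lapply(comps, `[[`, "index_map")))
  expect_identical(idx, seq_len(6))

  # a single isolated atom is its own component
  lone <- atomic_structure(tibble::tibble(element = "O", x = 0, y = 0, z = 0))
  expect_length(extract_molecules(lone), 1)

  # a chain bonded to its own periodic image is polymeric
  expect_error(extract_molecules(micro$polymer_chain), "not a molecular crystal")
})

test_that("extraction is invariant to rigid translation and re-wrapping", {
  s <- micro$two_waters_cell
  ref <- extract_molecules(s)
  ref_parts <- lapply(ref, `[[`, "index_map")

  shifted <- transform_structure(s, shift = c(3.3, -1.7, 0.4))
  parts2 <- lapply(extract_molecules(shifted), `[[`, "index_map")
  expect_identical(ref_parts, parts2)

  # wrap all atoms back into the cell
  p <- positions(s) + 7 # move partly outside
  frac <- p %*% solve(s$cell)
  pw <- (frac %% 1) %*% s$cell
  wrapped <- atomic_structure(
    tibble::tibble(
      element = species(s), x = pw[, 1], y = pw[, 2], z = pw[, 3]
    ),
    cell = s$cell, pbc = TRUE, id = s$id
  )
  comps_w <- extract_molecules(wrapped)
  expect_identical(ref_parts, lapply(comps_w, `[[`, "index_map"))
  # unwrapped molecules have every bond at its direct distance
  for (cm in comps_w) {
    g <- build_bond_graph(cm$structure)
    expect_true(all(g$sa == 0 & g$sb == 0 & g$sc == 0))
    rcov <- covalent_radii()
    lim <- 1.2 * (rcov[species(cm$structure)[g$i]] +
      rcov[species(cm$structure)[g$j]])
    expect_true(all(g$d <= lim))
  }
})

test_that("crystal records enforce the composition partition", {
  s <- micro$two_waters_cell
  w <- water_molecule()
  rec <- assemble_crystal_record(s, list(w, w), -600, c(-280, -280))
  expect_equal(
    sum(vapply(rec$molecules, function(m) n_atoms(m$gas_structure), numeric(1))),
    n_atoms(s)
  )
  ev <- energy_view(rec)
  expect_equal(ev$Delta_c, -600 - (-560))
  expect_equal(ev$delta_c * ev$n_c, ev$Delta_c)

  # wrong molecule count
  expect_error(
    assemble_crystal_record(s, list(w, w, w), -600, c(-280, -280, -280)),
    "composition mismatch"
  )
  # wrong composition
  nh3 <- molecule_templates("ammonia")$ammonia
  expect_error(
    assemble_crystal_record(s, list(w, nh3), -600, c(-280, -280)),
    "composition mismatch"
  )
})

test_that("co-crystals pair each gas molecule with its own component", {
  # one water + one ammonia in a large cell
  w <- water_molecule()
  nh3 <- molecule_templates("ammonia")$ammonia
  atoms <- dplyr::bind_rows(
    dplyr::mutate(w$atoms, x = x + 2, y = y + 2, z = z + 2),
    dplyr::mutate(nh3$atoms, x = x + 7, y = y + 7, z = z + 7)
  )
  cc <- atomic_structure(atoms, cell = diag(3) * 12, pbc = TRUE, id = "cocrystal")
  rec <- assemble_crystal_record(cc, list(nh3, w), -500, c(-220, -280))
  key <- function(st) paste(sort(species(st)), collapse = "")
  for (m in rec$molecules) {
    expect_identical(
      key(m$gas_structure),
      paste(sort(species(cc)[m$index_map]), collapse = "")
    )
  }
})
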