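test_that("graph perception annotates bonds and aromaticity from SMILES and coordinates", {
  # water from coordinates: O with two single bonds
  gw <- perceive_molecular_graph(water_molecule())
  expect_equal(nrow(gw$bonds), 2)
  expect_true(all(gw$bonds$order == 1))
  expect_false(any(gw$atoms$aromatic))

  # benzene from SMILES: six aromatic carbons
  gb <- perceive_molecular_graph("benzene", smiles = micro$benzene)
  expect_equal(sum(gb$atoms$aromatic & gb$atoms$element == "C"), 6)

  # phenanthrene: three fused six-membered aromatic rings
  gp <- perceive_molecular_graph("phenanthrene", smiles = micro$phenanthrene)
  expect_length(gp$rings, 3)
  expect_true(all(lengths(gp$rings) == 6))

  expect_error(
    perceive_molecular_graph("bad", smiles = "not-a-smiles"),
    "SMILES"
  )
})

test_that("SMARTS matching counts the expected motif instances", {
  pat <- motif_patterns()
  g_succ <- perceive_molecular_graph("succinic", smiles = micro$succinic_acid)
  g_methane <- perceive_molecular_graph("methane", smiles = "C")
  g_tatb <- perceive_molecular_graph(
    "tatb",
    smiles = "Nc1c([N+](=O)[O-])c(N)c([N+](=O)[O-])c(N)c1[N+](=O)[O-]"
  )
  m <- match_motifs(list(g_succ, g_methane, g_tatb), pat)

  counts <- dplyr::count(m, .data$molecule_id, .data$pattern)
  n_of <- function(mol, p) {
    hit <- counts$n[counts$molecule_id == mol & counts$pattern == p]
    if (length(hit) == 0) 0L else hit
  }
  expect_equal(n_of("succinic", "carboxylic_acid"), 2L)
  expect_equal(n_of("methane", "carboxylic_acid"), 0L)
  # nitro: nitrogen bonded to two terminal oxygens, three on the TATB ring
  expect_equal(n_of("tatb", "nitro"), 3L)
  expect_equal(n_of("tatb", "primary_amine"), 3L)
  expect_equal(n_of("tatb", "ring6_unsaturated"), 1L)

  expect_error(
    match_motifs(g_methane, tibble::tibble(
      name = "broken", smarts = "[[[", add_h = TRUE
    )),
    "SMARTS"
  )
})

test_that("matching is graph-only: invariant to atom order and coordinates", {
  pat <- motif_patterns()
  w1 <- water_molecule()
  perm <- c(3, 1, 2)
  w2 <- atomic_structure(w1$atoms[perm, ], id = "water_perm")
  w3 <- transform_structure(w1, rot = rotation_matrix(c(0, 0, 1), 2), shift = c(9, 9, 9))
  w3$id <- "water_rot"
  m <- match_motifs(
    list(
      perceive_molecular_graph(w1),
      perceive_molecular_graph(w2),
      perceive_molecular_graph(w3)
    ),
    pat[pat$name == "water", ]
  )
  expect_equal(nrow(m), 3)
  expect_true(all(m$n_atoms == 3))
  # counts per molecule identical regardless of order/placement
  expect_equal(unname(table(m$molecule_id)), rep(1L, 3), ignore_attr = TRUE)
})

test_that("motif census respects the reporting threshold", {
  pat <- motif_patterns(min_count = 2L)
  g <- perceive_molecular_graph("succinic", smiles = micro$succinic_acid)
  m <- match_motifs(g, pat)
  cen <- count_motifs(m, pat)
  expect_equal(cen$count[cen$pattern == "carboxylic_acid"], 2L)
  expect_false(cen$low_sample[cen$pattern == "carboxylic_acid"])
  expect_true(all(cen$low_sample[cen$count < 2]))
})

test_that("hydrogen bonds obey the 2.5-angstrom and 150-degree thresholds", {
  # linear O-H...O at 1.9 A and 180 degrees: detected, class OH...O
  hb <- detect_hbonds(micro$hbond_linear)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$class, "OH...O")
  expect_equal(hb$distance, 1.9, tolerance = 1e-9)
  expect_equal(hb$angle, 180, tolerance = 1e-6)
  expect_identical(hb$donor, 1L)
  expect_identical(hb$acceptor, 3L)

  # 2.6 A is too long
  expect_equal(nrow(detect_hbonds(micro$hbond_long)), 0)
  # 120 degrees is too bent
  expect_equal(nrow(detect_hbonds(micro$hbond_bent)), 0)
})

test_that("hydrogen-bond detection is invariant to rigid motion and wrapping", {
  s <- micro$hbond_linear
  moved <- transform_structure(
    s,
    rot = rotation_matrix(c(1, 1, 0), 0.8), shift = c(-4, 2, 6)
  )
  hb0 <- detect_hbonds(s)
  hb1 <- detect_hbonds(moved)
  expect_equal(nrow(hb1), nrow(hb0))
  expect_equal(hb1$distance, hb0$distance, tolerance = 1e-9)
  expect_equal(hb1$angle, hb0$angle, tolerance = 1e-6)

  # same geometry across a periodic boundary
  atoms <- s$atoms
  atoms$x <- atoms$x + 9 # donor near the boundary of a 10 A box
  per <- atomic_structure(atoms, cell = diag(3) * 10, pbc = TRUE, id = "wrapped")
  pw <- positions(per) %*% solve(per$cell)
  pw <- (pw %% 1) %*% per$cell
  per2 <- atomic_structure(
    tibble::tibble(
      element = species(per), x = pw[, 1], y = pw[, 2], z = pw[, 3]
    ),
    cell = per$cell, pbc = TRUE, id = "wrapped"
  )
  hb2 <- detect_hbonds(per2)
  expect_equal(nrow(hb2), 1)
  expect_equal(hb2$distance, 1.9, tolerance = 1e-9)
})

test_that("per-molecule hydrogen-bond counts split donated and accepted", {
  # water dimer: molecule 1 donates one bond to molecule 2
  atoms <- dplyr::bind_rows(
    water_molecule()$atoms,
    dplyr::mutate(water_molecule()$atoms, x = x + 2.86)
  )
  dimer <- atomic_structure(atoms, id = "dimer")
  hb <- detect_hbonds(dimer)
  expect_equal(nrow(hb), 1)
  counts <- count_hbonds_per_molecule(hb, dimer)
  expect_equal(counts$donated, c(1, 0))
  expect_equal(counts$accepted, c(0, 1))
  expect_equal(counts$donated_to_O, c(1, 0))
  expect_equal(counts$donated_to_N, c(0, 0))
})
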