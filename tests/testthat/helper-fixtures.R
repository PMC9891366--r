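# shared fixtures and small utilities for the test suite

micro <- make_worked_micro_examples()

water_molecule <- function() {
  atomic_structure(
    tibble::tibble(
      element = c("O", "H", "H"),
      x = c(0, 0.9572, -0.2399), y = c(0, 0, 0.9266), z = c(0, 0, 0)
    ),
    id = "water"
  )
}

rotation_matrix <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(
    0, -axis[3], axis[2],
    axis[3], 0, -axis[1],
    -axis[2], axis[1], 0
  ), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * K %*% K
}

transform_structure <- function(s, rot = diag(3), shift = c(0, 0, 0)) {
  p <- positions(s) %*% t(rot)
  p <- sweep(p, 2, shift, "+")
  atomic_structure(
    tibble::tibble(
      element = species(s), x = p[, 1], y = p[, 2], z = p[, 3]
    ),
    cell = if (!is.null(s$cell)) s$cell %*% t(rot) else NULL,
    pbc = s$pbc, id = s$id
  )
}

tiny_soap <- function(...) {
  soap_config(
    r_cut = 3.0, n_max = 2L, l_max = 2L, sigma_atom = 0.4,
    species = c("O", "H"), n_quad = 60L, ...
  )
}

pair_dist_between_molecules <- function(s, rmax = 20) {
  comps <- extract_molecules(s)
  mol_of <- rep(NA_integer_, n_atoms(s))
  for (k in seq_along(comps)) mol_of[comps[[k]]$index_map] <- k
  pt <- latticemotifs:::pair_table(s, rmax)
  pt$d[mol_of[pt$i] != mol_of[pt$j]]
}

# small cached synthetic dataset shared across test files (lazy)
.fixture_cache <- new.env(parent = emptyenv())

small_synth <- function() {
  if (is.null(.fixture_cache$small)) {
    .fixture_cache$small <- generate_synthetic(synthetic_spec(
      seed = 42L, n_crystals = 20L, templates = "water",
      descriptor_cfg = soap_config(
        r_cut = 4, n_max = 2, l_max = 2, sigma_atom = 0.35,
        species = c("H", "O"), n_quad = 50
      )
    ))
  }
  .fixture_cache$small
}

collection_matrix <- function(ds, space = c("remnant", "s", "g", "concat")) {
  space <- match.arg(space)
  Xs <- do.call(rbind, lapply(
    seq_along(ds$records),
    function(i) average_descriptor(ds$descriptors$solid[[i]])$x
  ))
  Xr <- do.call(rbind, lapply(ds$remnants, function(r) r$collection$x))
  switch(space,
    remnant = Xr,
    s = Xs,
    g = Xs - Xr,
    concat = cbind(Xs, Xs - Xr)
  )
}
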