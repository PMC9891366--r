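#' Rigid molecule templates for the synthetic generator
#'
#' Small rigid molecules (experimental-like geometries, angstrom) used as
#' building blocks: water, formaldehyde (a carbonyl carrier), ammonia (an
#' amine-like donor) and methane.  Gas-phase geometries are identical to
#' the in-crystal geometries, so the planted lattice energy is driven
#' purely by intermolecular structure.
#'
#' @param names Which templates to return (default all).
#' @return Named list of [atomic_structure()] objects.
#' @export
molecule_templates <- function(names = c("water", "formaldehyde", "ammonia", "methane")) {
  all <- list(
    water = tibble::tibble(
      element = c("O", "H", "H"),
      x = c(0, 0.9572, -0.2399), y = c(0, 0, 0.9266), z = c(0, 0, 0)
    ),
    formaldehyde = tibble::tibble(
      element = c("C", "O", "H", "H"),
      x = c(0, 1.205, -0.543, -0.543), y = c(0, 0, 0.939, -0.939), z = 0
    ),
    ammonia = tibble::tibble(
      element = c("N", "H", "H", "H"),
      x = c(0, 0.9377, -0.4689, -0.4689),
      y = c(0, 0, 0.8121, -0.8121),
      z = c(0.0, -0.3816, -0.3816, -0.3816)
    ),
    methane = tibble::tibble(
      element = c("C", "H", "H", "H", "H"),
      x = c(0, 0.6293, -0.6293, -0.6293, 0.6293),
      y = c(0, 0.6293, -0.6293, 0.6293, -0.6293),
      z = c(0, 0.6293, 0.6293, -0.6293, -0.6293)
    )
  )
  bad <- setdiff(names, names(all))
  if (length(bad) > 0) stop("unknown template(s): ", paste(bad, collapse = ", "))
  lapply(
    stats::setNames(names, names),
    function(n) atomic_structure(all[[n]], id = n)
  )
}

#' Specification of a synthetic molecular-crystal dataset
#'
#' The generator emulates the statistical structure of a curated
#' organic-crystal dataset: per-atom total energies dominated by a
#' composition baseline, with a small lattice-energy signal (standard
#' deviation `target_sd_delta`, kJ per mol of atoms) that is exactly
#' linear in the atom-centered remnant descriptor, plus optional Gaussian
#' noise and an optional pairwise Lennard-Jones-like term ("hard mode")
#' that breaks the linearity to probe model misspecification.
#'
#' @param seed Integer seed; the same seed reproduces the dataset
#'   byte-identically.
#' @param n_crystals Number of crystals.
#' @param templates Template names (see [molecule_templates()]).
#' @param n_molecules_range Min/max molecules per cell.
#' @param cell_range Cubic cell side range (angstrom).
#' @param min_contact Minimum intermolecular contact distance enforced by
#'   rejection sampling (angstrom).
#' @param conformer_sigma Per-molecule conformational jitter (angstrom):
#'   each placed molecule gets a small Gaussian distortion of its template
#'   geometry, and its gas-phase reference uses the SAME distorted
#'   conformer.  The conformational term therefore cancels exactly in the
#'   remnant descriptor, while the solid-phase descriptor alone cannot
#'   separate conformation from packing -- mirroring real crystallization,
#'   where molecules deform upon packing.
#' @param noise_sigma Gaussian noise on the per-atom lattice energy
#'   (kJ per mol of atoms), added last.
#' @param target_sd_delta Dataset standard deviation the planted noiseless
#'   `delta_c` is scaled to (kJ per mol of atoms).
#' @param baseline Named per-element energies (kJ per mol of atoms)
#'   forming the composition-dominated part of the total energies.
#' @param descriptor_cfg [soap_config()] the planted energies are linear
#'   in (kept modest by default so desk-scale studies stay fast).
#' @param lj_epsilon Strength of the optional pairwise term (0 = off).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(seed = 1L, n_crystals = 50L,
                           templates = c("water", "formaldehyde", "ammonia"),
                           n_molecules_range = c(2L, 4L),
                           cell_range = c(5.0, 6.5),
                           min_contact = 1.8,
                           conformer_sigma = 0.15,
                           noise_sigma = 0,
                           target_sd_delta = 2.0,
                           baseline = c(H = -500, C = -2000, N = -2600, O = -3200),
                           descriptor_cfg = NULL,
                           lj_epsilon = 0) {
  if (is.null(descriptor_cfg)) {
    el <- sort(unique(unlist(lapply(
      molecule_templates(templates),
      species
    ))))
    descriptor_cfg <- soap_config(
      r_cut = 4.0, n_max = 3L, l_max = 3L, sigma_atom = 0.35,
      species = el, n_quad = 60L
    )
  }
  structure(
    list(
      seed = as.integer(seed), n_crystals = as.integer(n_crystals),
      templates = templates, n_molecules_range = as.integer(n_molecules_range),
      cell_range = cell_range, min_contact = min_contact,
      conformer_sigma = conformer_sigma,
      noise_sigma = noise_sigma, target_sd_delta = target_sd_delta,
      baseline = baseline, descriptor_cfg = descriptor_cfg,
      lj_epsilon = lj_epsilon
    ),
    class = "synthetic_spec"
  )
}

random_rotation <- function() {
  # uniform over SO(3) via QR of a Gaussian matrix
  repeat {
    M <- matrix(stats::rnorm(9), 3, 3)
    qrm <- qr(M)
    Q <- qr.Q(qrm)
    Q <- Q %*% diag(sign(diag(qr.R(qrm))))
    if (det(Q) > 0) return(Q)
  }
}

# minimum-image distances between a candidate atom block and existing atoms
min_image_dist <- function(new_pos, old_pos, cell) {
  inv <- solve(cell)
  mind <- Inf
  for (i in seq_len(nrow(new_pos))) {
    dv <- sweep(old_pos, 2, new_pos[i, ])
    df <- dv %*% inv
    df <- df - round(df)
    # search adjacent images around the rounded minimum (cubic cells here)
    for (sa in -1:1) for (sb in -1:1) for (sc in -1:1) {
      dd <- (df + matrix(rep(c(sa, sb, sc), each = nrow(df)), ncol = 3)) %*% cell
      mind <- min(mind, sqrt(min(rowSums(dd^2))))
    }
  }
  mind
}

pack_crystal <- function(tmpls, which_mols, side, min_contact,
                         conformer_sigma = 0, max_tries = 300) {
  cell <- diag(3) * side
  atoms <- NULL
  pos_all <- NULL
  gas_mols <- vector("list", length(which_mols))
  for (mi in seq_along(which_mols)) {
    t0 <- tmpls[[which_mols[mi]]]
    base0 <- positions(t0)
    base0 <- sweep(base0, 2, colMeans(base0))
    ref_edges <- build_bond_graph(t0)[, c("i", "j")]
    base <- base0
    if (conformer_sigma > 0) {
      # redraw the jitter until the covalent topology is unchanged
      for (jt in 1:100) {
        base <- base0 + matrix(
          stats::rnorm(length(base0), 0, conformer_sigma),
          nrow(base0), 3
        )
        cand_mol <- atomic_structure(
          tibble::tibble(
            element = species(t0),
            x = base[, 1], y = base[, 2], z = base[, 3]
          )
        )
        if (identical(
          build_bond_graph(cand_mol)[, c("i", "j")],
          ref_edges
        )) {
          break
        }
        base <- base0
      }
    }
    # the gas-phase reference is the same conformer (relaxed geometry
    # taken equal to the in-crystal one)
    gas_mols[[mi]] <- atomic_structure(
      tibble::tibble(
        element = species(t0),
        x = base[, 1], y = base[, 2], z = base[, 3]
      ),
      id = t0$id
    )
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      rot <- random_rotation()
      shiftv <- stats::runif(3, 0, side)
      cand <- sweep(base %*% t(rot), 2, shiftv, "+")
      if (is.null(pos_all) ||
        min_image_dist(cand, pos_all, cell) >= min_contact) {
        ok <- TRUE
        break
      }
    }
    if (!ok) return(NULL)
    atoms <- dplyr::bind_rows(atoms, tibble::tibble(
      element = species(t0), x = cand[, 1], y = cand[, 2], z = cand[, 3]
    ))
    pos_all <- rbind(pos_all, cand)
  }
  list(
    crystal = atomic_structure(atoms, cell = cell, pbc = TRUE),
    gas = gas_mols
  )
}

lj_pair_energy <- function(s, epsilon, sigma = 2.9, cutoff = 6.0) {
  if (epsilon == 0) return(0)
  comps <- extract_molecules(s)
  mol_of <- rep(NA_integer_, n_atoms(s))
  for (k in seq_along(comps)) mol_of[comps[[k]]$index_map] <- k
  pt <- pair_table(s, cutoff)
  pt <- pt[mol_of[pt$i] != mol_of[pt$j], , drop = FALSE]
  if (nrow(pt) == 0) return(0)
  sr6 <- (sigma / pt$d)^6
  sum(4 * epsilon * (sr6^2 - sr6))
}

#' Generate a synthetic dataset of molecular crystals
#'
#' Random rigid placements of the template molecules in cubic periodic
#' boxes (rejection sampling against a minimum-contact distance), with
#' per-atom energies planted as a composition term plus a fixed linear
#' function of that atom's descriptor (computed with
#' `spec$descriptor_cfg`).  Gas-phase energies use the isolated templates,
#' so the planted lattice energy `Delta_c = E_c - sum(E_m)` is exactly
#' linear in the remnant descriptor; Gaussian noise is added last.  The
#' planted linear weights are scaled once so the noiseless `delta_c` has
#' the spec's target standard deviation.
#'
#' @param spec A [synthetic_spec()].
#' @return A `synthetic_dataset`: list with `records` (crystal records),
#'   `descriptors` (`solid` per crystal, `gas` per crystal, one set per
#'   molecule),
#'   `remnants` (per crystal: `per_atom`, `collection`), `planted`
#'   (`w_star`, noiseless `delta_c`, per-atom contributions), `energy`
#'   (the [energy_view()] tibble), and the `spec`.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, globalenv())
    }
  })
  set.seed(spec$seed)
  tmpls <- molecule_templates(spec$templates)
  cfg <- spec$descriptor_cfg

  crystals <- vector("list", spec$n_crystals)
  gas_structs <- vector("list", spec$n_crystals)
  for (i in seq_len(spec$n_crystals)) {
    made <- NULL
    for (restart in 1:50) {
      nm <- sample(seq(spec$n_molecules_range[1], spec$n_molecules_range[2]), 1)
      which_mols <- sample(names(tmpls), nm, replace = TRUE)
      side <- stats::runif(1, spec$cell_range[1], spec$cell_range[2]) *
        (nm / mean(spec$n_molecules_range))^(1 / 3)
      made <- pack_crystal(tmpls, which_mols, side, spec$min_contact,
        conformer_sigma = spec$conformer_sigma
      )
      if (!is.null(made)) break
    }
    if (is.null(made)) {
      stop(sprintf(
        "infeasible packing for crystal %d (cells too small for min_contact = %g)",
        i, spec$min_contact
      ), call. = FALSE)
    }
    made$crystal$id <- sprintf("synth_%04d", i)
    crystals[[i]] <- made$crystal
    gas_structs[[i]] <- made$gas
  }

  ds_solid <- lapply(crystals, compute_descriptors, cfg = cfg)
  ds_gas <- lapply(gas_structs, function(gl) {
    lapply(gl, compute_descriptors, cfg = cfg)
  })

  # planted weights, scaled once to the target lattice-energy spread
  w_star <- stats::rnorm(n_features(cfg))
  raw_delta <- vapply(seq_len(spec$n_crystals), function(i) {
    Xg <- do.call(rbind, lapply(ds_gas[[i]], function(d) d$X))
    mean((ds_solid[[i]]$X - Xg) %*% w_star)
  }, numeric(1))
  sdr <- stats::sd(raw_delta)
  if (sdr >= 1e-12) {
    w_star <- w_star * spec$target_sd_delta / sdr
  } else {
    # no intermolecular signal (e.g. molecules placed beyond r_cut):
    # leave the weights unscaled; all planted lattice energies are ~ 0
    warning("planted lattice-energy signal is degenerate (no contacts?); ",
      "weights left unscaled")
  }

  noise <- stats::rnorm(spec$n_crystals, 0, spec$noise_sigma)
  records <- vector("list", spec$n_crystals)
  planted_delta <- numeric(spec$n_crystals)
  planted_atoms <- vector("list", spec$n_crystals)
  remnants <- vector("list", spec$n_crystals)
  for (i in seq_len(spec$n_crystals)) {
    E_m <- vapply(seq_along(gas_structs[[i]]), function(k) {
      sum(spec$baseline[species(gas_structs[[i]][[k]])]) +
        sum(ds_gas[[i]][[k]]$X %*% w_star)
    }, numeric(1))
    n_c <- n_atoms(crystals[[i]])
    E_lj <- lj_pair_energy(crystals[[i]], spec$lj_epsilon)
    E_c <- sum(spec$baseline[species(crystals[[i]])]) +
      sum(ds_solid[[i]]$X %*% w_star) + E_lj + n_c * noise[i]
    rec <- assemble_crystal_record(
      crystals[[i]], gas_structs[[i]],
      E_crystal = E_c, E_molecules = E_m
    )
    records[[i]] <- rec
    remnants[[i]] <- remnant_descriptor(rec, ds_solid[[i]], ds_gas[[i]])
    per_atom <- as.vector(remnants[[i]]$per_atom %*% w_star)
    planted_atoms[[i]] <- per_atom
    planted_delta[i] <- mean(per_atom)
  }

  out <- structure(
    list(
      records = records,
      descriptors = list(solid = ds_solid, gas = ds_gas),
      remnants = remnants,
      planted = list(
        w_star = w_star, delta_c = planted_delta,
        per_atom = planted_atoms, noise = noise
      ),
      spec = spec
    ),
    class = "synthetic_dataset"
  )
  out$energy <- energy_view(records)
  out
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset: %d crystals, templates %s, noise sd %g, sd(delta_c) %.3f>\n",
    length(x$records), paste(x$spec$templates, collapse = "/"),
    x$spec$noise_sigma, stats::sd(x$energy$delta_c)
  ))
  invisible(x)
}

#' Write a synthetic dataset in the package's exchange layout
#'
#' Crystals go to `crystals.xyz`, gas molecules to `molecules.xyz`
#' (extended XYZ, ids linking molecules to their parent crystal), energies
#' to `energies.csv` (`id`, `kind`, `parent_id`, `E_kJ_per_mol`) and the
#' generator settings to `spec.yaml`.
#'
#' @param ds A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  crystals <- lapply(ds$records, function(r) r$crystal)
  write_extxyz(crystals, file.path(dir, "crystals.xyz"))
  mols <- list()
  rows <- list()
  for (r in ds$records) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      id = r$crystal$id, kind = "crystal", parent_id = "",
      E_kJ_per_mol = r$E_crystal
    )
    for (k in seq_along(r$molecules)) {
      m <- r$molecules[[k]]$gas_structure
      m$id <- sprintf("%s_mol%d", r$crystal$id, k)
      mols[[length(mols) + 1]] <- m
      rows[[length(rows) + 1]] <- tibble::tibble(
        id = m$id, kind = "molecule", parent_id = r$crystal$id,
        E_kJ_per_mol = r$molecules[[k]]$E
      )
    }
  }
  write_extxyz(mols, file.path(dir, "molecules.xyz"))
  readr::write_csv(dplyr::bind_rows(rows), file.path(dir, "energies.csv"))
  sp <- ds$spec
  sp$descriptor_cfg <- unclass(sp$descriptor_cfg)
  yaml::write_yaml(unclass(sp), file.path(dir, "spec.yaml"))
  invisible(dir)
}

#' Deterministic micro-fixtures for unit tests and worked examples
#'
#' A named bundle of tiny, hand-constructed cases: the two-atom filter
#' geometry, linear/bent/long hydrogen-bond probes, a periodic cell with
#' two waters, an O-H dimer, a periodic chain bonded to its own image
#' (polymeric), and reference molecules given as SMILES.
#'
#' @return Named list; entries are [atomic_structure()]s or SMILES
#'   strings (`succinic_acid`, `phenanthrene`, `benzene`).
#' @export
make_worked_micro_examples <- function() {
  st <- function(el, m, id) {
    atomic_structure(
      tibble::tibble(element = el, x = m[, 1], y = m[, 2], z = m[, 3]),
      id = id
    )
  }
  list(
    two_atom_filter = st(
      c("C", "C"), rbind(c(0, 0, 0), c(1.0, 0, 0)), "two_atom_filter"
    ),
    oh_dimer = st(c("O", "H"), rbind(c(0, 0, 0), c(1.0, 0, 0)), "oh_dimer"),
    # donor hydroxyl O-H ... acceptor O: linear at 1.9 A
    hbond_linear = st(
      c("O", "H", "O"),
      rbind(c(0, 0, 0), c(0.97, 0, 0), c(2.87, 0, 0)), "hbond_linear"
    ),
    # H...A too long (2.6 A)
    hbond_long = st(
      c("O", "H", "O"),
      rbind(c(0, 0, 0), c(0.97, 0, 0), c(3.57, 0, 0)), "hbond_long"
    ),
    # bent to 120 degrees at 1.9 A
    hbond_bent = st(
      c("O", "H", "O"),
      rbind(
        c(0, 0, 0), c(0.97, 0, 0),
        c(0.97 + 1.9 * cos(pi / 3), 1.9 * sin(pi / 3), 0)
      ), "hbond_bent"
    ),
    two_waters_cell = atomic_structure(
      dplyr::bind_rows(
        tibble::tibble(
          element = c("O", "H", "H"),
          x = c(1, 1.9572, 0.7601), y = c(1, 1, 1.9266), z = c(1, 1, 1)
        ),
        tibble::tibble(
          element = c("O", "H", "H"),
          x = c(5, 5.9572, 4.7601), y = c(5, 5, 5.9266), z = c(5, 5, 5)
        )
      ),
      cell = diag(3) * 10, pbc = TRUE, id = "two_waters_cell"
    ),
    polymer_chain = atomic_structure(
      tibble::tibble(element = "C", x = 0, y = 5, z = 5),
      cell = diag(c(1.4, 10, 10)), pbc = TRUE, id = "polymer_chain"
    ),
    succinic_acid = "OC(=O)CCC(=O)O",
    phenanthrene = "c1ccc2ccc3ccccc3c2c1",
    benzene = "c1ccccc1"
  )
}
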