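#' Covalent radii (angstrom)
#'
#' Single-bond covalent radii (Cordero-type values) used for bond
#' perception.  For carbon the sp3 value is used.
#'
#' @return Named numeric vector of radii in angstrom.
#' @export
covalent_radii <- function() {
  c(
    H = 0.31, He = 0.28,
    B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57, Ne = 0.58,
    Na = 1.66, Mg = 1.41, Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02,
    Br = 1.20, I = 1.39
  )
}

# All displacement vectors from atoms i to atoms j (and the integer lattice
# shifts applied to j), searching periodic images so the minimum-image pair
# is always found.  Returns, per (i, j) pair considered, the closest image.
# For non-periodic structures this is plain pairwise geometry.
pair_table <- function(s, rmax) {
  pos <- positions(s)
  n <- nrow(pos)
  if (n < 2 && !any(s$pbc)) {
    return(tibble::tibble(
      i = integer(), j = integer(), d = numeric(),
      sa = integer(), sb = integer(), sc = integer()
    ))
  }
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  if (n >= 2) {
    i <- idx[, 1]; j <- idx[, 2]
  } else {
    i <- integer(); j <- integer()
  }
  if (!any(s$pbc)) {
    dvec <- pos[j, , drop = FALSE] - pos[i, , drop = FALSE]
    d <- sqrt(rowSums(dvec^2))
    keep <- d <= rmax
    return(tibble::tibble(
      i = i[keep], j = j[keep], d = d[keep],
      sa = 0L, sb = 0L, sc = 0L
    ))
  }
  cell <- s$cell
  inv <- solve(cell)
  # include self pairs (i == j) against periodic images for chains bonded to
  # their own image
  i <- c(i, seq_len(n)); j <- c(j, seq_len(n))
  dcart <- pos[j, , drop = FALSE] - pos[i, , drop = FALSE]
  dfrac <- dcart %*% inv
  base <- round(dfrac)
  # how many neighbor cells must be searched so nothing within rmax is missed
  perp <- abs(det(cell)) / c(
    sqrt(sum(cross3(cell[2, ], cell[3, ])^2)),
    sqrt(sum(cross3(cell[3, ], cell[1, ])^2)),
    sqrt(sum(cross3(cell[1, ], cell[2, ])^2))
  )
  reach <- pmin(ceiling(rmax / perp), 3L)
  shifts <- as.matrix(expand.grid(
    sa = -(reach[1] + 1L):(reach[1] + 1L),
    sb = -(reach[2] + 1L):(reach[2] + 1L),
    sc = -(reach[3] + 1L):(reach[3] + 1L)
  ))
  out <- vector("list", nrow(shifts))
  for (k in seq_len(nrow(shifts))) {
    sh <- sweep(-base, 2, shifts[k, ], "+")
    dv <- dcart + sh %*% cell
    d <- sqrt(rowSums(dv^2))
    keep <- d <= rmax & !(i == j & sh[, 1] == 0 & sh[, 2] == 0 & sh[, 3] == 0)
    if (any(keep)) {
      out[[k]] <- tibble::tibble(
        i = i[keep], j = j[keep], d = d[keep],
        sa = as.integer(sh[keep, 1]), sb = as.integer(sh[keep, 2]),
        sc = as.integer(sh[keep, 3])
      )
    }
  }
  dplyr::bind_rows(out)
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

#' Perceive covalent bonds from interatomic distances
#'
#' Two atoms are bonded when their (minimum-image, for periodic structures)
#' distance does not exceed `scale` times the sum of their covalent radii.
#' For periodic structures every relevant lattice image is searched, and the
#' integer image shift realizing each bond is recorded so molecules can
#' later be unwrapped.
#'
#' @param s An [atomic_structure()].
#' @param scale Multiplier on the sum of covalent radii (default 1.2).
#' @return A `bond_graph`: a tibble with columns `i`, `j` (1-based atom
#'   indices), `d` (angstrom) and `sa`, `sb`, `sc` (lattice shift applied to
#'   atom `j`), with class `"bond_graph"`.
#' @export
build_bond_graph <- function(s, scale = 1.2) {
  if (any(s$pbc) && is.null(s$cell)) {
    stop("build_bond_graph: periodic structure without a cell", call. = FALSE)
  }
  rcov <- covalent_radii()
  validate_elements(species(s))
  ri <- rcov[species(s)]
  rmax <- scale * 2 * max(ri)
  pt <- pair_table(s, rmax)
  if (nrow(pt) > 0) {
    cut <- scale * (ri[pt$i] + ri[pt$j])
    pt <- pt[pt$d <= cut, , drop = FALSE]
    # a pair may bond through several images (e.g. small cells); keep all
    pt <- dplyr::distinct(pt)
  }
  structure(pt, class = c("bond_graph", class(pt)))
}

#' Extract whole molecules from a (possibly periodic) structure
#'
#' Connected components of the bond graph are traversed breadth-first while
#' accumulating lattice image shifts, so each molecule is unwrapped: every
#' bonded pair ends at its direct (non-wrapped) distance.  A component that
#' bonds to its own periodic image with a non-zero net shift is not a finite
#' molecule; this raises a "not a molecular crystal" error.
#'
#' @param s An [atomic_structure()].
#' @param g A [build_bond_graph()] result for `s` (computed if `NULL`).
#' @return A list with one entry per molecule, each a list with elements
#'   `structure` (non-periodic [atomic_structure()], unwrapped coordinates)
#'   and `index_map` (1-based indices of the molecule's atoms in `s`, in the
#'   same atom order).
#' @export
extract_molecules <- function(s, g = NULL) {
  if (is.null(g)) g <- build_bond_graph(s)
  n <- n_atoms(s)
  # adjacency with shifts: edge i->j shift applies to j; reverse is -shift
  adj <- vector("list", n)
  if (nrow(g) > 0) {
    for (r in seq_len(nrow(g))) {
      adj[[g$i[r]]] <- c(adj[[g$i[r]]], list(c(g$j[r], g$sa[r], g$sb[r], g$sc[r])))
      adj[[g$j[r]]] <- c(adj[[g$j[r]]], list(c(g$i[r], -g$sa[r], -g$sb[r], -g$sc[r])))
    }
  }
  seen <- rep(FALSE, n)
  shift <- matrix(NA_real_, n, 3)
  comp <- integer(n)
  ncomp <- 0L
  for (start in seq_len(n)) {
    if (seen[start]) next
    ncomp <- ncomp + 1L
    queue <- list(c(start, 0, 0, 0))
    seen[start] <- TRUE
    shift[start, ] <- 0
    comp[start] <- ncomp
    while (length(queue) > 0) {
      cur <- queue[[1]]; queue <- queue[-1]
      a <- cur[1]
      for (e in adj[[a]]) {
        b <- e[1]
        sb_ <- shift[a, ] + e[2:4]
        if (!seen[b]) {
          seen[b] <- TRUE
          shift[b, ] <- sb_
          comp[b] <- ncomp
          queue <- c(queue, list(c(b, sb_)))
        } else if (any(abs(shift[b, ] - sb_) > 1e-9)) {
          stop(sprintf(
            paste0(
              "not a molecular crystal: component containing atom %d is ",
              "polymeric (bonded to its own periodic image)"
            ), b
          ), call. = FALSE)
        }
      }
    }
  }
  pos <- positions(s)
  if (any(s$pbc)) pos <- pos + shift %*% s$cell
  lapply(seq_len(ncomp), function(k) {
    idx <- which(comp == k)
    list(
      structure = atomic_structure(
        tibble::tibble(
          element = species(s)[idx],
          x = pos[idx, 1], y = pos[idx, 2], z = pos[idx, 3]
        ),
        id = sprintf("%s_mol%d", s$id, k)
      ),
      index_map = idx
    )
  })
}

# Kabsch RMSD after optimal superposition (both structures centered).
superposition_rmsd <- function(a, b) {
  pa <- scale(positions(a), scale = FALSE)
  pb <- scale(positions(b), scale = FALSE)
  sv <- svd(crossprod(pa, pb))
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sqrt(mean(rowSums((pb - pa %*% t(rot))^2)))
}

#' Pair a crystal with its gas-phase molecular constituents
#'
#' Extracts molecules from the crystal and assigns each supplied gas-phase
#' molecule to one extracted component.  Assignment is by sorted-species
#' string first and, when several components share a composition, by lowest
#' RMSD after optimal superposition; remaining ties are broken by input
#' order, so the pairing is deterministic.
#'
#' @param crystal Periodic [atomic_structure()].
#' @param gas_molecules List of non-periodic [atomic_structure()] objects,
#'   the relaxed gas-phase geometry of each molecule in the cell.
#' @param E_crystal Total energy of the crystal (kJ/mol).
#' @param E_molecules Numeric vector: total energy of each gas molecule
#'   (kJ/mol), aligned with `gas_molecules`.
#' @param bond_scale Covalent-radius multiplier for bond perception.
#' @return A `crystal_record`: list with `crystal`, `molecules` (each with
#'   `gas_structure`, `index_map`, `E`), `E_crystal`, `E_molecules`.
#' @export
assemble_crystal_record <- function(crystal, gas_molecules, E_crystal,
                                    E_molecules, bond_scale = 1.2) {
  stopifnot(length(gas_molecules) >= 1)
  stopifnot(length(E_molecules) == length(gas_molecules))
  comps <- extract_molecules(crystal, build_bond_graph(crystal, bond_scale))
  if (length(comps) != length(gas_molecules)) {
    stop(sprintf(
      "composition mismatch: crystal has %d molecular components but %d gas molecules supplied",
      length(comps), length(gas_molecules)
    ), call. = FALSE)
  }
  keyof <- function(st) paste(sort(species(st)), collapse = "")
  comp_keys <- vapply(comps, function(cm) keyof(cm$structure), "")
  gas_keys <- vapply(gas_molecules, keyof, "")
  if (!identical(sort(comp_keys), sort(gas_keys))) {
    stop("composition mismatch between crystal components and gas molecules",
      call. = FALSE
    )
  }
  taken <- rep(FALSE, length(comps))
  molecules <- vector("list", length(gas_molecules))
  for (gi in seq_along(gas_molecules)) {
    cand <- which(!taken & comp_keys == gas_keys[gi])
    if (length(cand) > 1) {
      r <- vapply(
        cand,
        function(ci) {
          tryCatch(
            superposition_rmsd(
              sort_by_species(gas_molecules[[gi]]),
              sort_by_species(comps[[ci]]$structure)
            ),
            error = function(e) Inf
          )
        },
        numeric(1)
      )
      cand <- cand[order(r)]
    }
    ci <- cand[1]
    taken[ci] <- TRUE
    # reorder the gas molecule's atoms to match the component's species order
    gmol <- align_species_order(gas_molecules[[gi]], comps[[ci]]$structure)
    molecules[[gi]] <- list(
      gas_structure = gmol,
      index_map = comps[[ci]]$index_map,
      E = E_molecules[gi]
    )
  }
  nc <- n_atoms(crystal)
  nm <- sum(vapply(molecules, function(m) n_atoms(m$gas_structure), numeric(1)))
  stopifnot(nc == nm)
  structure(
    list(
      crystal = crystal, molecules = molecules,
      E_crystal = E_crystal,
      E_molecules = vapply(molecules, function(m) m$E, numeric(1))
    ),
    class = "crystal_record"
  )
}

sort_by_species <- function(st) {
  o <- order(species(st))
  atomic_structure(st$atoms[o, ], id = st$id)
}

# Reorder atoms of `g` so its species sequence matches `ref`'s; within an
# element the original relative order is kept.
align_species_order <- function(g, ref) {
  if (identical(species(g), species(ref))) return(g)
  o <- integer(0)
  pool <- seq_len(n_atoms(g))
  for (el in species(ref)) {
    hit <- pool[species(g)[pool] == el][1]
    if (is.na(hit)) stop("species mismatch while aligning molecules", call. = FALSE)
    o <- c(o, hit)
    pool <- setdiff(pool, hit)
  }
  atomic_structure(g$atoms[o, ], id = g$id, tags = g$tags)
}

#' @export
print.crystal_record <- function(x, ...) {
  cat(sprintf(
    "<crystal_record '%s': %d atoms, %d molecules, E_crystal = %.3f kJ/mol>\n",
    x$crystal$id, n_atoms(x$crystal), length(x$molecules), x$E_crystal
  ))
  invisible(x)
}

#' Energy bookkeeping for a crystal record
#'
#' Computes the per-atom total energies, the lattice (binding) energy
#' `Delta_c = E_c - sum(E_m)` and its per-atom value `delta_c = Delta_c /
#' n_c`.  All energies are kJ/mol; per-atom quantities are kJ per mol of
#' atoms.  Negative `delta_c` means the crystal binds.
#'
#' @param rec A `crystal_record` (or list of them).
#' @return A tibble with one row per record: `id`, `n_c`, `E_c`, `e_c`,
#'   `Delta_c`, `delta_c`, plus list-columns `n_m`, `e_m` for the molecules.
#' @export
energy_view <- function(rec) {
  recs <- if (inherits(rec, "crystal_record")) list(rec) else rec
  purrr::map_dfr(recs, function(r) {
    n_c <- n_atoms(r$crystal)
    n_m <- vapply(r$molecules, function(m) n_atoms(m$gas_structure), numeric(1))
    Delta <- r$E_crystal - sum(r$E_molecules)
    em <- r$E_molecules / n_m
    tibble::tibble(
      id = r$crystal$id,
      n_c = n_c,
      E_c = r$E_crystal,
      e_c = r$E_crystal / n_c,
      Delta_c = Delta,
      delta_c = Delta / n_c,
      n_m = list(n_m),
      e_m = list(em)
    )
  })
}

#' Read an energy table
#'
#' CSV with columns `id`, `kind` (`"crystal"` or `"molecule"`),
#' `parent_id` (crystal id a molecule belongs to; empty for crystals) and
#' `E_kJ_per_mol`.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_energy_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("id", "kind", "parent_id", "E_kJ_per_mol")
  if (!all(need %in% names(tab))) {
    stop("energy table must have columns ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  tab
}
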