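#' Locate the Python interpreter used for SMARTS matching
#'
#' SMARTS substructure matching is delegated to RDKit through a bundled
#' Python helper script.  The interpreter is found from, in order, the
#' option `latticemotifs.python`, the environment variable
#' `LATTICEMOTIFS_PYTHON`, then `python3` / `python` on the PATH.
#'
#' @return Path to the interpreter.
#' @export
find_python <- function() {
  cand <- c(
    getOption("latticemotifs.python", ""),
    Sys.getenv("LATTICEMOTIFS_PYTHON", ""),
    Sys.which("python3"), Sys.which("python")
  )
  cand <- cand[nzchar(cand)]
  if (length(cand) == 0) {
    stop("no Python interpreter found (needed for SMARTS motif matching)",
      call. = FALSE
    )
  }
  cand[[1]]
}

motif_helper_path <- function() {
  p <- system.file("python", "motif_match.py", package = "latticemotifs")
  if (!nzchar(p)) {
    # during development (load_all) inst/ is not installed
    p <- file.path("inst", "python", "motif_match.py")
  }
  if (!file.exists(p)) stop("motif_match.py helper not found", call. = FALSE)
  p
}

# One batched call to the RDKit helper.  `molecules` is a list of specs
# (see inst/python/motif_match.py); `patterns` a tibble with name, smarts,
# add_h.  Returns the parsed JSON.
call_motif_helper <- function(molecules, patterns) {
  job <- list(
    molecules = molecules,
    patterns = purrr::pmap(
      list(patterns$name, patterns$smarts, patterns$add_h %||% TRUE),
      function(n, s, a) list(name = n, smarts = s, add_h = a)
    )
  )
  infile <- tempfile(fileext = ".json")
  on.exit(unlink(infile))
  jsonlite::write_json(job, infile, auto_unbox = TRUE, digits = NA)
  out <- suppressWarnings(system2(
    find_python(), shQuote(motif_helper_path()),
    stdout = TRUE, stderr = TRUE, stdin = infile
  ))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop(
      "SMARTS helper failed:\n", paste(out, collapse = "\n"),
      call. = FALSE
    )
  }
  jsonlite::parse_json(paste(out, collapse = ""))
}

molecule_spec <- function(m, bonds = NULL, smiles = NULL, charge = 0L) {
  if (!is.null(smiles)) {
    return(list(id = if (is.character(m)) m else m$id, smiles = smiles))
  }
  stopifnot(inherits(m, "atomic_structure"))
  if (is.null(bonds)) bonds <- build_bond_graph(m)
  pos <- positions(m)
  list(
    id = m$id,
    elements = species(m),
    coords = lapply(seq_len(nrow(pos)), function(i) as.numeric(pos[i, ])),
    bonds = if (nrow(bonds) > 0) {
      lapply(seq_len(nrow(bonds)), function(r) c(bonds$i[r] - 1L, bonds$j[r] - 1L))
    } else {
      list()
    },
    charge = charge
  )
}

#' Perceive a molecular graph (bond orders, aromaticity)
#'
#' Builds an annotated molecular graph for SMARTS semantics.  When a
#' SMILES string is supplied it is used verbatim (the preferred path);
#' otherwise bond orders and aromatic flags are perceived from the 3-D
#' coordinates and connectivity via RDKit.  Valence problems downgrade to
#' single-bond connectivity with a warning recorded in the result.
#'
#' @param m An [atomic_structure()] (finite molecule), or an id string
#'   when `smiles` is given.
#' @param bonds Optional [build_bond_graph()] result (computed if absent).
#' @param smiles Optional SMILES; takes precedence over coordinates.
#' @return A `molecular_graph`: list with `id`, tibbles `atoms` (element,
#'   aromatic, n_h) and `bonds` (i, j, order, aromatic; 1-based), `rings`
#'   (list of atom-index vectors), `warnings`, and the `spec` reused for
#'   matching.
#' @export
perceive_molecular_graph <- function(m, bonds = NULL, smiles = NULL) {
  spec <- molecule_spec(m, bonds, smiles)
  res <- call_motif_helper(list(spec), tibble::tibble(
    name = character(), smarts = character(), add_h = logical()
  ))$molecules[[1]]
  if (!isTRUE(res$ok)) stop(res$error, call. = FALSE)
  graph_from_result(res, spec)
}

graph_from_result <- function(res, spec) {
  warn <- unlist(res$warnings)
  if (length(warn) > 0) {
    warning(
      "graph perception for '", res$id, "': ",
      paste(warn, collapse = "; ")
    )
  }
  structure(
    list(
      id = res$id,
      atoms = purrr::map_dfr(res$atoms, tibble::as_tibble),
      bonds = if (length(res$bonds) > 0) {
        purrr::map_dfr(res$bonds, tibble::as_tibble) |>
          dplyr::mutate(i = .data$i + 1L, j = .data$j + 1L)
      } else {
        tibble::tibble(
          i = integer(), j = integer(),
          order = numeric(), aromatic = logical()
        )
      },
      rings = lapply(res$rings, function(r) unlist(r) + 1L),
      warnings = warn %||% character(),
      spec = spec
    ),
    class = "molecular_graph"
  )
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf(
    "<molecular_graph '%s': %d atoms, %d bonds, %d rings>\n",
    x$id, nrow(x$atoms), nrow(x$bonds), length(x$rings)
  ))
  invisible(x)
}

#' Default functional-group motif table
#'
#' A reconstruction of the common functional-group classes used for the
#' motif census (water, carboxylic acid, nitro/nitroso, amines, amide,
#' ether, alkyl/alkene groups, 6-membered unsaturated carbon rings, azoles,
#' imide), as editable SMARTS rows.  `add_h` grows each match with the
#' hydrogens bonded to matched heavy atoms (so e.g. a water motif has 3
#' atoms and its per-atom contribution times 3 is the per-molecule value).
#' `min_count` is the reporting threshold for census summaries.
#'
#' @param path Optional TSV (columns `name`, `smarts`, optional `add_h`,
#'   `notes`) replacing the built-in table.
#' @param min_count Reporting threshold attached to every pattern
#'   (default 200).
#' @return Tibble with columns `name`, `smarts`, `add_h`, `min_count`,
#'   `notes`.
#' @export
motif_patterns <- function(path = NULL, min_count = 200L) {
  if (is.null(path)) {
    path <- system.file("extdata", "motifs_default.tsv",
      package = "latticemotifs"
    )
    if (!nzchar(path)) path <- file.path("inst", "extdata", "motifs_default.tsv")
  }
  # no comment character: SMARTS uses '#' for atomic numbers
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("name", "smarts") %in% names(tab)))
  if (anyDuplicated(tab$name)) stop("duplicate motif names", call. = FALSE)
  if (!"add_h" %in% names(tab)) tab$add_h <- TRUE
  if (!"notes" %in% names(tab)) tab$notes <- ""
  tab$min_count <- as.integer(min_count)
  tab[, c("name", "smarts", "add_h", "min_count", "notes")]
}

#' Match motif patterns against molecular graphs
#'
#' Runs RDKit substructure matching for every pattern on every molecule,
#' collapsing symmetry-equivalent matches to unique atom sets.  Matching
#' is purely graph-based: it ignores 3-D coordinates and is invariant to
#' atom reordering.
#'
#' @param graphs A `molecular_graph` or list of them (see
#'   [perceive_molecular_graph()]).
#' @param patterns Tibble with columns `name`, `smarts`, optional `add_h`
#'   (see [motif_patterns()]).
#' @return Tibble of motif instances: `molecule_id`, `pattern`, `atoms`
#'   (list-column of 1-based atom indices within the molecule), `n_atoms`.
#' @export
match_motifs <- function(graphs, patterns) {
  if (inherits(graphs, "molecular_graph")) graphs <- list(graphs)
  res <- call_motif_helper(lapply(graphs, function(g) g$spec), patterns)
  purrr::map_dfr(res$molecules, function(m) {
    if (!isTRUE(m$ok)) stop(m$error, call. = FALSE)
    if (length(m$matches) == 0) {
      return(tibble::tibble(
        molecule_id = character(), pattern = character(),
        atoms = list(), n_atoms = integer()
      ))
    }
    tibble::tibble(
      molecule_id = m$id,
      pattern = vapply(m$matches, function(x) x$pattern, ""),
      atoms = lapply(m$matches, function(x) unlist(x$atoms) + 1L),
      n_atoms = vapply(m$matches, function(x) length(x$atoms), integer(1))
    )
  })
}

#' Count motif instances per pattern
#' @param instances Output of [match_motifs()].
#' @param patterns The pattern table used (for zero counts and
#'   `min_count`).
#' @return Tibble `pattern`, `count`, `low_sample` (below `min_count`).
#' @export
count_motifs <- function(instances, patterns) {
  counts <- instances |>
    dplyr::count(.data$pattern, name = "count")
  patterns |>
    dplyr::select("name", "min_count") |>
    dplyr::left_join(counts, by = c(name = "pattern")) |>
    dplyr::mutate(
      count = dplyr::coalesce(.data$count, 0L),
      low_sample = .data$count < .data$min_count
    ) |>
    dplyr::rename(pattern = "name") |>
    dplyr::select("pattern", "count", "low_sample")
}

# --------------------------------------------------------------------------
# Hydrogen bonds
# --------------------------------------------------------------------------

#' Detect hydrogen bonds by geometric criteria
#'
#' A hydrogen bond X--H...A is recorded when the (minimum-image) H...A
#' distance is below `d_max` and the X--H...A angle at the hydrogen
#' exceeds `angle_min`.  Donor heavy atoms X are identified from the bond
#' graph (any H covalently bound to an element in `donors`); acceptors A
#' are atoms of an element in `acceptors` other than the donor itself.
#' Only intermolecular bonds are kept by default.
#'
#' @param s An [atomic_structure()] (typically the periodic crystal).
#' @param g A [build_bond_graph()] result for `s` (computed if `NULL`).
#' @param d_max Maximum H...A distance (angstrom, default 2.5).
#' @param angle_min Minimum X--H...A angle (degrees, default 150).
#' @param acceptors,donors Element sets (default N and O; add `"S"` to
#'   include sulfur).
#' @param intermolecular_only Drop bonds within one molecule (default
#'   `TRUE`).
#' @return Tibble of hydrogen bonds: `donor` (X index), `hydrogen`,
#'   `acceptor`, `donor_element`, `acceptor_element`, `distance`
#'   (H...A, angstrom), `angle` (degrees), `class` (e.g. `"OH...O"`).
#' @export
detect_hbonds <- function(s, g = NULL, d_max = 2.5, angle_min = 150,
                          acceptors = c("N", "O"), donors = c("N", "O"),
                          intermolecular_only = TRUE) {
  if (is.null(g)) g <- build_bond_graph(s)
  el <- species(s)
  pos <- positions(s)
  empty <- tibble::tibble(
    donor = integer(), hydrogen = integer(), acceptor = integer(),
    donor_element = character(), acceptor_element = character(),
    distance = numeric(), angle = numeric(), class = character()
  )
  if (nrow(g) == 0) return(empty)
  # covalent X-H pairs
  xh <- dplyr::bind_rows(
    tibble::tibble(h = g$i, x = g$j, sa = g$sa, sb = g$sb, sc = g$sc),
    tibble::tibble(h = g$j, x = g$i, sa = -g$sa, sb = -g$sb, sc = -g$sc)
  ) |>
    dplyr::filter(el[.data$h] == "H", el[.data$x] %in% donors)
  if (nrow(xh) == 0) return(empty)
  mol_of <- rep(NA_integer_, n_atoms(s))
  comps <- tryCatch(extract_molecules(s, g), error = function(e) NULL)
  if (!is.null(comps)) {
    for (k in seq_along(comps)) mol_of[comps[[k]]$index_map] <- k
  }
  # candidate H...A contacts within d_max
  pt <- pair_table(s, d_max)
  shift_cart <- if (any(s$pbc)) {
    as.matrix(pt[, c("sa", "sb", "sc")]) %*% s$cell
  } else {
    matrix(0, nrow(pt), 3)
  }
  ha <- dplyr::bind_rows(
    tibble::tibble(
      h = pt$i, a = pt$j, d = pt$d,
      avx = pos[pt$j, 1] + shift_cart[, 1] - pos[pt$i, 1],
      avy = pos[pt$j, 2] + shift_cart[, 2] - pos[pt$i, 2],
      avz = pos[pt$j, 3] + shift_cart[, 3] - pos[pt$i, 3]
    ),
    tibble::tibble(
      h = pt$j, a = pt$i, d = pt$d,
      avx = -(pos[pt$j, 1] + shift_cart[, 1] - pos[pt$i, 1]),
      avy = -(pos[pt$j, 2] + shift_cart[, 2] - pos[pt$i, 2]),
      avz = -(pos[pt$j, 3] + shift_cart[, 3] - pos[pt$i, 3])
    )
  ) |>
    dplyr::filter(el[.data$h] == "H", el[.data$a] %in% acceptors, .data$d < d_max)
  if (nrow(ha) == 0) return(empty)
  out <- dplyr::inner_join(xh, ha, by = "h", relationship = "many-to-many")
  if (nrow(out) == 0) return(empty)
  # exclude the covalent partner itself (A == X through the same image)
  out <- dplyr::filter(out, .data$a != .data$x | .data$d > 1.2)
  if (intermolecular_only && !is.null(comps)) {
    out <- dplyr::filter(out, mol_of[.data$h] != mol_of[.data$a])
  }
  if (nrow(out) == 0) return(empty)
  # X-H...A angle at the hydrogen
  hx <- if (any(s$pbc)) {
    cbind(out$sa, out$sb, out$sc) %*% s$cell +
      pos[out$x, , drop = FALSE] - pos[out$h, , drop = FALSE]
  } else {
    pos[out$x, , drop = FALSE] - pos[out$h, , drop = FALSE]
  }
  av <- cbind(out$avx, out$avy, out$avz)
  cosang <- rowSums(hx * av) /
    (sqrt(rowSums(hx^2)) * sqrt(rowSums(av^2)))
  # angle between the H->X and H->A directions: 180 degrees when linear
  out$angle <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  out <- dplyr::filter(out, .data$angle > angle_min)
  if (nrow(out) == 0) return(empty)
  tibble::tibble(
    donor = out$x, hydrogen = out$h, acceptor = out$a,
    donor_element = el[out$x], acceptor_element = el[out$a],
    distance = out$d, angle = out$angle,
    class = paste0(el[out$x], "H...", el[out$a])
  )
}

#' Count hydrogen bonds donated and accepted per molecule
#'
#' Summarizes a [detect_hbonds()] table per molecular component, split by
#' donated (this molecule's X--H) versus accepted (this molecule's
#' acceptor atom) and by the partner element, as used when correlating map
#' axes with hydrogen-bond counts.
#'
#' @param hbonds A [detect_hbonds()] tibble.
#' @param s The structure it was computed for.
#' @param g Optional bond graph.
#' @return Tibble: `molecule`, `donated`, `accepted`, `donated_to_N`,
#'   `donated_to_O`, `accepted_from_N`, `accepted_from_O`.
#' @export
count_hbonds_per_molecule <- function(hbonds, s, g = NULL) {
  comps <- extract_molecules(s, g)
  mol_of <- rep(NA_integer_, n_atoms(s))
  for (k in seq_along(comps)) mol_of[comps[[k]]$index_map] <- k
  purrr::map_dfr(seq_along(comps), function(k) {
    don <- hbonds[mol_of[hbonds$donor] == k, ]
    acc <- hbonds[mol_of[hbonds$acceptor] == k, ]
    tibble::tibble(
      molecule = k,
      donated = nrow(don),
      accepted = nrow(acc),
      donated_to_N = sum(don$acceptor_element == "N"),
      donated_to_O = sum(don$acceptor_element == "O"),
      accepted_from_N = sum(acc$donor_element == "N"),
      accepted_from_O = sum(acc$donor_element == "O")
    )
  })
}
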