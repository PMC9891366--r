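#' Atomic structure container
#'
#' An `atomic_structure` is a light S3 wrapper around a tibble of atoms
#' (columns `element`, `x`, `y`, `z`; coordinates in Cartesian angstrom)
#' carrying the periodic cell, periodic-boundary flags, an identifier and
#' free-form tags as attributes.  It is the common currency for crystals
#' (periodic) and gas-phase molecules (non-periodic) throughout the package.
#'
#' @param atoms A data frame with columns `element` (chemical symbol),
#'   `x`, `y`, `z` (Cartesian coordinates, angstrom).
#' @param cell Optional 3x3 matrix of lattice vectors (rows; angstrom).
#' @param pbc Logical vector of length 3 (or a single logical, recycled):
#'   periodic boundary conditions along each lattice vector.
#' @param id Character identifier.
#' @param tags Named list of free-form metadata (e.g. energies parsed from
#'   an extended-XYZ comment line).
#'
#' @return An object of class `atomic_structure`.
#' @export
atomic_structure <- function(atoms, cell = NULL, pbc = FALSE, id = "structure",
                             tags = list()) {
  atoms <- tibble::as_tibble(atoms)
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  atoms <- dplyr::mutate(atoms, dplyr::across(c("x", "y", "z"), as.numeric))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("atomic_structure: non-finite coordinates", call. = FALSE)
  }
  if (length(pbc) == 1) pbc <- rep(as.logical(pbc), 3)
  stopifnot(length(pbc) == 3)
  if (any(pbc)) {
    if (is.null(cell)) {
      stop("atomic_structure: pbc set but no cell given", call. = FALSE)
    }
    cell <- matrix(as.numeric(cell), 3, 3)
    if (abs(det(cell)) <= 1e-6) {
      stop("atomic_structure: cell is singular (|det| <= 1e-6)", call. = FALSE)
    }
  }
  structure(
    list(id = id, atoms = atoms, cell = cell, pbc = pbc, tags = tags),
    class = "atomic_structure"
  )
}

#' @export
print.atomic_structure <- function(x, ...) {
  per <- if (any(x$pbc)) "periodic" else "molecular"
  cat(sprintf(
    "<atomic_structure '%s': %d atoms (%s), %s>\n",
    x$id, nrow(x$atoms), paste(unique(x$atoms$element), collapse = ","), per
  ))
  invisible(x)
}

#' Number of atoms in a structure
#' @param s An `atomic_structure`.
#' @return Integer atom count.
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Cartesian coordinates as a matrix
#' @param s An `atomic_structure`.
#' @return Numeric n x 3 matrix.
#' @export
positions <- function(s) unname(as.matrix(s$atoms[, c("x", "y", "z")]))

#' Element symbols of a structure
#' @param s An `atomic_structure`.
#' @return Character vector.
#' @export
species <- function(s) s$atoms$element

known_elements <- function() names(covalent_radii())

validate_elements <- function(el) {
  bad <- setdiff(unique(el), known_elements())
  if (length(bad) > 0) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(el)
}

# --------------------------------------------------------------------------
# Extended XYZ
# --------------------------------------------------------------------------

# Parse the key=value comment line of an extended-XYZ frame.  Values may be
# bare tokens or double-quoted strings containing spaces.
parse_extxyz_comment <- function(line) {
  out <- list()
  pat <- '([A-Za-z_][A-Za-z0-9_:]*)=("([^"]*)"|\\S+)'
  m <- gregexpr(pat, line, perl = TRUE)[[1]]
  if (m[1] == -1) return(out)
  for (i in seq_along(m)) {
    tok <- substr(line, m[i], m[i] + attr(m, "match.length")[i] - 1)
    eq <- regexpr("=", tok, fixed = TRUE)
    key <- substr(tok, 1, eq - 1)
    val <- substr(tok, eq + 1, nchar(tok))
    val <- gsub('^"|"$', "", val)
    out[[key]] <- val
  }
  out
}

format_extxyz_value <- function(x) {
  if (is.numeric(x)) x <- paste(format(x, digits = 17), collapse = " ")
  x <- as.character(x)
  if (grepl("\\s", x)) x <- paste0('"', x, '"') else x
  x
}

#' Read structures from an extended-XYZ file
#'
#' Supports multi-frame files.  A `Lattice="ax ay az bx by bz cx cy cz"`
#' entry in the comment line populates the cell (row vectors) and sets
#' `pbc = c(TRUE, TRUE, TRUE)` unless an explicit `pbc="T T F"` entry says
#' otherwise.  All other `key=value` entries land in `tags` (numeric where
#' they parse as numbers).
#'
#' @param path Path to an (extended) XYZ file.
#' @return A list of [atomic_structure()] objects, one per frame.
#' @export
read_extxyz <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  out <- list()
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    if (!grepl("\\S", lines[i])) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1) {
      stop(sprintf("extxyz parse error at line %d: expected atom count", i),
        call. = FALSE
      )
    }
    if (i + 1L + n > length(lines)) {
      stop(sprintf("extxyz parse error: frame at line %d truncated", i),
        call. = FALSE
      )
    }
    frame <- frame + 1L
    tags <- parse_extxyz_comment(lines[i + 1L])
    cell <- NULL
    pbc <- c(FALSE, FALSE, FALSE)
    if (!is.null(tags$Lattice)) {
      v <- as.numeric(strsplit(trimws(tags$Lattice), "\\s+")[[1]])
      if (length(v) != 9 || anyNA(v)) {
        stop(sprintf("extxyz parse error at line %d: bad Lattice", i + 1L),
          call. = FALSE
        )
      }
      cell <- matrix(v, 3, 3, byrow = TRUE)
      pbc <- c(TRUE, TRUE, TRUE)
      tags$Lattice <- NULL
    }
    if (!is.null(tags$pbc)) {
      pbc <- toupper(strsplit(trimws(tags$pbc), "\\s+")[[1]]) %in% c("T", "TRUE")
      tags$pbc <- NULL
    }
    tags$Properties <- NULL
    id <- tags$id %||% sprintf("%s_frame%d", sub("\\.[^.]*$", "", basename(path)), frame)
    tags$id <- NULL
    tags <- lapply(tags, function(v) {
      num <- suppressWarnings(as.numeric(v))
      if (!is.na(num)) num else v
    })
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    el <- vapply(rows, `[[`, "", 1L)
    xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    if (anyNA(xyz)) {
      stop(sprintf("extxyz parse error in frame starting at line %d", i),
        call. = FALSE
      )
    }
    validate_elements(el)
    out[[frame]] <- atomic_structure(
      tibble::tibble(element = el, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
      cell = cell, pbc = pbc, id = id, tags = tags
    )
    i <- i + 2L + n
  }
  out
}

#' Write structures to an extended-XYZ file
#'
#' @param structures A single [atomic_structure()] or a list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_extxyz <- function(structures, path) {
  if (inherits(structures, "atomic_structure")) structures <- list(structures)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in structures) {
    fields <- list(id = s$id)
    if (any(s$pbc)) {
      fields$Lattice <- paste(format(as.vector(t(s$cell)), digits = 17),
        collapse = " "
      )
      fields$pbc <- paste(ifelse(s$pbc, "T", "F"), collapse = " ")
    }
    fields <- c(fields, s$tags)
    fields$Properties <- "species:S:1:pos:R:3"
    comment <- paste(
      vapply(
        names(fields),
        function(k) paste0(k, "=", format_extxyz_value(fields[[k]])),
        ""
      ),
      collapse = " "
    )
    writeLines(as.character(nrow(s$atoms)), con)
    writeLines(comment, con)
    writeLines(
      sprintf(
        "%-3s %.12f %.12f %.12f",
        s$atoms$element, s$atoms$x, s$atoms$y, s$atoms$z
      ),
      con
    )
  }
  invisible(path)
}

# --------------------------------------------------------------------------
# CIF (minimal small-molecule reader)
# --------------------------------------------------------------------------

cell_from_parameters <- function(a, b, c, alpha, beta, gamma) {
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
  v1 <- c(a, 0, 0)
  v2 <- c(b * cg, b * sg, 0)
  cx <- c * cb
  cy <- c * (ca - cb * cg) / sg
  cz <- sqrt(max(c^2 - cx^2 - cy^2, 0))
  rbind(v1, v2, c(cx, cy, cz), deparse.level = 0)
}

cif_number <- function(x) as.numeric(sub("\\(.*\\)", "", x))

# Evaluate one symmetry operator string like "1/2-x, y, -z+1/2" at
# fractional coordinates xyz.
apply_symop <- function(op, xyz) {
  parts <- strsplit(gsub("['\"]", "", op), ",")[[1]]
  if (length(parts) != 3) stop("bad CIF symmetry operator: ", op, call. = FALSE)
  env <- list2env(list(x = xyz[1], y = xyz[2], z = xyz[3]))
  vapply(parts, function(p) eval(parse(text = tolower(p)), env), numeric(1),
    USE.NAMES = FALSE
  )
}

#' Read a crystal structure from a (small-molecule) CIF file
#'
#' Parses cell parameters, the `_atom_site_` loop (fractional coordinates)
#' and, when present, the symmetry-operator loop
#' (`_symmetry_equiv_pos_as_xyz` / `_space_group_symop_operation_xyz`),
#' expanding the asymmetric unit to P1.  Duplicate generated positions
#' (within `tol` fractional units, modulo lattice translations) are merged.
#'
#' @param path Path to a CIF file.
#' @param tol Tolerance for merging symmetry-equivalent duplicates
#'   (fractional coordinates).
#' @return An [atomic_structure()] with `pbc = c(TRUE, TRUE, TRUE)`.
#' @export
read_cif <- function(path, tol = 1e-3) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  getpar <- function(tag) {
    hit <- grep(paste0("^\\s*", tag, "\\s"), lines, value = TRUE)
    if (length(hit) == 0) stop("CIF: missing ", tag, call. = FALSE)
    cif_number(strsplit(trimws(hit[1]), "\\s+")[[1]][2])
  }
  cell <- cell_from_parameters(
    getpar("_cell_length_a"), getpar("_cell_length_b"), getpar("_cell_length_c"),
    getpar("_cell_angle_alpha"), getpar("_cell_angle_beta"),
    getpar("_cell_angle_gamma")
  )

  # walk loop_ blocks
  symops <- character()
  sites <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (grepl("^\\s*loop_\\s*$", lines[i])) {
      j <- i + 1L
      headers <- character()
      while (j <= length(lines) && grepl("^\\s*_", lines[j])) {
        headers <- c(headers, trimws(strsplit(trimws(lines[j]), "\\s+")[[1]][1]))
        j <- j + 1L
      }
      body <- character()
      while (j <= length(lines) && grepl("\\S", lines[j]) &&
        !grepl("^\\s*(_|loop_|data_)", lines[j])) {
        body <- c(body, trimws(lines[j]))
        j <- j + 1L
      }
      if (any(grepl("symop_operation_xyz|equiv_pos_as_xyz", headers))) {
        k <- grep("symop_operation_xyz|equiv_pos_as_xyz", headers)[1]
        symops <- vapply(body, function(b) {
          if (grepl("'", b)) {
            sub(".*?'([^']*)'.*", "\\1", b)
          } else {
            toks <- strsplit(b, "\\s+")[[1]]
            paste(toks[k:length(toks)], collapse = " ")
          }
        }, "", USE.NAMES = FALSE)
      } else if (any(headers == "_atom_site_fract_x")) {
        tab <- do.call(rbind, strsplit(body, "\\s+"))
        colnames(tab) <- headers[seq_len(ncol(tab))]
        el_col <- if ("_atom_site_type_symbol" %in% headers) {
          "_atom_site_type_symbol"
        } else {
          "_atom_site_label"
        }
        sites <- tibble::tibble(
          element = gsub("[0-9'+-].*$", "", tab[, el_col]),
          fx = cif_number(tab[, "_atom_site_fract_x"]),
          fy = cif_number(tab[, "_atom_site_fract_y"]),
          fz = cif_number(tab[, "_atom_site_fract_z"])
        )
      }
      i <- j
    } else {
      i <- i + 1L
    }
  }
  if (is.null(sites)) stop("CIF: no _atom_site loop found", call. = FALSE)
  if (length(symops) == 0) symops <- "x, y, z"
  validate_elements(sites$element)

  frac <- list()
  el <- character()
  for (r in seq_len(nrow(sites))) {
    for (op in symops) {
      f <- apply_symop(op, c(sites$fx[r], sites$fy[r], sites$fz[r])) %% 1
      dup <- FALSE
      for (g in frac) {
        d <- f - g
        d <- d - round(d)
        if (max(abs(d)) < tol) { dup <- TRUE; break }
      }
      if (!dup) {
        frac[[length(frac) + 1L]] <- f
        el <- c(el, sites$element[r])
      }
    }
  }
  fr <- do.call(rbind, frac)
  xyz <- fr %*% cell
  atomic_structure(
    tibble::tibble(element = el, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
    cell = cell, pbc = TRUE, id = sub("\\.[^.]*$", "", basename(path))
  )
}

#' Read structures from a file, dispatching on format
#'
#' @param path File path.
#' @param format `"extxyz"` or `"cif"`; `"auto"` picks by extension.
#' @return A list of [atomic_structure()] objects (CIF yields length 1).
#' @export
read_structures <- function(path, format = c("auto", "extxyz", "cif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "extxyz"
  }
  switch(format,
    extxyz = read_extxyz(path),
    cif = list(read_cif(path))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
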