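#' Configuration for atom-centered power-spectrum descriptors
#'
#' Defines the three-body (SOAP-style) descriptor: each atom's neighbor
#' density (every neighbor smeared by a Gaussian of width `sigma_atom`,
#' the central atom included) is expanded within `r_cut` in an
#' orthonormalized Gaussian radial basis times real spherical harmonics,
#' and contracted into the rotation-invariant power spectrum
#' p_(an,bn',l) per species pair.  The species list is global: every
#' structure in a dataset shares one column space, with absent pairs
#' zero-filled.
#'
#' @param r_cut Environment cutoff (angstrom).
#' @param n_max Number of radial basis functions.
#' @param l_max Maximum spherical-harmonic degree.
#' @param sigma_atom Gaussian smearing of the neighbor density (angstrom).
#' @param species Ordered global element set.
#' @param normalize Normalize each atom's feature vector to unit L2 norm.
#' @param n_quad Gauss-Legendre nodes for the radial integrals.
#' @return A `soap_config` list with a `config_hash` field.
#' @export
soap_config <- function(r_cut = 5.0, n_max = 6L, l_max = 4L, sigma_atom = 0.3,
                        species = c("C", "H", "N", "O", "S"),
                        normalize = TRUE, n_quad = 80L) {
  stopifnot(r_cut > 0, n_max >= 1, l_max >= 0, sigma_atom > 0)
  cfg <- list(
    r_cut = r_cut, n_max = as.integer(n_max), l_max = as.integer(l_max),
    sigma_atom = sigma_atom, species = species, normalize = normalize,
    n_quad = as.integer(n_quad),
    basis = "gaussian-centers/cos-cutoff/lowdin"
  )
  cfg$config_hash <- rlang::hash(cfg)
  class(cfg) <- "soap_config"
  cfg
}

# Gauss-Legendre nodes/weights on [0, b] via the Golub-Welsch Jacobi matrix.
gauss_legendre <- function(n, b) {
  k <- seq_len(n - 1)
  beta <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- beta
  J[cbind(k + 1, k)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  list(x = (x + 1) * b / 2, w = w * b / 2)
}

# Orthonormalized radial basis evaluated on the quadrature grid.
# Primitive functions: Gaussians centered on an even grid in (0, r_cut],
# multiplied by a smooth cosine cutoff; Lowdin (S^{-1/2}) orthonormalized
# under the weight r^2 dr.
radial_basis <- function(cfg) {
  gl <- gauss_legendre(cfg$n_quad, cfg$r_cut)
  r <- gl$x
  w <- gl$w
  centers <- seq_len(cfg$n_max) * cfg$r_cut / cfg$n_max
  width <- cfg$r_cut / cfg$n_max
  fc <- 0.5 * (cos(pi * r / cfg$r_cut) + 1)
  phi <- sapply(centers, function(c0) exp(-(r - c0)^2 / (2 * width^2)) * fc)
  S <- crossprod(phi, phi * (w * r^2))
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (min(e$values) < 1e-12 * max(e$values)) {
    stop("radial basis numerically dependent; reduce n_max", call. = FALSE)
  }
  Shalf <- e$vectors %*% diag(1 / sqrt(e$values), cfg$n_max) %*% t(e$vectors)
  R <- phi %*% Shalf # grid x n_max, orthonormal columns under w*r^2
  list(r = r, w = w, R = R)
}

# Real spherical harmonics Z_lm for unit vectors (rows of u), orthonormal on
# the sphere, returned as a matrix with columns ordered (l, m = -l..l).
real_sph_harm <- function(u, l_max) {
  n <- nrow(u)
  ct <- pmin(pmax(u[, 3], -1), 1)
  st <- sqrt(pmax(1 - ct^2, 0))
  phi <- atan2(u[, 2], u[, 1])
  nlm <- (l_max + 1)^2
  Z <- matrix(0, n, nlm)
  # associated Legendre P_l^m with Condon-Shortley phase, by recurrence
  P <- array(0, dim = c(n, l_max + 1, l_max + 1)) # [, l+1, m+1]
  P[, 1, 1] <- 1
  if (l_max >= 1) {
    for (m in 1:l_max) {
      P[, m + 1, m + 1] <- -(2 * m - 1) * st * P[, m, m]
    }
    for (m in 0:(l_max - 1)) {
      P[, m + 2, m + 1] <- (2 * m + 1) * ct * P[, m + 1, m + 1]
      if (m + 2 <= l_max) {
        for (l in (m + 2):l_max) {
          P[, l + 1, m + 1] <- ((2 * l - 1) * ct * P[, l, m + 1] -
            (l + m - 1) * P[, l - 1, m + 1]) / (l - m)
        }
      }
    }
  }
  col <- function(l, m) l^2 + l + m + 1
  for (l in 0:l_max) {
    Z[, col(l, 0)] <- sqrt((2 * l + 1) / (4 * pi)) * P[, l + 1, 1]
    if (l >= 1) {
      for (m in 1:l) {
        N <- sqrt((2 * l + 1) / (2 * pi) *
          exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
        Z[, col(l, m)] <- N * P[, l + 1, m + 1] * cos(m * phi)
        Z[, col(l, -m)] <- N * P[, l + 1, m + 1] * sin(m * phi)
      }
    }
  }
  Z
}

# Scaled modified spherical Bessel function i_l(x) * exp(-x), vectorized,
# stable for x in [0, large).
sph_bessel_i_scaled <- function(x, l) {
  out <- numeric(length(x))
  tiny <- x < 1e-10
  if (any(!tiny)) {
    xs <- x[!tiny]
    out[!tiny] <- sqrt(pi / (2 * xs)) * besselI(xs, l + 0.5, expon.scaled = TRUE)
  }
  if (any(tiny)) out[tiny] <- if (l == 0) 1 else 0
  out
}

# Neighbor lists (within r_cut) for every atom, periodic images included.
# Each entry: tibble with j (atom index), element, d, and the displacement
# vector (dx, dy, dz) from atom i to the neighbor image.  The central atom
# itself (d = 0) is NOT included here.
neighbor_lists <- function(s, r_cut) {
  pt <- pair_table(s, r_cut)
  n <- n_atoms(s)
  pos <- positions(s)
  el <- species(s)
  res <- lapply(seq_len(n), function(i) NULL)
  if (nrow(pt) > 0) {
    shift_cart <- if (any(s$pbc)) {
      as.matrix(pt[, c("sa", "sb", "sc")]) %*% s$cell
    } else {
      matrix(0, nrow(pt), 3)
    }
    dv <- pos[pt$j, , drop = FALSE] + shift_cart - pos[pt$i, , drop = FALSE]
    fwd <- tibble::tibble(
      i = pt$i, j = pt$j, d = pt$d,
      dx = dv[, 1], dy = dv[, 2], dz = dv[, 3]
    )
    bwd <- tibble::tibble(
      i = pt$j, j = pt$i, d = pt$d,
      dx = -dv[, 1], dy = -dv[, 2], dz = -dv[, 3]
    )
    allp <- dplyr::bind_rows(fwd, bwd)
    allp$element <- el[allp$j]
    sp <- split(allp, allp$i)
    for (k in names(sp)) res[[as.integer(k)]] <- sp[[k]]
  }
  res
}

#' Compute atom-centered power-spectrum descriptors
#'
#' For every atom the Gaussian-smeared neighbor density within
#' `cfg$r_cut` (central atom included; periodic images searched) is
#' expanded in the radial basis times real spherical harmonics, and the
#' rotation-invariant power spectrum is formed per species pair.  Feature
#' columns have identical meaning for any two sets computed with the same
#' configuration (compare `config_hash`).
#'
#' @param s An [atomic_structure()].
#' @param cfg A [soap_config()].
#' @return A `descriptor_set`: list with `structure_id`, `phase` (unset
#'   here; see [phase<-]), `X` (atoms x features matrix), `config_hash`.
#' @export
compute_descriptors <- function(s, cfg = soap_config()) {
  el <- species(s)
  bad <- setdiff(unique(el), cfg$species)
  if (length(bad) > 0) {
    stop(
      "species outside the configured species list: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  rb <- radial_basis(cfg)
  n_max <- cfg$n_max
  l_max <- cfg$l_max
  sig2 <- cfg$sigma_atom^2
  nsp <- length(cfg$species)
  Q <- nsp * n_max
  # quadrature operator: A_l[n, j] = 4*pi * sum_g w_g r_g^2 R_n(r_g) K_l(r_g, r_j)
  Bq <- t(rb$R * (rb$w * rb$r^2)) * (4 * pi) # n_max x grid

  # self-contribution (neighbor at r = 0): only l = 0, m = 0 survives
  A_self <- as.vector(Bq %*% exp(-rb$r^2 / (2 * sig2))) # length n_max
  Z00 <- 1 / sqrt(4 * pi)

  nl <- neighbor_lists(s, cfg$r_cut)
  n_feat <- n_features(cfg)
  X <- matrix(0, n_atoms(s), n_feat)
  pairs <- feature_pairs(cfg) # q <= q' index table
  for (i in seq_len(n_atoms(s))) {
    Cmat <- matrix(0, Q, (l_max + 1)^2)
    qi <- (match(el[i], cfg$species) - 1) * n_max
    Cmat[qi + seq_len(n_max), 1] <- A_self * Z00
    nb <- nl[[i]]
    if (!is.null(nb) && nrow(nb) > 0) {
      rj <- nb$d
      u <- cbind(nb$dx, nb$dy, nb$dz) / rj
      Z <- real_sph_harm(u, l_max)
      Xarg <- outer(rb$r, rj) / sig2
      Gau <- exp(-(outer(rb$r, rj, "-"))^2 / (2 * sig2))
      spidx <- match(nb$element, cfg$species)
      for (l in 0:l_max) {
        Il <- matrix(
          sph_bessel_i_scaled(as.vector(Xarg), l),
          nrow(Xarg), ncol(Xarg)
        )
        A_l <- Bq %*% (Gau * Il) # n_max x J
        cols <- (l^2 + 1):((l + 1)^2)
        for (a in unique(spidx)) {
          Ja <- which(spidx == a)
          rows <- (a - 1) * n_max + seq_len(n_max)
          Cmat[rows, cols] <- Cmat[rows, cols] +
            A_l[, Ja, drop = FALSE] %*% Z[Ja, cols, drop = FALSE]
        }
      }
    }
    feat <- numeric(n_feat)
    off <- 0L
    for (l in 0:l_max) {
      cols <- (l^2 + 1):((l + 1)^2)
      Pl <- tcrossprod(Cmat[, cols, drop = FALSE]) / sqrt(2 * l + 1)
      v <- Pl[pairs$lin]
      v[pairs$off_diag] <- v[pairs$off_diag] * sqrt(2)
      feat[off + seq_along(v)] <- v
      off <- off + length(v)
    }
    if (cfg$normalize) {
      nrm <- sqrt(sum(feat^2))
      if (nrm > 0) feat <- feat / nrm
    }
    X[i, ] <- feat
  }
  structure(
    list(
      structure_id = s$id, phase = NA_character_, X = X,
      config_hash = cfg$config_hash
    ),
    class = "descriptor_set"
  )
}

# q <= q' pairs of the combined (species, n) radial index, as linear indices
# into the Q x Q per-l block.
feature_pairs <- function(cfg) {
  Q <- length(cfg$species) * cfg$n_max
  idx <- which(upper.tri(matrix(0, Q, Q), diag = TRUE), arr.ind = TRUE)
  list(
    lin = (idx[, 2] - 1) * Q + idx[, 1],
    off_diag = idx[, 1] != idx[, 2]
  )
}

#' Number of descriptor features for a configuration
#' @param cfg A [soap_config()].
#' @return Integer feature count.
#' @export
n_features <- function(cfg) {
  Q <- length(cfg$species) * cfg$n_max
  as.integer(Q * (Q + 1) / 2 * (cfg$l_max + 1))
}

#' Set or get the phase tag of a descriptor set
#' @param ds A `descriptor_set`.
#' @param value `"s"` (solid) or `"g"` (gas).
#' @return The modified descriptor set.
#' @export
`phase<-` <- function(ds, value) {
  stopifnot(value %in% c("s", "g"))
  ds$phase <- value
  ds
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat(sprintf(
    "<descriptor_set '%s' (%s): %d atoms x %d features, hash %s>\n",
    x$structure_id, x$phase, nrow(x$X), ncol(x$X),
    substr(x$config_hash, 1, 8)
  ))
  invisible(x)
}

#' Average atomic descriptors over a collection
#'
#' The descriptor of a collection (molecule, crystal, motif) is the
#' arithmetic mean of its constituent atoms' descriptors.
#'
#' @param ds A `descriptor_set`.
#' @param indices Atom indices to average over (default: all atoms).
#' @param scope One of `"atom"`, `"molecule"`, `"crystal"`, `"motif"`.
#' @return A `collection_descriptor`: list with `x` (feature vector),
#'   `n` (atoms averaged), `scope`, `config_hash`.
#' @export
average_descriptor <- function(ds, indices = seq_len(nrow(ds$X)),
                               scope = "crystal") {
  if (length(indices) == 0) stop("empty index list", call. = FALSE)
  if (any(indices < 1 | indices > nrow(ds$X))) {
    stop("atom index out of range", call. = FALSE)
  }
  structure(
    list(
      x = colMeans(ds$X[indices, , drop = FALSE]),
      n = length(indices), scope = scope, config_hash = ds$config_hash
    ),
    class = "collection_descriptor"
  )
}

#' Remnant (solid-minus-gas) descriptor of a crystal
#'
#' Per atom, the difference between the solid-phase descriptor row and the
#' gas-phase row of the same atom (aligned through the record's index
#' maps); the collection value is the mean over atoms, and equals the
#' difference of the phase averages (averaging and differencing commute).
#'
#' @param rec A `crystal_record`.
#' @param ds_s `descriptor_set` of the crystal (solid phase).
#' @param ds_g List of `descriptor_set`s, one per gas molecule, atom order
#'   matching each molecule's `index_map`.
#' @return List with `per_atom` (n_c x p matrix, crystal atom order) and
#'   `collection` (a `collection_descriptor`).
#' @export
remnant_descriptor <- function(rec, ds_s, ds_g) {
  hashes <- vapply(ds_g, function(d) d$config_hash, "")
  if (any(hashes != ds_s$config_hash)) {
    stop("descriptor configuration mismatch between phases", call. = FALSE)
  }
  Xg <- matrix(0, nrow(ds_s$X), ncol(ds_s$X))
  for (k in seq_along(rec$molecules)) {
    im <- rec$molecules[[k]]$index_map
    if (nrow(ds_g[[k]]$X) != length(im)) {
      stop("gas descriptor rows do not match the index map", call. = FALSE)
    }
    Xg[im, ] <- ds_g[[k]]$X
  }
  Xr <- ds_s$X - Xg
  coll <- structure(
    list(
      x = colMeans(Xr), n = nrow(Xr), scope = "crystal",
      config_hash = ds_s$config_hash
    ),
    class = "collection_descriptor"
  )
  list(per_atom = Xr, collection = coll)
}

#' Concatenate two collection descriptors feature-wise
#'
#' Forms the combined representation (e.g. solid block followed by gas
#' block).  Block origins are recorded in the `blocks` attribute.
#'
#' @param a,b `collection_descriptor`s with equal `n` and `scope`.
#' @return A `collection_descriptor` of the concatenated features.
#' @export
concatenate_descriptors <- function(a, b) {
  if (!identical(a$scope, b$scope)) stop("scope mismatch", call. = FALSE)
  if (!identical(a$n, b$n)) stop("collection size mismatch", call. = FALSE)
  out <- structure(
    list(
      x = c(a$x, b$x), n = a$n, scope = a$scope,
      config_hash = rlang::hash(list(a$config_hash, b$config_hash))
    ),
    class = "collection_descriptor"
  )
  attr(out, "blocks") <- c(length(a$x), length(b$x))
  out
}

#' Write a descriptor matrix with its JSON sidecar
#'
#' The matrix goes to `<path>.csv` (atoms as rows) and the configuration,
#' species list and hash to `<path>.json`.
#'
#' @param ds A `descriptor_set`.
#' @param path Output path stem (no extension).
#' @param cfg The [soap_config()] used (stored in the sidecar).
#' @return `path`, invisibly.
#' @export
write_descriptors <- function(ds, path, cfg = NULL) {
  utils::write.table(
    ds$X, paste0(path, ".csv"),
    sep = ",", row.names = FALSE, col.names = FALSE
  )
  side <- list(
    structure_id = ds$structure_id, phase = ds$phase,
    config_hash = ds$config_hash, n_atoms = nrow(ds$X),
    n_features = ncol(ds$X)
  )
  if (!is.null(cfg)) side$config <- unclass(cfg)
  jsonlite::write_json(side, paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a descriptor matrix written by [write_descriptors()]
#' @param path Path stem used at write time.
#' @return A `descriptor_set`.
#' @export
read_descriptors <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  X <- as.matrix(utils::read.table(paste0(path, ".csv"), sep = ","))
  dimnames(X) <- NULL
  structure(
    list(
      structure_id = side$structure_id, phase = side$phase, X = X,
      config_hash = side$config_hash
    ),
    class = "descriptor_set"
  )
}
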