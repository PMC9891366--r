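#' Gaussian-filter configuration for atomic contributions
#'
#' The raw per-atom contributions of a linear model can swing wildly
#' between bonded atoms (the decomposition is gauge-like: only sums are
#' constrained).  The filter redistributes each atom's raw contribution
#' over its neighborhood within `neighbor_cutoff`, with Gaussian weights
#' `f(a, b) = exp(-d_ab^2 / (2 varsigma^2))`, `f(a, a) = 1`, normalized
#' over the recipients so the total is conserved exactly.  Note the
#' negative exponent: the kernel decays with distance (a positive exponent
#' would grow without bound and is physically meaningless).
#'
#' @param varsigma Gaussian width (angstrom); must be positive.
#' @param neighbor_cutoff Neighborhood radius (angstrom, default 2).
#' @return A `filter_config` list.
#' @export
filter_config <- function(varsigma = 0.5, neighbor_cutoff = 2.0) {
  if (varsigma <= 0) stop("varsigma must be positive", call. = FALSE)
  if (neighbor_cutoff <= 0) stop("neighbor_cutoff must be positive", call. = FALSE)
  structure(
    list(varsigma = varsigma, neighbor_cutoff = neighbor_cutoff),
    class = "filter_config"
  )
}

#' Per-atom contributions to the lattice energy
#'
#' For a model fitted on the remnant feature space, each atom's
#' contribution is `delta_a = x_a^(s-g) w` (plus the model intercept,
#' shared equally by all atoms, so the atom mean equals the structure
#' prediction exactly).
#'
#' @param remnant Result of [remnant_descriptor()] (or a bare per-atom
#'   remnant matrix in crystal atom order).
#' @param model A `lattice_model` with `feature_space = "remnant"`.
#' @param s The crystal [atomic_structure()] (for element labels and the
#'   structure id).
#' @return An `attribution` object: tibble `atoms` with columns `atom`,
#'   `element`, `delta` (and later `delta_filtered`), plus `structure_id`
#'   and the structure-level prediction.
#' @export
atomic_contributions <- function(remnant, model, s) {
  if (!identical(model$feature_space, "remnant")) {
    stop("atomic contributions require a remnant-space model", call. = FALSE)
  }
  Xr <- if (is.list(remnant) && !is.null(remnant$per_atom)) {
    remnant$per_atom
  } else {
    as.matrix(remnant)
  }
  if (nrow(Xr) != n_atoms(s)) {
    stop("remnant rows do not align with the crystal's atoms", call. = FALSE)
  }
  if (ncol(Xr) != length(model$w)) {
    stop("feature dimension does not match the model", call. = FALSE)
  }
  delta <- as.vector(Xr %*% model$w) + model$b
  structure(
    list(
      atoms = tibble::tibble(
        atom = seq_len(nrow(Xr)),
        element = species(s),
        delta = delta
      ),
      structure_id = s$id,
      prediction = mean(delta),
      filter = NULL
    ),
    class = "attribution"
  )
}

#' @export
print.attribution <- function(x, ...) {
  filt <- if (is.null(x$filter)) "unfiltered" else {
    sprintf("filtered (varsigma = %g)", x$filter$varsigma)
  }
  cat(sprintf(
    "<attribution '%s': %d atoms, prediction %.4f kJ/mol-atom, %s>\n",
    x$structure_id, nrow(x$atoms), x$prediction, filt
  ))
  invisible(x)
}

# Column-stochastic smoothing matrix over the <= cutoff neighborhood:
# W[i, j] = f(i, j) / sum_k f(k, j), nonzero only within the cutoff,
# f(a, a) = 1.  Column normalization makes the filter conserve the sum.
smoothing_matrix <- function(s, cfg) {
  n <- n_atoms(s)
  f <- diag(n)
  pt <- pair_table(s, cfg$neighbor_cutoff)
  if (nrow(pt) > 0) {
    # a pair may be within the cutoff through several images; keep the
    # closest
    pt <- pt |>
      dplyr::group_by(.data$i, .data$j) |>
      dplyr::summarise(d = min(.data$d), .groups = "drop")
    g <- exp(-pt$d^2 / (2 * cfg$varsigma^2))
    f[cbind(pt$i, pt$j)] <- g
    f[cbind(pt$j, pt$i)] <- g
  }
  sweep(f, 2, colSums(f), "/")
}

#' Smooth per-atom contributions with the Gaussian filter
#'
#' Applies the conservation-preserving Gaussian filter: each atom's raw
#' contribution is redistributed over its neighborhood (minimum-image
#' distances, cutoff `cfg$neighbor_cutoff`), so the sum of contributions
#' -- and hence the regression result -- is unchanged exactly, while
#' gauge-like cancellations between bonded atoms are suppressed.
#'
#' @param att An `attribution` from [atomic_contributions()].
#' @param s The crystal [atomic_structure()] the attribution belongs to.
#' @param cfg A [filter_config()].
#' @return The attribution with a `delta_filtered` column added.
#' @export
gaussian_filter <- function(att, s, cfg = filter_config()) {
  stopifnot(inherits(att, "attribution"))
  if (nrow(att$atoms) != n_atoms(s)) {
    stop("attribution does not match the structure", call. = FALSE)
  }
  W <- smoothing_matrix(s, cfg)
  att$atoms$delta_filtered <- as.vector(W %*% att$atoms$delta)
  att$filter <- cfg
  att
}

#' Motif contribution: mean smoothed contribution of member atoms
#'
#' The effective cohesive interaction of a motif instance is the
#' arithmetic mean of the filtered per-atom contributions over the atoms
#' the motif matches (kJ per mol of atoms).  Because motifs may overlap
#' and are averages, the crystal's lattice energy is NOT the sum of its
#' motif contributions.  For water, multiplying the per-atom value by 3
#' gives the conventional per-water-molecule contribution.
#'
#' @param att A filtered `attribution` (run [gaussian_filter()] first; the
#'   raw `delta` is used with a warning otherwise).
#' @param indices Crystal-frame atom indices of the motif instance.
#' @return The motif contribution (scalar, kJ per mol of atoms).
#' @export
motif_contribution <- function(att, indices) {
  if (length(indices) == 0) stop("empty motif", call. = FALSE)
  if (any(indices < 1 | indices > nrow(att$atoms))) {
    stop("motif atom index out of range", call. = FALSE)
  }
  vals <- if ("delta_filtered" %in% names(att$atoms)) {
    att$atoms$delta_filtered
  } else {
    warning("attribution is unfiltered; using raw contributions")
    att$atoms$delta
  }
  mean(vals[indices])
}

#' Tidy an attribution
#' @param x An `attribution`.
#' @param ... Unused.
#' @return The per-atom tibble with the structure id attached.
#' @method tidy attribution
#' @export
tidy.attribution <- function(x, ...) {
  dplyr::mutate(x$atoms, structure_id = x$structure_id, .before = 1)
}

#' One-row attribution summary
#' @param x An `attribution`.
#' @param ... Unused.
#' @return Tibble: `structure_id`, `n_atoms`, `prediction`, `sum_delta`,
#'   `sum_delta_filtered`, `sd_delta`, `sd_delta_filtered`.
#' @method glance attribution
#' @export
glance.attribution <- function(x, ...) {
  filtered <- "delta_filtered" %in% names(x$atoms)
  tibble::tibble(
    structure_id = x$structure_id,
    n_atoms = nrow(x$atoms),
    prediction = x$prediction,
    sum_delta = sum(x$atoms$delta),
    sum_delta_filtered = if (filtered) sum(x$atoms$delta_filtered) else NA_real_,
    sd_delta = stats::sd(x$atoms$delta),
    sd_delta_filtered = if (filtered) stats::sd(x$atoms$delta_filtered) else NA_real_
  )
}

#' Write per-atom contributions to CSV
#'
#' Columns: `structure_id`, `atom` (1-based index), `element`, `delta`,
#' `delta_filtered`; suitable for recoloring structures by contribution.
#'
#' @param att An `attribution` or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_attribution <- function(att, path) {
  atts <- if (inherits(att, "attribution")) list(att) else att
  tab <- purrr::map_dfr(atts, tidy)
  readr::write_csv(tab, path)
  invisible(path)
}

#' Plot per-atom contributions of one structure
#' @param object An `attribution`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot attribution
#' @export
autoplot.attribution <- function(object, ...) {
  tab <- tidy(object) |>
    tidyr::pivot_longer(
      dplyr::any_of(c("delta", "delta_filtered")),
      names_to = "kind", values_to = "value"
    )
  ggplot2::ggplot(
    tab,
    ggplot2::aes(
      x = factor(.data$atom), y = .data$value,
      fill = .data$element, alpha = .data$kind
    )
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_alpha_manual(values = c(delta = 0.45, delta_filtered = 1)) +
    ggplot2::labs(
      x = "atom", y = "contribution (kJ / mol of atoms)",
      title = object$structure_id
    ) +
    ggplot2::theme_minimal()
}
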