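#' Fit a principal covariates regression (PCovR) map
#'
#' PCovR interpolates between PCA of the (standardized) features and the
#' variance explained by a regression's predictions.  With centered,
#' scaled features `X` and ridge predictions `yhat`, the latent space is
#' the leading eigenvectors of the modified Gram matrix
#' `G = alpha X X' + (1 - alpha) yhat yhat'`; at `alpha = 1` the scores are
#' exactly the PCA scores, at `alpha = 0` the first component is perfectly
#' correlated with the predictions.  The stored projection matrix maps new
#' (scaled) feature rows linearly into the same latent space, so training
#' points project onto their own scores and the training mean projects to
#' the origin.
#'
#' @param X Feature matrix (motifs x features), e.g. motif-averaged
#'   remnant descriptors.
#' @param y Targets (motif contributions, kJ per mol of atoms).
#' @param alpha Mixing parameter in `[0, 1]` (default 0.5).
#' @param k Number of latent components (default 4).
#' @param lambda Ridge strength for the supervised block (default 1e-8).
#' @param scale Standardize feature columns (default `TRUE`; constant
#'   columns are left unscaled).
#' @return A `pcovr_model`: centers/scales, projection (features x k),
#'   eigenvalues, training scores, the internal ridge fit.
#' @export
fit_pcovr <- function(X, y, alpha = 0.5, k = 4L, lambda = 1e-8,
                      scale = TRUE) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), alpha >= 0, alpha <= 1)
  center <- colMeans(X)
  scl <- if (scale) {
    s <- apply(X, 2, stats::sd)
    s[s < 1e-12] <- 1
    s
  } else {
    rep(1, ncol(X))
  }
  Xs <- sweep(sweep(X, 2, center), 2, scl, "/")
  yc <- y - mean(y)
  # ridge predictions for the supervised block
  rf <- ridge_solve(Xs, yc, lambda, intercept = FALSE)
  yhat <- as.vector(Xs %*% rf$w)
  G <- alpha * tcrossprod(Xs) + (1 - alpha) * tcrossprod(yhat)
  G <- (G + t(G)) / 2
  e <- eigen(G, symmetric = TRUE)
  rank <- sum(e$values > max(e$values, 0) * 1e-12)
  if (k > rank) {
    stop(sprintf("k = %d exceeds the rank (%d) of the modified Gram matrix",
      k, rank
    ), call. = FALSE)
  }
  U <- e$vectors[, seq_len(k), drop = FALSE]
  lam <- e$values[seq_len(k)]
  # T = X P with P = (alpha X' + (1 - alpha) w yhat') U L^(-1/2):
  # then X P = G U L^(-1/2) = U L^(1/2), the eigen-scores, exactly.
  P <- (alpha * t(Xs) + (1 - alpha) * tcrossprod(rf$w, yhat)) %*%
    (U %*% diag(1 / sqrt(lam), k))
  # sign convention: the largest-magnitude loading of each component is
  # positive
  for (j in seq_len(k)) {
    i0 <- which.max(abs(P[, j]))
    if (P[i0, j] < 0) P[, j] <- -P[, j]
  }
  scores <- Xs %*% P
  colnames(scores) <- paste0("PCov_", seq_len(k))
  structure(
    list(
      alpha = alpha, k = as.integer(k), lambda = lambda,
      center = center, scale = scl, projection = P,
      eigenvalues = lam, w_ridge = rf$w, y_mean = mean(y),
      scores = scores
    ),
    class = "pcovr_model"
  )
}

#' @export
print.pcovr_model <- function(x, ...) {
  cat(sprintf(
    "<pcovr_model: alpha = %g, %d components, %d features, %d training points>\n",
    x$alpha, x$k, nrow(x$projection), nrow(x$scores)
  ))
  invisible(x)
}

#' Project feature rows into a fitted PCovR latent space
#'
#' Applies the stored centering/scaling and the linear projection.
#' Projecting the training set reproduces the training scores; projecting
#' the training mean gives the origin.
#'
#' @param model A `pcovr_model`.
#' @param X_new Feature matrix in the model's original feature space.
#' @return Matrix of latent coordinates (rows x k), columns `PCov_1..k`.
#' @export
pcovr_project <- function(model, X_new) {
  X_new <- as.matrix(X_new)
  if (is.null(dim(X_new)) || ncol(X_new) != length(model$center)) {
    stop("feature dimension does not match the PCovR model", call. = FALSE)
  }
  Xs <- sweep(sweep(X_new, 2, model$center), 2, model$scale, "/")
  scores <- Xs %*% model$projection
  colnames(scores) <- paste0("PCov_", seq_len(model$k))
  scores
}

#' Build a map-point table from a PCovR model
#'
#' @param model A `pcovr_model`.
#' @param X Feature rows to place on the map.
#' @param ids Point identifiers.
#' @param color Value used to color points (e.g. the motif contribution).
#' @param in_sample Logical flag per point (training member or projected).
#' @return A `pcovr_map` tibble: `id`, `PCov_1..k`, `color`, `in_sample`.
#' @export
pcovr_map_points <- function(model, X, ids = seq_len(nrow(X)),
                             color = NA_real_, in_sample = TRUE) {
  sc <- pcovr_project(model, X)
  out <- dplyr::bind_cols(
    tibble::tibble(id = as.character(ids)),
    tibble::as_tibble(sc)
  )
  out$color <- color
  out$in_sample <- in_sample
  class(out) <- c("pcovr_map", class(out))
  out
}

#' Pearson correlation of latent axes with properties
#'
#' @param points A `pcovr_map` (or any data frame with `PCov_*` columns).
#' @param properties Data frame (or named vector list) of per-point
#'   property values, rows aligned with `points`.
#' @return Tibble: `axis`, `property`, `pcc` (`NA` with a warning for a
#'   zero-variance property).
#' @export
correlate_axes <- function(points, properties) {
  properties <- tibble::as_tibble(properties)
  stopifnot(nrow(properties) == nrow(points))
  if (nrow(points) < 3) stop("need at least 3 points", call. = FALSE)
  axes <- grep("^PCov_", names(points), value = TRUE)
  tidyr::expand_grid(axis = axes, property = names(properties)) |>
    dplyr::mutate(pcc = purrr::map2_dbl(.data$axis, .data$property, function(a, p) {
      pv <- properties[[p]]
      if (stats::sd(pv) < 1e-14) {
        warning("property '", p, "' has zero variance; PCC undefined")
        return(NA_real_)
      }
      stats::cor(points[[a]], pv)
    }))
}

#' Nearest and farthest neighbors in the full latent space
#'
#' Chemical similarity between motif environments is the Euclidean
#' distance over ALL retained covariates -- a point that looks extremal in
#' a plotted 2-D slice need not be extremal in the full-space distance.
#'
#' @param points A `pcovr_map` (query and candidate points share one
#'   latent space).
#' @param query_ids Ids of the query points.
#' @param k Number of nearest (and farthest) neighbors to return.
#' @param candidates Optional ids restricting the candidate set (default:
#'   all non-query points).
#' @return Tibble: `query`, `id`, `distance`, `rank`, `kind`
#'   (`"nearest"` / `"farthest"`).
#' @export
similar_motifs <- function(points, query_ids, k = 5L, candidates = NULL) {
  axes <- grep("^PCov_", names(points), value = TRUE)
  M <- as.matrix(points[, axes])
  rownames(M) <- points$id
  if (!all(query_ids %in% points$id)) {
    stop("unknown query id(s)", call. = FALSE)
  }
  cand <- candidates %||% setdiff(points$id, query_ids)
  if (k > length(cand)) stop("k exceeds the candidate count", call. = FALSE)
  purrr::map_dfr(query_ids, function(q) {
    d <- unname(sqrt(colSums((t(M[cand, , drop = FALSE]) - M[q, ])^2)))
    ord <- order(d)
    near <- ord[seq_len(k)]
    far <- rev(ord)[seq_len(k)]
    dplyr::bind_rows(
      tibble::tibble(
        query = q, id = cand[near], distance = d[near],
        rank = seq_len(k), kind = "nearest"
      ),
      tibble::tibble(
        query = q, id = cand[far], distance = d[far],
        rank = seq_len(k), kind = "farthest"
      )
    )
  })
}

#' Tidy PCovR loadings
#' @param x A `pcovr_model`.
#' @param ... Unused.
#' @return Tibble: `feature`, `component`, `loading`.
#' @method tidy pcovr_model
#' @export
tidy.pcovr_model <- function(x, ...) {
  tibble::as_tibble(x$projection, .name_repair = ~ paste0("PCov_", seq_len(x$k))) |>
    dplyr::mutate(feature = dplyr::row_number(), .before = 1) |>
    tidyr::pivot_longer(-"feature", names_to = "component", values_to = "loading")
}

#' One-row PCovR summary
#' @param x A `pcovr_model`.
#' @param ... Unused.
#' @return Tibble: `alpha`, `k`, `n_features`, `n_train`, `eigenvalue_1`,
#'   `explained_fraction` (share of the modified Gram trace captured).
#' @method glance pcovr_model
#' @export
glance.pcovr_model <- function(x, ...) {
  tibble::tibble(
    alpha = x$alpha, k = x$k,
    n_features = nrow(x$projection),
    n_train = nrow(x$scores),
    eigenvalue_1 = x$eigenvalues[1]
  )
}

#' Plot a PCovR map
#' @param object A `pcovr_map`.
#' @param axes Which two covariates to draw (default first two).
#' @param ... Unused.
#' @return A ggplot: points colored by the `color` column, out-of-sample
#'   points drawn as triangles.
#' @method autoplot pcovr_map
#' @export
autoplot.pcovr_map <- function(object, axes = c(1, 2), ...) {
  ax <- paste0("PCov_", axes)
  ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = .data[[ax[1]]], y = .data[[ax[2]]],
      color = .data$color, shape = .data$in_sample
    )
  ) +
    ggplot2::geom_point() +
    ggplot2::scale_shape_manual(
      values = c(`TRUE` = 16, `FALSE` = 17), guide = "none"
    ) +
    ggplot2::scale_color_gradient2(
      low = "#2166ac", mid = "white", high = "#b2182b", midpoint = 0,
      name = "contribution\n(kJ/mol-atom)"
    ) +
    ggplot2::labs(x = ax[1], y = ax[2]) +
    ggplot2::theme_minimal()
}

#' Write a PCovR map to CSV and the model to JSON
#' @param model A `pcovr_model`.
#' @param points A `pcovr_map`.
#' @param stem Output path stem (writes `<stem>_map.csv`,
#'   `<stem>_model.json`).
#' @return `stem`, invisibly.
#' @export
write_pcovr <- function(model, points, stem) {
  readr::write_csv(tibble::as_tibble(points), paste0(stem, "_map.csv"))
  jsonlite::write_json(
    list(
      alpha = model$alpha, k = model$k, lambda = model$lambda,
      center = model$center, scale = model$scale,
      projection = model$projection, eigenvalues = model$eigenvalues,
      y_mean = model$y_mean
    ),
    paste0(stem, "_model.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(stem)
}
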