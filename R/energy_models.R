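#' Composition matrix of crystal records
#'
#' One row per structure, one column per element; entries are count
#' fractions (they sum to 1 per row), so the baseline prediction of a
#' structure depends only on its composition.
#'
#' @param structures List of [atomic_structure()] objects.
#' @param elements Element set defining the columns (default: union seen).
#' @return Numeric matrix (structures x elements).
#' @export
composition_matrix <- function(structures, elements = NULL) {
  if (is.null(elements)) {
    elements <- sort(unique(unlist(lapply(structures, species))))
  }
  M <- matrix(0, length(structures), length(elements),
    dimnames = list(NULL, elements)
  )
  for (i in seq_along(structures)) {
    cnt <- table(factor(species(structures[[i]]), levels = elements))
    M[i, ] <- as.numeric(cnt) / n_atoms(structures[[i]])
  }
  M
}

#' Fit a per-element composition baseline for total energies
#'
#' Least-squares regression of per-atom total energies on the atomic
#' composition (count fractions).  Subtracting this baseline removes the
#' composition-dominated part of the total-energy variance before the
#' descriptor models are fitted; because a crystal and its constituent
#' molecules share one composition, any such baseline cancels exactly in
#' the lattice energy.
#'
#' @param structures List of [atomic_structure()]s (crystals and/or gas
#'   molecules).
#' @param e Per-atom energies `E/n` (kJ per mol of atoms), aligned.
#' @param elements Element set (default: union seen in `structures`).
#' @param allow_rank_deficient Use the minimum-norm least-squares solution
#'   when the compositions do not span the element space (the fitted
#'   baseline values are still unique on that span; only the per-element
#'   split is gauge-like).  Default `FALSE`: rank deficiency is an error.
#' @return A `baseline_model` with per-element coefficients (kJ per mol of
#'   atoms per count fraction).
#' @export
fit_baseline <- function(structures, e, elements = NULL,
                         allow_rank_deficient = FALSE) {
  M <- composition_matrix(structures, elements)
  if (nrow(M) < ncol(M) && !allow_rank_deficient) {
    stop("need at least as many structures as elements", call. = FALSE)
  }
  qrM <- qr(M)
  if (qrM$rank < ncol(M) && !allow_rank_deficient) {
    stop(
      "rank-deficient composition matrix; pool structures with more ",
      "varied compositions",
      call. = FALSE
    )
  }
  coefs <- if (qrM$rank < ncol(M)) {
    sv <- svd(M)
    keep <- sv$d > max(sv$d) * 1e-10
    w <- sv$v[, keep, drop = FALSE] %*%
      ((1 / sv$d[keep]) * crossprod(sv$u[, keep, drop = FALSE], e))
    stats::setNames(as.vector(w), colnames(M))
  } else {
    qr.coef(qrM, e)
  }
  structure(
    list(coefficients = coefs, elements = colnames(M)),
    class = "baseline_model"
  )
}

#' Baseline prediction for structures
#' @param object A `baseline_model`.
#' @param structures A single [atomic_structure()] or list of them.
#' @param ... Unused.
#' @return Numeric vector of baseline per-atom energies (kJ per mol of
#'   atoms).
#' @export
predict.baseline_model <- function(object, structures, ...) {
  if (inherits(structures, "atomic_structure")) structures <- list(structures)
  M <- composition_matrix(structures, object$elements)
  as.vector(M %*% object$coefficients)
}

# --------------------------------------------------------------------------
# Ridge regression (SVD path, exact lambda -> 0 limit)
# --------------------------------------------------------------------------

ridge_solve <- function(X, y, lambda, intercept = TRUE) {
  if (intercept) {
    mx <- colMeans(X)
    my <- mean(y)
  } else {
    mx <- rep(0, ncol(X))
    my <- 0
  }
  Xc <- sweep(X, 2, mx)
  yc <- y - my
  sv <- svd(Xc)
  d <- sv$d
  keep <- d > max(d, 0) * 1e-12
  shrink <- numeric(length(d))
  if (lambda == 0) {
    shrink[keep] <- 1 / d[keep]
  } else {
    shrink <- d / (d^2 + lambda)
  }
  w <- sv$v %*% (shrink * crossprod(sv$u, yc))
  list(w = as.vector(w), b = my - sum(mx * w), lambda = lambda)
}

default_lambda_grid <- function() c(0, 10^seq(-12, 2, by = 0.5))

#' Fit a cross-validated ridge model of an energy target
#'
#' Linear ansatz `y = x w (+ b)` fitted by ridge regression with the
#' regularization strength chosen to minimize k-fold cross-validated RMSE.
#' The intercept is handled by centering features and targets on the
#' training data; `lambda = 0` (exact least squares through the
#' pseudo-inverse) is part of the default grid, so noise-free linear
#' targets are interpolated exactly.
#'
#' @param X Feature matrix (collections x features).
#' @param y Targets (kJ per mol of atoms), aligned with rows of `X`.
#' @param feature_space One of `"s"`, `"g"`, `"concat"`, `"remnant"`
#'   (bookkeeping tag checked at prediction time).
#' @param lambda_grid Ridge strengths to scan.
#' @param folds Cross-validation fold count (default 5); folds are
#'   assigned round-robin over the row order, so the fit is deterministic.
#' @param intercept Fit an intercept (via centering)?
#' @return A `lattice_model`: weights `w`, intercept `b`, chosen `lambda`,
#'   the CV table, `feature_space`, and training residuals.
#' @export
fit_energy_model <- function(X, y, feature_space = "remnant",
                             lambda_grid = default_lambda_grid(),
                             folds = 5, intercept = TRUE) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("non-finite features or targets", call. = FALSE)
  }
  stopifnot(nrow(X) == length(y))
  n <- nrow(X)
  folds <- min(folds, n)
  fold_id <- rep_len(seq_len(folds), n)
  cv <- purrr::map_dfr(lambda_grid, function(lam) {
    sse <- 0
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      fit <- ridge_solve(X[tr, , drop = FALSE], y[tr], lam, intercept)
      pred <- X[!tr, , drop = FALSE] %*% fit$w + fit$b
      sse <- sse + sum((pred - y[!tr])^2)
    }
    tibble::tibble(lambda = lam, rmse_cv = sqrt(sse / n))
  })
  best <- cv$lambda[which.min(cv$rmse_cv)]
  fit <- ridge_solve(X, y, best, intercept)
  resid <- y - as.vector(X %*% fit$w + fit$b)
  structure(
    list(
      w = fit$w, b = fit$b, lambda = best, cv = cv, folds = folds,
      feature_space = feature_space, residuals = resid,
      intercept = intercept
    ),
    class = "lattice_model"
  )
}

#' @export
print.lattice_model <- function(x, ...) {
  cat(sprintf(
    "<lattice_model [%s]: %d features, lambda = %g, CV RMSE = %.4g kJ/mol>\n",
    x$feature_space, length(x$w), x$lambda, min(x$cv$rmse_cv)
  ))
  invisible(x)
}

#' Predict with a fitted lattice model
#' @param object A `lattice_model`.
#' @param X Feature matrix, feature vector, or `collection_descriptor`.
#' @param ... Unused.
#' @return Numeric predictions (kJ per mol of atoms).
#' @export
predict.lattice_model <- function(object, X, ...) {
  if (inherits(X, "collection_descriptor")) X <- X$x
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != length(object$w)) {
    stop("feature dimension does not match the model", call. = FALSE)
  }
  as.vector(X %*% object$w + object$b)
}

#' Lattice energy from two independent phase models
#'
#' Combines a crystal-energy model (fit on solid-phase descriptors) and a
#' molecular-energy model (fit on gas-phase descriptors) into a lattice
#' energy estimate: the predicted per-atom crystal energy minus the
#' predicted per-atom energy of the gas molecules, the latter evaluated on
#' the atom-count-weighted molecular average descriptor.  Composition
#' baselines cancel exactly because both phases share one composition;
#' this is checked when a `crystal_record` is supplied.
#'
#' @param x_s Solid-phase `collection_descriptor` of the crystal.
#' @param x_g Gas-phase `collection_descriptor` (atom average over all gas
#'   molecules, i.e. the molecule averages weighted by atom count).
#' @param model_c Model of the (baselined) crystal per-atom energy.
#' @param model_m Model of the (baselined) molecular per-atom energy.
#' @param rec Optional `crystal_record` for the composition guard.
#' @return Estimated per-atom lattice energy `delta_c` (kJ per mol of
#'   atoms).
#' @export
predict_lattice_energy_combined <- function(x_s, x_g, model_c, model_m,
                                            rec = NULL) {
  if (!is.null(rec)) {
    crystal_comp <- sort(species(rec$crystal))
    gas_comp <- sort(unlist(lapply(
      rec$molecules,
      function(m) species(m$gas_structure)
    )))
    if (!identical(crystal_comp, gas_comp)) {
      stop("composition mismatch: baseline cancellation would be invalid",
        call. = FALSE
      )
    }
  }
  predict(model_c, x_s) - predict(model_m, x_g)
}

#' Lattice energy from a direct model
#'
#' Evaluates `delta_c = x w (+ b)` for a model fitted directly on the
#' lattice energy in any of the four direct feature spaces (solid, gas,
#' concatenated, remnant).  The descriptor's feature-space tag must match
#' the model's.
#'
#' @param x A `collection_descriptor` or feature vector/matrix.
#' @param model A `lattice_model`.
#' @param feature_space Tag of `x` when `x` is a bare vector/matrix
#'   (defaults to the model's, i.e. unchecked).
#' @return Estimated per-atom lattice energy (kJ per mol of atoms).
#' @export
predict_lattice_energy_direct <- function(x, model,
                                          feature_space = model$feature_space) {
  if (!identical(feature_space, model$feature_space)) {
    stop(sprintf(
      "feature-space mismatch: descriptor is '%s' but model is '%s'",
      feature_space, model$feature_space
    ), call. = FALSE)
  }
  predict(model, x)
}

#' Error metrics of predictions against reference values
#'
#' @param pred,truth Aligned numeric vectors (kJ per mol of atoms).
#' @return A one-row tibble: `rmse`, `mae`, `sd_truth`, `n`.
#' @export
evaluate_model <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("prediction/reference length mismatch", call. = FALSE)
  }
  r <- pred - truth
  tibble::tibble(
    rmse = sqrt(mean(r^2)),
    mae = mean(abs(r)),
    sd_truth = stats::sd(truth),
    n = length(truth)
  )
}

#' Farthest point sampling
#'
#' Greedy max-min selection: starting from `start`, repeatedly add the
#' point whose minimum Euclidean distance to the already-selected set is
#' largest.  Deterministic given `start`; ties broken by lowest index.
#'
#' @param X Feature matrix (points x features).
#' @param k Number of points to select (`k <= nrow(X)`).
#' @param start Index of the first selected point.
#' @return Integer vector of selected row indices, in selection order.
#' @export
fps_select <- function(X, k, start = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k > n) stop("k exceeds the number of points", call. = FALSE)
  if (k < 1) return(integer(0))
  sel <- integer(k)
  sel[1] <- as.integer(start)
  mind <- sqrt(rowSums(sweep(X, 2, X[start, ])^2))
  if (k > 1) {
    for (t in 2:k) {
      nxt <- which.max(mind)
      sel[t] <- as.integer(nxt)
      d <- sqrt(rowSums(sweep(X, 2, X[nxt, ])^2))
      mind <- pmin(mind, d)
    }
  }
  sel
}

# ---- broom-style methods --------------------------------------------------

#' Tidy a lattice model
#' @param x A `lattice_model`.
#' @param ... Unused.
#' @return Tibble with one row per feature: `term`, `estimate`.
#' @method tidy lattice_model
#' @export
tidy.lattice_model <- function(x, ...) {
  tibble::tibble(
    term = c(
      if (x$intercept) "(Intercept)" else NULL,
      paste0("feature_", seq_along(x$w))
    ),
    estimate = c(if (x$intercept) x$b else NULL, x$w)
  )
}

#' One-row model summary
#' @param x A `lattice_model`.
#' @param ... Unused.
#' @return Tibble: `feature_space`, `n_features`, `lambda`, `rmse_cv`,
#'   `folds`, `rmse_train`.
#' @method glance lattice_model
#' @export
glance.lattice_model <- function(x, ...) {
  tibble::tibble(
    feature_space = x$feature_space,
    n_features = length(x$w),
    lambda = x$lambda,
    rmse_cv = min(x$cv$rmse_cv),
    folds = x$folds,
    rmse_train = sqrt(mean(x$residuals^2))
  )
}

#' Save a lattice model (with optional baseline) as JSON
#' @param model A `lattice_model`.
#' @param path Output JSON path.
#' @param baseline Optional `baseline_model`.
#' @param config_hash Optional descriptor configuration hash.
#' @return `path`, invisibly.
#' @export
write_lattice_model <- function(model, path, baseline = NULL,
                                config_hash = NULL) {
  obj <- list(
    w = model$w, b = model$b, lambda = model$lambda,
    feature_space = model$feature_space, intercept = model$intercept,
    config_hash = config_hash
  )
  if (!is.null(baseline)) {
    obj$baseline <- list(
      coefficients = as.list(baseline$coefficients),
      elements = baseline$elements
    )
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a lattice model written by [write_lattice_model()]
#' @param path JSON path.
#' @return List with `model` (a `lattice_model`) and `baseline` (a
#'   `baseline_model` or `NULL`).
#' @export
read_lattice_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- structure(
    list(
      w = obj$w, b = obj$b, lambda = obj$lambda,
      cv = tibble::tibble(lambda = obj$lambda, rmse_cv = NA_real_),
      folds = NA_integer_, feature_space = obj$feature_space,
      residuals = numeric(0), intercept = obj$intercept
    ),
    class = "lattice_model"
  )
  baseline <- NULL
  if (!is.null(obj$baseline)) {
    baseline <- structure(
      list(
        coefficients = stats::setNames(
          unlist(obj$baseline$coefficients),
          obj$baseline$elements
        ),
        elements = obj$baseline$elements
      ),
      class = "baseline_model"
    )
  }
  list(model = model, baseline = baseline, config_hash = obj$config_hash)
}
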