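make_toy_xy <- function(n = 30, p = 5, seed = 8) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- X %*% rnorm(p) + rnorm(n, 0, 0.3)
  list(X = X, y = as.vector(y))
}

test_that("alpha = 1 reproduces PCA scores up to sign", {
  d <- make_toy_xy()
  m <- fit_pcovr(d$X, d$y, alpha = 1, k = 3)
  pca <- stats::prcomp(d$X, center = TRUE, scale. = TRUE)
  for (j in 1:3) {
    a <- m$scores[, j]
    b <- pca$x[, j]
    expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-8)
  }
})

test_that("alpha = 0 with one component is perfectly correlated with the ridge prediction", {
  d <- make_toy_xy()
  m <- fit_pcovr(d$X, d$y, alpha = 0, k = 1)
  Xs <- sweep(sweep(d$X, 2, m$center), 2, m$scale, "/")
  yhat <- as.vector(Xs %*% m$w_ridge)
  expect_equal(abs(stats::cor(m$scores[, 1], yhat)), 1, tolerance = 1e-10)
})

test_that("a 3-point toy set matches a hand eigen-decomposition", {
  # 3 samples x 2 features, unscaled to keep the arithmetic transparent
  X <- rbind(c(1, 0), c(-1, 1), c(0, -1))
  y <- c(1, -1, 0)
  alpha <- 0.7
  m <- fit_pcovr(X, y, alpha = alpha, k = 2, scale = FALSE, lambda = 1e-10)
  # hand construction of the modified Gram matrix
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  w <- solve(crossprod(Xc) + 1e-10 * diag(2), crossprod(Xc, yc))
  yhat <- Xc %*% w
  G <- alpha * Xc %*% t(Xc) + (1 - alpha) * yhat %*% t(yhat)
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  hand_scores <- e$vectors[, 1:2] %*% diag(sqrt(e$values[1:2]))
  for (j in 1:2) {
    a <- m$scores[, j]
    b <- hand_scores[, j]
    expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-8)
  }
  expect_error(fit_pcovr(X, y, k = 3), "rank")
})

test_that("projection is exact on training data, centered, and linear", {
  d <- make_toy_xy()
  m <- fit_pcovr(d$X, d$y, alpha = 0.5, k = 3)
  # training rows project onto their own scores
  expect_lt(max(abs(pcovr_project(m, d$X) - m$scores)), 1e-10)
  # the training mean lands at the origin
  expect_lt(max(abs(pcovr_project(m, matrix(m$center, 1)))), 1e-10)
  # a midpoint in feature space lands midway in latent space
  mid <- (d$X[1, ] + d$X[2, ]) / 2
  expect_lt(
    max(abs(
      pcovr_project(m, matrix(mid, 1)) - (m$scores[1, ] + m$scores[2, ]) / 2
    )),
    1e-10
  )
  expect_error(pcovr_project(m, matrix(0, 1, 2)), "dimension")
})

test_that("axis-property correlations behave like Pearson correlation should", {
  d <- make_toy_xy()
  m <- fit_pcovr(d$X, d$y, alpha = 0.5, k = 3)
  pts <- pcovr_map_points(m, d$X, ids = seq_len(nrow(d$X)), color = d$y)
  cc <- correlate_axes(pts, tibble::tibble(
    same = pts$PCov_1, flipped = -pts$PCov_2
  ))
  expect_equal(cc$pcc[cc$axis == "PCov_1" & cc$property == "same"], 1)
  expect_equal(cc$pcc[cc$axis == "PCov_2" & cc$property == "flipped"], -1)
  expect_warning(
    cc0 <- correlate_axes(pts, tibble::tibble(flat = rep(1, nrow(pts)))),
    "zero variance"
  )
  expect_true(all(is.na(cc0$pcc)))

  # an independent property decorrelates as ~ 2/sqrt(n)
  set.seed(31)
  trials <- replicate(50, {
    cc <- suppressWarnings(correlate_axes(
      pts, tibble::tibble(noise = rnorm(nrow(pts)))
    ))
    abs(cc$pcc[cc$axis == "PCov_1"])
  })
  expect_lt(mean(trials), 2 / sqrt(nrow(pts)))
})

test_that("latent-space similarity search matches brute force and uses all covariates", {
  set.seed(17)
  n <- 100
  X <- matrix(rnorm(n * 6), n, 6)
  y <- X %*% rnorm(6)
  m <- fit_pcovr(X, y, alpha = 0.5, k = 3)
  pts <- pcovr_map_points(m, X, ids = paste0("p", seq_len(n)), color = y)
  res <- similar_motifs(pts, "p7", k = 5)
  M <- as.matrix(pts[, c("PCov_1", "PCov_2", "PCov_3")])
  d <- sqrt(colSums((t(M) - M[7, ])^2))
  d <- d[-7]
  names(d) <- pts$id[-7]
  near <- res[res$kind == "nearest", ]
  expect_identical(near$id, names(sort(d))[1:5])
  expect_equal(near$distance, unname(sort(d)[1:5]), tolerance = 1e-12)
  far <- res[res$kind == "farthest", ]
  expect_identical(far$id, names(sort(d, decreasing = TRUE))[1:5])

  # a duplicated query point is its own nearest neighbor at distance zero
  pts2 <- dplyr::bind_rows(pts, dplyr::mutate(pts[7, ], id = "dup"))
  res2 <- similar_motifs(pts2, "p7", k = 1)
  expect_identical(res2$id[res2$kind == "nearest"], "dup")
  expect_equal(res2$distance[res2$kind == "nearest"], 0, tolerance = 1e-12)

  # extremal in a 2-D slice need not be extremal in the full space:
  # a point far out along PCov_3 only
  Mx <- rbind(
    c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.1, 0.1, 9)
  )
  ptsx <- tibble::tibble(
    id = c("q", "a", "b", "hidden"),
    PCov_1 = Mx[, 1], PCov_2 = Mx[, 2], PCov_3 = Mx[, 3],
    color = 0, in_sample = TRUE
  )
  class(ptsx) <- c("pcovr_map", class(ptsx))
  resx <- similar_motifs(ptsx, "q", k = 1)
  # in the PCov_1/PCov_2 slice "hidden" looks closest to q ...
  slice_d <- sqrt(rowSums(Mx[-1, 1:2]^2))
  expect_equal(which.min(slice_d), 3L, ignore_attr = TRUE)
  # ... but the full-space farthest point is exactly "hidden"
  expect_identical(resx$id[resx$kind == "farthest"], "hidden")

  expect_error(similar_motifs(pts, "nope", k = 1), "unknown query")
  expect_error(similar_motifs(pts, "p7", k = 1000), "exceeds")
})

test_that("scores vary continuously with alpha after canonicalization", {
  d <- make_toy_xy(n = 20, p = 4, seed = 12)
  alphas <- seq(0.2, 0.8, by = 0.05)
  prev <- NULL
  for (a in alphas) {
    m <- fit_pcovr(d$X, d$y, alpha = a, k = 2)
    # deterministic: refitting gives identical scores (fixed eigen
    # ordering and sign convention)
    expect_identical(m$scores, fit_pcovr(d$X, d$y, alpha = a, k = 2)$scores)
    if (!is.null(prev)) {
      # the spanned 2-D subspace moves continuously with alpha (smallest
      # canonical correlation stays near 1 even where eigenvalues cross
      # and the component ORDER legitimately changes)
      cc <- svd(crossprod(
        qr.Q(qr(m$scores)), qr.Q(qr(prev))
      ))$d
      expect_gt(min(cc), 0.95)
    }
    prev <- m$scores
  }
})

test_that("neighbor ranking is unchanged under a rigid rotation of the latent basis", {
  set.seed(23)
  M <- matrix(rnorm(40 * 3), 40, 3)
  rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  mk <- function(mat) {
    p <- tibble::tibble(
      id = paste0("m", seq_len(nrow(mat))),
      PCov_1 = mat[, 1], PCov_2 = mat[, 2], PCov_3 = mat[, 3],
      color = 0, in_sample = TRUE
    )
    class(p) <- c("pcovr_map", class(p))
    p
  }
  r1 <- similar_motifs(mk(M), "m5", k = 4)
  r2 <- similar_motifs(mk(M %*% rot), "m5", k = 4)
  expect_identical(r1$id, r2$id)
  expect_equal(r1$distance, r2$distance, tolerance = 1e-10)
})

test_that("pcovr maps glance, tidy and plot", {
  d <- make_toy_xy()
  m <- fit_pcovr(d$X, d$y, alpha = 0.5, k = 2)
  gl <- glance(m)
  expect_equal(gl$k, 2L)
  td <- tidy(m)
  expect_equal(nrow(td), 2 * ncol(d$X))
  pts <- pcovr_map_points(m, d$X, color = d$y)
  expect_s3_class(autoplot(pts), "ggplot")
  stem <- withr::local_tempfile()
  write_pcovr(m, pts, stem)
  expect_true(file.exists(paste0(stem, "_map.csv")))
  expect_true(file.exists(paste0(stem, "_model.json")))
})
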