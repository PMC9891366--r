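test_that("composition baseline reproduces closed-form least squares", {
  w <- water_molecule() # H2O: fractions (H 2/3, O 1/3)
  oh <- atomic_structure(
    tibble::tibble(element = c("O", "H"), x = c(0, 1), y = 0, z = 0)
  ) # fractions (1/2, 1/2)
  structures <- list(w, w, oh, oh)
  # energies exactly linear in composition: zero residuals
  cH <- -400
  cO <- -3000
  e <- c(
    2 / 3 * cH + 1 / 3 * cO, 2 / 3 * cH + 1 / 3 * cO,
    0.5 * cH + 0.5 * cO, 0.5 * cH + 0.5 * cO
  )
  bl <- fit_baseline(structures, e)
  expect_equal(unname(bl$coefficients[c("H", "O")]), c(cH, cO), tolerance = 1e-9)
  expect_lt(max(abs(predict(bl, structures) - e)), 1e-9)

  # single-element data: coefficient is the mean per-atom energy
  lone <- atomic_structure(tibble::tibble(element = "O", x = 0, y = 0, z = 0))
  bl1 <- fit_baseline(list(lone, lone), c(-10, -12))
  expect_equal(unname(bl1$coefficients), -11)

  # two-element toy set solved by hand via the 2x2 normal equations
  e2 <- c(-1000, -1010, -1600, -1580)
  M <- rbind(
    c(2 / 3, 1 / 3), c(2 / 3, 1 / 3),
    c(1 / 2, 1 / 2), c(1 / 2, 1 / 2)
  )
  hand <- solve(crossprod(M), crossprod(M, e2))
  bl2 <- fit_baseline(structures, e2)
  expect_equal(unname(bl2$coefficients), as.vector(hand), tolerance = 1e-9)

  # identical compositions cannot identify per-element energies
  expect_error(fit_baseline(list(w, w, w), c(-1, -2, -3)), "rank-deficient")
})

test_that("ridge fitting recovers exact linear relations and handles degenerate targets", {
  X <- matrix(seq(-2, 2, length.out = 9), ncol = 1)
  m <- fit_energy_model(X, 2 * X[, 1], feature_space = "s")
  expect_equal(unname(m$w), 2, tolerance = 1e-10)
  expect_equal(m$b, 0, tolerance = 1e-10)

  m0 <- fit_energy_model(X, rep(0, 9), lambda_grid = c(1e-3, 1, 10))
  expect_equal(unname(m0$w), 0, tolerance = 1e-12)

  expect_error(fit_energy_model(X, c(rep(0, 8), NA)), "non-finite")
  expect_error(
    predict_lattice_energy_direct(c(1, 2), fit_energy_model(X, 2 * X[, 1],
      feature_space = "remnant"
    ), feature_space = "s"),
    "mismatch"
  )
})

test_that("direct lattice models are linear and vanish on the zero remnant", {
  set.seed(3)
  X <- matrix(rnorm(40), 10, 4)
  w <- c(1, -2, 0.5, 3)
  m <- fit_energy_model(X, as.vector(X %*% w),
    feature_space = "remnant", intercept = FALSE
  )
  # a crystal indistinguishable from its gas molecules binds by zero
  expect_equal(predict_lattice_energy_direct(rep(0, 4), m), 0, tolerance = 1e-10)
  # linearity
  x1 <- rnorm(4)
  x2 <- rnorm(4)
  expect_equal(
    predict(m, x1 + x2), predict(m, x1) + predict(m, x2),
    tolerance = 1e-10
  )
})

test_that("the combined two-model route equals the difference of its parts and drops baselines", {
  ds <- small_synth()
  ev <- ds$energy
  n <- length(ds$records)
  Xs <- collection_matrix(ds, "s")
  Xg <- collection_matrix(ds, "g")
  m_c <- fit_energy_model(Xs, ev$e_c, feature_space = "s")
  m_m <- fit_energy_model(Xg, vapply(
    seq_len(n),
    function(i) sum(ev$E_c[i] * 0 + unlist(ev$e_m[i]) * unlist(ev$n_m[i])) / ev$n_c[i],
    numeric(1)
  ), feature_space = "g")
  x_s <- structure(
    list(x = Xs[1, ], n = ev$n_c[1], scope = "crystal", config_hash = "h"),
    class = "collection_descriptor"
  )
  x_g <- structure(
    list(x = Xg[1, ], n = ev$n_c[1], scope = "crystal", config_hash = "h"),
    class = "collection_descriptor"
  )
  comb <- predict_lattice_energy_combined(x_s, x_g, m_c, m_m,
    rec = ds$records[[1]]
  )
  expect_equal(comb, predict(m_c, x_s) - predict(m_m, x_g), tolerance = 1e-12)

  # identical models on identical features predict zero binding
  expect_equal(
    predict_lattice_energy_combined(x_s, x_s, m_c, m_c),
    0,
    tolerance = 1e-12
  )
})

test_that("per-element energy shifts leave every lattice-energy prediction unchanged", {
  ds <- small_synth()
  ev <- ds$energy
  Xr <- collection_matrix(ds, "remnant")
  # shift all total energies by an arbitrary per-element constant
  shift <- c(H = 17.3, O = -41.2)
  ev2_delta <- vapply(seq_along(ds$records), function(i) {
    r <- ds$records[[i]]
    dE_c <- sum(shift[species(r$crystal)])
    dE_m <- vapply(
      r$molecules,
      function(m) sum(shift[species(m$gas_structure)]), numeric(1)
    )
    ((r$E_crystal + dE_c) - sum(r$E_molecules + dE_m)) / ev$n_c[i]
  }, numeric(1))
  # the lattice energy itself is invariant ...
  expect_lt(max(abs(ev2_delta - ev$delta_c)), 1e-9)
  # ... hence so is any model fitted on it
  m1 <- fit_energy_model(Xr, ev$delta_c, feature_space = "remnant")
  m2 <- fit_energy_model(Xr, ev2_delta, feature_space = "remnant")
  expect_lt(max(abs(predict(m1, Xr) - predict(m2, Xr))), 1e-7)
})

test_that("error metrics match their definitions and converge for Gaussian residuals", {
  expect_equal(evaluate_model(1:5, 1:5)$rmse, 0)
  expect_equal(evaluate_model(1:5, 1:5)$mae, 0)
  m <- evaluate_model(c(1, -1, 1, -1), c(0, 0, 0, 0))
  expect_equal(m$rmse, 1)
  expect_equal(m$mae, 1)
  expect_error(evaluate_model(1:3, 1:4), "length")

  set.seed(99)
  r <- rnorm(20000, 0, 0.7)
  mc <- evaluate_model(r, rep(0, 20000))
  expect_equal(mc$rmse, 0.7, tolerance = 0.02)
})

test_that("farthest point sampling matches exhaustive max-min search", {
  # hand case: {0, 1, 10} starting at 0 picks the far point first
  X <- matrix(c(0, 1, 10), ncol = 1)
  expect_identical(fps_select(X, 3, start = 1), c(1L, 3L, 2L))

  # k = n yields a permutation
  set.seed(5)
  Xn <- matrix(rnorm(16), 8, 2)
  expect_setequal(fps_select(Xn, 8), 1:8)
  expect_error(fps_select(Xn, 9), "exceeds")

  # greedy trace equals brute-force greedy on <= 8 points
  brute_greedy <- function(X, k, start) {
    sel <- start
    while (length(sel) < k) {
      rest <- setdiff(seq_len(nrow(X)), sel)
      score <- vapply(rest, function(j) {
        min(vapply(
          sel,
          function(i) sqrt(sum((X[i, ] - X[j, ])^2)), numeric(1)
        ))
      }, numeric(1))
      best <- max(score)
      cand <- rest[score >= best - 1e-12]
      sel <- c(sel, min(cand))
    }
    sel
  }
  for (trial in 1:5) {
    Xt <- matrix(rnorm(8 * 3), 8, 3)
    expect_identical(
      fps_select(Xt, 6, start = 2),
      as.integer(brute_greedy(Xt, 6, 2L))
    )
  }

  # FPS spreads points: min pairwise distance beats random selection
  set.seed(7)
  Xbig <- matrix(rnorm(200), 100, 2)
  minpair <- function(idx) {
    min(dist(Xbig[idx, ]))
  }
  fps_d <- minpair(fps_select(Xbig, 10))
  rnd <- replicate(100, minpair(sample(100, 10)))
  expect_gt(fps_d, mean(rnd))
})

test_that("models round-trip through JSON with their baseline", {
  ds <- small_synth()
  Xr <- collection_matrix(ds, "remnant")
  m <- fit_energy_model(Xr, ds$energy$delta_c, feature_space = "remnant")
  bl <- fit_baseline(
    lapply(ds$records, function(r) r$crystal),
    ds$energy$e_c,
    allow_rank_deficient = TRUE # water-only data: one shared composition
  )
  path <- withr::local_tempfile(fileext = ".json")
  write_lattice_model(m, path, baseline = bl, config_hash = "abc")
  back <- read_lattice_model(path)
  expect_equal(back$model$w, m$w, tolerance = 1e-12)
  expect_equal(back$model$b, m$b, tolerance = 1e-12)
  expect_identical(back$config_hash, "abc")
  expect_equal(back$baseline$coefficients, bl$coefficients, tolerance = 1e-12)
  expect_lt(
    max(abs(predict(back$model, Xr) - predict(m, Xr))), 1e-10
  )
})

test_that("tidy and glance summarize lattice models", {
  X <- matrix(rnorm(30), 10, 3)
  m <- fit_energy_model(X, rnorm(10), feature_space = "remnant")
  td <- tidy(m)
  expect_identical(td$term[1], "(Intercept)")
  expect_equal(nrow(td), 4)
  gl <- glance(m)
  expect_identical(gl$feature_space, "remnant")
  expect_equal(gl$n_features, 3L)
})
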