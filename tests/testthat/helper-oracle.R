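# independent oracle: expansion coefficients of the Gaussian-smeared
# neighbor density by full 3-D numerical quadrature, with hard-coded
# Cartesian real spherical harmonics (no code shared with the
# implementation's recurrences)
oracle_power_spectrum <- function(s, cfg, center_atom = 1) {
  Zfun <- list(
    function(x, y, z) rep(0.28209479177387814, length(x)),
    function(x, y, z) 0.4886025119029199 * y,
    function(x, y, z) 0.4886025119029199 * z,
    function(x, y, z) 0.4886025119029199 * x,
    function(x, y, z) 1.0925484305920792 * x * y,
    function(x, y, z) 1.0925484305920792 * y * z,
    function(x, y, z) 0.31539156525252005 * (3 * z^2 - 1),
    function(x, y, z) 1.0925484305920792 * x * z,
    function(x, y, z) 0.5462742152960396 * (x^2 - y^2)
  )
  lof <- c(0, 1, 1, 1, 2, 2, 2, 2, 2)
  stopifnot(cfg$l_max == 2)
  glr <- latticemotifs:::gauss_legendre(120, cfg$r_cut)
  centers <- seq_len(cfg$n_max) * cfg$r_cut / cfg$n_max
  width <- cfg$r_cut / cfg$n_max
  fc <- 0.5 * (cos(pi * glr$x / cfg$r_cut) + 1)
  phi0 <- sapply(centers, function(c0) exp(-(glr$x - c0)^2 / (2 * width^2)) * fc)
  S <- crossprod(phi0, phi0 * (glr$w * glr$x^2))
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  Rn <- phi0 %*% (e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors))
  glt <- latticemotifs:::gauss_legendre(40, 2)
  ct <- glt$x - 1
  wt <- glt$w
  st <- sqrt(pmax(1 - ct^2, 0))
  ngp <- 60
  ph <- (seq_len(ngp) - 1) * 2 * pi / ngp
  wp <- rep(2 * pi / ngp, ngp)
  pos <- positions(s)
  rel <- sweep(pos, 2, pos[center_atom, ])
  el <- species(s)
  sig2 <- cfg$sigma_atom^2
  Q <- length(cfg$species) * cfg$n_max
  Cora <- matrix(0, Q, 9)
  for (j in seq_len(nrow(rel))) {
    a <- match(el[j], cfg$species)
    rows <- (a - 1) * cfg$n_max + seq_len(cfg$n_max)
    for (lm in 1:9) {
      acc <- numeric(cfg$n_max)
      for (it in seq_along(ct)) {
        for (ip in seq_len(ngp)) {
          ux <- st[it] * cos(ph[ip])
          uy <- st[it] * sin(ph[ip])
          uz <- ct[it]
          zval <- Zfun[[lm]](ux, uy, uz)
          d2 <- (glr$x * ux - rel[j, 1])^2 + (glr$x * uy - rel[j, 2])^2 +
            (glr$x * uz - rel[j, 3])^2
          rho <- exp(-d2 / (2 * sig2))
          acc <- acc + wt[it] * wp[ip] * zval *
            as.vector(crossprod(rho * glr$w * glr$x^2, Rn))
        }
      }
      Cora[rows, lm] <- Cora[rows, lm] + acc
    }
  }
  pairs <- latticemotifs:::feature_pairs(cfg)
  feat <- c()
  for (l in 0:2) {
    Pl <- tcrossprod(Cora[, which(lof == l), drop = FALSE]) / sqrt(2 * l + 1)
    v <- Pl[pairs$lin]
    v[pairs$off_diag] <- v[pairs$off_diag] * sqrt(2)
    feat <- c(feat, v)
  }
  feat
}
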