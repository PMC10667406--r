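# Independent oracles used across the suite.  These deliberately avoid the
# code paths they check: finite differences instead of closed-form Jacobians,
# polyroot instead of sign tests, circle-sampling Fourier extraction instead
# of symbolic normal-form coefficients.

# central-difference Jacobian of map_step
fd_jacobian <- function(s, p, h = NULL) {
  if (is.null(h)) h <- 1e-6 * max(1, abs(s))
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    e <- c(0, 0); e[j] <- h
    J[, j] <- (map_step(s + e, p) - map_step(s - e, p)) / (2 * h)
  }
  J
}

# classify a quadratic lambda^2 + B lambda + C from its numerically solved
# roots (only meaningful away from boundaries)
oracle_classify <- function(B, C) {
  r <- polyroot(c(C, B, 1))
  m <- Mod(r)
  if (all(m < 1)) return("both_inside")
  if (all(m > 1)) {
    re <- Re(r)
    if (all(abs(Im(r)) < 1e-9) && min(re) < -1 && max(re) > 1)
      return("one_beyond_one_other_below_minus_one")
    return("both_outside")
  }
  # one inside, one outside: roots are real; which side is the outside one?
  re <- Re(r)
  out_root <- re[which.max(m)]
  if (out_root > 1) "one_beyond_one_other_inside" else "split_inside_outside"
}

# deterministic sampler of (a, delta) pairs inside the Neimark-Sacker region
sample_ns_pairs <- function(n, a_range = c(1.05, 3), frac = c(0.1, 0.9)) {
  a <- runif(n, a_range[1], a_range[2])
  t(vapply(a, function(ai) {
    ds <- delta_star(ai)
    sq <- sqrt((ai - 1) / ai)
    c(ai, ds + (sq - ds) * runif(1, frac[1], frac[2]))
  }, numeric(2)))
}

# sampler of (a, delta) pairs where E2 exists (not necessarily NS region)
sample_e2_pairs <- function(n, a_range = c(0.2, 3)) {
  a <- runif(n, a_range[1], a_range[2])
  t(vapply(a, function(ai) {
    lo <- max(0, (ai - 1) / ai)
    c(ai, lo + (1 - lo) * runif(1, 0.05, 0.95))
  }, numeric(2)))
}

# directed + symmetric Hausdorff distance between two point clouds (n x 2)
hausdorff_dist <- function(A, B) {
  directed <- function(P, Q) {
    m <- 0
    for (i in seq_len(nrow(P))) {
      d <- sqrt((Q[, 1] - P[i, 1])^2 + (Q[, 2] - P[i, 2])^2)
      m <- max(m, min(d))
    }
    m
  }
  max(directed(A, B), directed(B, A))
}

# plain bisection root of delta^3 - delta^2 + delta - (a-1)/a, independent of
# delta_star()'s uniroot/Newton path
bisect_delta_star <- function(a, iter = 200) {
  cc <- (a - 1) / a
  f <- function(d) d^3 - d^2 + d - cc
  lo <- cc; hi <- sqrt(cc)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Fourier (circle-sampling) extraction of the complex normal-form
# coefficients zeta_jk and the discriminant L, built only on map_step and
# base eigen(): independent of the symbolic pipeline.
oracle_ns_L <- function(a, delta) {
  e0 <- epsilon0(a, delta)
  p <- model_params(a, delta, e0)
  x0 <- 1 - a + a * delta; y0 <- x0 * (1 - delta) / delta
  J <- jacobian_at_e2(p)
  lam <- eigen(J)$values
  lam1 <- lam[which(Im(lam) > 0)][1]
  al1 <- Re(lam1); al2 <- Im(lam1)
  c10 <- J[1, 1]; c01 <- J[1, 2]
  Tm <- matrix(c(c01, 0, al1 - c10, -al2), 2, 2, byrow = TRUE)
  Tinv <- solve(Tm)
  planar <- function(X, Y) {
    uv <- Tm %*% c(X, Y)
    im <- map_step(c(uv[1] + x0, uv[2] + y0), p) - c(x0, y0)
    Tinv %*% im
  }
  wcirc <- function(r, M = 64) {
    th <- 2 * pi * (0:(M - 1)) / M
    w <- complex(length.out = M)
    for (k in seq_len(M)) {
      o <- planar(r * cos(th[k]), r * sin(th[k]))
      w[k] <- complex(real = o[1], imaginary = o[2])
    }
    f <- stats::fft(w) / M
    list(c0 = f[1], c1 = f[2], c2 = f[3], cm2 = f[M - 1])
  }
  r1 <- 1e-3; r2 <- 2e-3        # Richardson over two radii kills O(r^2) bias
  A <- wcirc(r1); B <- wcirc(r2)
  z20 <- (4 * A$c2 / r1^2 - B$c2 / r2^2) / 3
  z11 <- (4 * A$c0 / r1^2 - B$c0 / r2^2) / 3
  z02 <- (4 * A$cm2 / r1^2 - B$cm2 / r2^2) / 3
  z21 <- (4 * (A$c1 - lam1 * r1) / r1^3 - (B$c1 - lam1 * r2) / r2^3) / 3
  lam2 <- Conj(lam1)
  list(L = -Re((1 - 2 * lam1) * lam2^2 / (1 - lam1) * z20 * z11) -
         0.5 * Mod(z11)^2 - Mod(z02)^2 + Re(lam2 * z21),
       zeta20 = z20, zeta11 = z11, zeta02 = z02, zeta21 = z21,
       lambda1 = lam1)
}

# finite-difference extraction of bivariate Taylor series coefficients of a
# planar function around the origin.  Tensor products of second-order central
# stencils, sharpened to O(h^6) by double Richardson extrapolation over
# h, h/2, h/4.
fd_stencil <- function(k, h) {
  switch(as.character(k),
    "0" = list(off = 0, w = 1),
    "1" = list(off = c(-1, 1), w = c(-0.5, 0.5) / h),
    "2" = list(off = c(-1, 0, 1), w = c(1, -2, 1) / h^2),
    "3" = list(off = c(-2, -1, 1, 2), w = c(-0.5, 1, -1, 0.5) / h^3),
    stop("stencil order > 3"))
}

fd_mixed_partial <- function(fun, iu, jv, h0 = 0.02) {
  once <- function(h) {
    su <- fd_stencil(iu, h); sv <- fd_stencil(jv, h)
    acc <- c(0, 0)
    for (p in seq_along(su$off)) for (q in seq_along(sv$off))
      acc <- acc + su$w[p] * sv$w[q] * fun(su$off[p] * h, sv$off[q] * h)
    acc
  }
  t1 <- once(h0); t2 <- once(h0 / 2); t3 <- once(h0 / 4)
  r1 <- (4 * t2 - t1) / 3; r2 <- (4 * t3 - t2) / 3
  (16 * r2 - r1) / 15
}

fd_series_coeffs <- function(fun, h0 = 0.02) {
  mono <- expand.grid(du = 0:3, dv = 0:3)
  mono <- mono[mono$du + mono$dv >= 1 & mono$du + mono$dv <= 3, ]
  cvals <- numeric(nrow(mono)); dvals <- numeric(nrow(mono))
  for (k in seq_len(nrow(mono))) {
    v <- fd_mixed_partial(fun, mono$du[k], mono$dv[k], h0) /
      (factorial(mono$du[k]) * factorial(mono$dv[k]))
    cvals[k] <- v[1]; dvals[k] <- v[2]
  }
  nm <- paste0(mono$du, mono$dv)
  list(c = stats::setNames(cvals, nm), d = stats::setNames(dvals, nm))
}
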