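# Numerical dynamics: orbits, Lyapunov exponents, parameter sweeps and phase
# portraits.  Everything here is deterministic: identical inputs give
# bit-identical outputs.

DIVERGENCE_GUARD <- 1e12

# fast scalar step, no validation (hot loop); callers validate once
step_xy <- function(x, y, a, delta, eps) {
  if (x + y == 0) return(c(0, 0))
  rx <- x / (x + y)
  c(x * exp(1 - x - a * (1 - rx)), y * exp(eps * (rx - delta)))
}

check_divergence <- function(x, y, i) {
  if (!is.finite(x) || !is.finite(y) || abs(x) > DIVERGENCE_GUARD ||
      abs(y) > DIVERGENCE_GUARD)
    stop("orbit diverged at step ", i, ": state (", x, ", ", y, ")",
         call. = FALSE)
}

#' Iterate an orbit of the map
#'
#' @param initial Numeric `c(x, y)`, nonnegative.
#' @param p An [model_params()] object.
#' @param n Number of states to keep (after discarding).
#' @param n_discard Transient length discarded before recording.
#' @return Object of class `sfpp_orbit`: list with `params`, `initial`,
#'   `n_discard` and `states`, an `n x 2` matrix of post-transient states
#'   (the first recorded row is the state after `n_discard + 1` steps).
#' @export
#' @examples
#' p <- model_params(16/11, 0.5, 0.6)
#' orb <- iterate_orbit(c(0.6, 0.2), p, n = 100, n_discard = 1000)
#' tail(orb$states, 1)   # near E2 = (3/11, 3/11): epsilon > epsilon0 regime
iterate_orbit <- function(initial, p, n, n_discard = 0) {
  stopifnot(inherits(p, "sfpp_params"))
  check_state(initial)
  if (n <= 0 || n_discard < 0) stop("need n > 0 and n_discard >= 0", call. = FALSE)
  check_divergence(initial[1], initial[2], 0L)
  a <- p$a; d <- p$delta; e <- p$epsilon
  x <- initial[[1]]; y <- initial[[2]]
  i <- 0L
  if (n_discard > 0) for (i in seq_len(n_discard)) {
    s <- step_xy(x, y, a, d, e); x <- s[1]; y <- s[2]
    check_divergence(x, y, i)
  }
  states <- matrix(0, nrow = n, ncol = 2, dimnames = list(NULL, c("x", "y")))
  for (k in seq_len(n)) {
    s <- step_xy(x, y, a, d, e); x <- s[1]; y <- s[2]
    check_divergence(x, y, n_discard + k)
    states[k, 1] <- x; states[k, 2] <- y
  }
  structure(list(params = p, initial = initial, n_discard = n_discard,
                 states = states),
            class = "sfpp_orbit")
}

#' Lyapunov exponents along an orbit
#'
#' Both Lyapunov exponents via products of Jacobians with per-step
#' Gram-Schmidt renormalization of the tangent 2-frame (log-norm
#' accumulation), the standard Benettin procedure.  On a fixed point the
#' maximal exponent equals the log-modulus of the dominant eigenvalue; the
#' sum of the two exponents always equals the orbit average of
#' \eqn{\log|\det J|}.
#'
#' @inheritParams iterate_orbit
#' @param n Number of accumulation steps (at least 1000).
#' @param n_discard Transient steps before accumulation starts.
#' @return Object of class `sfpp_lyapunov`: list with `exponents` (two
#'   reals, sorted descending), `n_iter`, `n_discard`.
#' @export
max_lyapunov <- function(initial, p, n = 1e5, n_discard = 1000) {
  stopifnot(inherits(p, "sfpp_params"))
  check_state(initial)
  if (n < 1000) stop("need n >= 1000 accumulation steps", call. = FALSE)
  a <- p$a; d <- p$delta; e <- p$epsilon
  x <- initial[[1]]; y <- initial[[2]]
  if (n_discard > 0) for (i in seq_len(n_discard)) {
    s <- step_xy(x, y, a, d, e); x <- s[1]; y <- s[2]
    check_divergence(x, y, i)
  }
  q11 <- 1; q21 <- 0; q12 <- 0; q22 <- 1     # orthonormal tangent frame
  s1 <- 0; s2 <- 0
  for (i in seq_len(n)) {
    if (x + y == 0)
      stop("Jacobian evaluation failure on the orbit at step ", i,
           ": state reached (0, 0)", call. = FALSE)
    rx <- x / (x + y); ry <- 1 - rx
    E1 <- exp(1 - x - a * ry); E2 <- exp(e * (rx - d))
    j11 <- (1 - x + a * rx * ry) * E1; j12 <- -a * rx^2 * E1
    j21 <- e * ry^2 * E2;              j22 <- (1 - e * rx * ry) * E2
    # M = J %*% Q, then Gram-Schmidt on columns
    m11 <- j11 * q11 + j12 * q21; m21 <- j21 * q11 + j22 * q21
    m12 <- j11 * q12 + j12 * q22; m22 <- j21 * q12 + j22 * q22
    n1 <- sqrt(m11^2 + m21^2)
    q11 <- m11 / n1; q21 <- m21 / n1
    pr <- q11 * m12 + q21 * m22
    r12 <- m12 - pr * q11; r22 <- m22 - pr * q21
    n2 <- sqrt(r12^2 + r22^2)
    q12 <- r12 / n2; q22 <- r22 / n2
    s1 <- s1 + log(n1); s2 <- s2 + log(n2)
    s <- step_xy(x, y, a, d, e); x <- s[1]; y <- s[2]
    check_divergence(x, y, n_discard + i)
  }
  structure(list(exponents = sort(c(s1, s2) / n, decreasing = TRUE),
                 n_iter = n, n_discard = n_discard),
            class = "sfpp_lyapunov")
}

#' Bifurcation sweep in the time-scale ratio epsilon
#'
#' For each epsilon on a uniform grid: iterate the map, record `n_keep`
#' post-transient prey values (the vertical slices of a bifurcation diagram
#' in the \eqn{(\epsilon, x)} plane), and optionally the maximal Lyapunov
#' exponent continued from the post-transient state.
#'
#' @inheritParams epsilon0
#' @param eps_lo,eps_hi Sweep range, `0 < eps_lo < eps_hi < 1`.
#' @param n_eps Number of grid points.
#' @param initial Initial state for every slice.
#' @param n_discard Transient discarded per slice.
#' @param n_keep Post-transient prey samples stored per slice.
#' @param mle Compute the maximal Lyapunov exponent per slice?
#' @param mle_n Accumulation steps for the exponent.
#' @return Object of class `sfpp_sweep`: list with `eps_grid`, `samples`
#'   (`n_eps x n_keep` matrix of x values), `mle` (vector or `NULL`), plus
#'   the generating settings.
#' @export
bifurcation_sweep <- function(a, delta, eps_lo, eps_hi, n_eps = 500,
                              initial = c(0.6, 0.2), n_discard = 1000,
                              n_keep = 200, mle = FALSE, mle_n = 10000) {
  if (!(eps_lo > 0 && eps_lo < eps_hi && eps_hi < 1))
    stop("need 0 < eps_lo < eps_hi < 1", call. = FALSE)
  grid <- seq(eps_lo, eps_hi, length.out = n_eps)
  samples <- matrix(NA_real_, nrow = n_eps, ncol = n_keep)
  mle_vals <- if (mle) rep(NA_real_, n_eps) else NULL
  for (k in seq_len(n_eps)) {
    p <- model_params(a, delta, grid[k])
    orb <- iterate_orbit(initial, p, n = n_keep, n_discard = n_discard)
    samples[k, ] <- orb$states[, "x"]
    if (mle) {
      start <- orb$states[n_keep, ]
      mle_vals[k] <- max_lyapunov(start, p, n = mle_n, n_discard = 0)$exponents[1]
    }
  }
  structure(list(a = a, delta = delta, eps_grid = grid, samples = samples,
                 mle = mle_vals, initial = initial, n_discard = n_discard,
                 n_keep = n_keep),
            class = "sfpp_sweep")
}

#' Estimate the Neimark-Sacker onset from a sweep
#'
#' The onset is estimated as the largest grid epsilon whose post-transient
#' sample spread (max minus min of the stored prey values) exceeds
#' `threshold`: below the critical value orbits settle on an invariant curve
#' of positive width, above it they collapse onto E2.
#'
#' @param sweep A [bifurcation_sweep()] result.
#' @param threshold Spread threshold separating point-like from curve-like
#'   slices.
#' @return The estimated onset epsilon (`NA` if no slice exceeds the
#'   threshold).
#' @export
ns_onset_estimate <- function(sweep, threshold = 1e-3) {
  stopifnot(inherits(sweep, "sfpp_sweep"))
  spread <- apply(sweep$samples, 1, function(r) diff(range(r)))
  wide <- which(spread > threshold)
  if (!length(wide)) return(NA_real_)
  sweep$eps_grid[max(wide)]
}

#' Post-transient point clouds for phase portraits
#'
#' @inheritParams iterate_orbit
#' @param initials List of initial states.
#' @param n Points kept per cloud.
#' @return Named list (`init1`, `init2`, ...) of `n x 2` matrices.
#' @export
phase_portrait_samples <- function(p, initials, n = 2000, n_discard = 1000) {
  stopifnot(inherits(p, "sfpp_params"), is.list(initials))
  out <- lapply(initials, function(s0)
    iterate_orbit(s0, p, n = n, n_discard = n_discard)$states)
  names(out) <- paste0("init", seq_along(out))
  out
}

#' @export
print.sfpp_orbit <- function(x, ...) {
  cat(sprintf("orbit: %d stored states after %d discarded (a = %g, delta = %g, epsilon = %g)\n",
              nrow(x$states), x$n_discard, x$params$a, x$params$delta,
              x$params$epsilon))
  cat(sprintf("  final state: (%.8g, %.8g)\n",
              x$states[nrow(x$states), 1], x$states[nrow(x$states), 2]))
  invisible(x)
}

#' @export
print.sfpp_lyapunov <- function(x, ...) {
  cat(sprintf("Lyapunov exponents (n = %d, discard = %d): %.6g, %.6g\n",
              x$n_iter, x$n_discard, x$exponents[1], x$exponents[2]))
  invisible(x)
}
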