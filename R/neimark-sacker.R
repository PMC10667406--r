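# Neimark-Sacker bifurcation analysis at the coexistence equilibrium E2.
#
# Along the path epsilon = epsilon0 + epsilon*, the characteristic polynomial
# of the Jacobian at E2 is F(lambda) = lambda^2 - p(eps*) lambda + q(eps*)
# with q(0) = 1: a conjugate eigenvalue pair sits on the unit circle at
# criticality and crosses it with nonzero speed.  The normal-form pipeline
# shifts E2 to the origin, expands the map to third order by exact symbolic
# differentiation, rotates the linear part to alpha1 +/- i alpha2 form, and
# evaluates the direction discriminant L.

# quoted expressions of the shifted map at E2; variables u, v; free
# parameters a, delta, eps, x0, y0.  (The predator component uses v + y0,
# required for E2 to be a fixed point of the shifted system.)
e2_shifted_exprs <- function() {
  list(u = quote((u + x0) * exp(1 - u - x0 - a * (v + y0) / (u + x0 + v + y0)) - x0),
       v = quote((v + y0) * exp(eps * ((u + x0) / (u + x0 + v + y0) - delta)) - y0))
}

# validate (a, delta) against S_E+, with a message naming the violated
# inequality
check_ns_region <- function(a, delta) {
  if (!is.numeric(a) || !is.finite(a) || a <= 1)
    stop("outside Neimark-Sacker region: requires a > 1 (got a = ", a, ")",
         call. = FALSE)
  ds <- delta_star(a)
  sq <- sqrt((a - 1) / a)
  if (!is.numeric(delta) || !is.finite(delta) || delta <= ds)
    stop("outside Neimark-Sacker region: requires delta > delta_star(a) = ",
         signif(ds, 10), " (got delta = ", delta, ")", call. = FALSE)
  if (delta >= sq)
    stop("outside Neimark-Sacker region: requires delta < sqrt((a-1)/a) = ",
         signif(sq, 10), " (got delta = ", delta, ")", call. = FALSE)
  invisible(list(delta_star = ds, delta_sqrt = sq))
}

#' Eigenvalue path of the Jacobian at E2 across the critical surface
#'
#' For `(a, delta)` inside the Neimark-Sacker region, returns the coefficient
#' functions of the characteristic polynomial along the perturbation
#' \eqn{\epsilon = \epsilon_0 + \epsilon^*}:
#' \deqn{p(\epsilon^*) = 1 + (1-\delta)(a(1+\delta) - \delta(\epsilon^* + \epsilon_0)),}
#' \deqn{q(\epsilon^*) = a(1-\delta)[1 + \delta - \delta(1-\delta)(\epsilon^* + \epsilon_0)],}
#' the conjugate eigenvalue pair
#' \eqn{\lambda_{1,2}(\epsilon^*) = (p \pm i\sqrt{4q - p^2})/2}, and the
#' closed-form modulus derivative
#' \eqn{d|\lambda|/d\epsilon^*|_0 = -a\delta(1-\delta)^2/2 < 0}
#' (the transversality speed: the pair crosses the unit circle inward as
#' \eqn{\epsilon} increases).
#'
#' @inheritParams epsilon0
#' @return Object of class `sfpp_eigen_path`: list with `a`, `delta`, `eps0`,
#'   functions `p_of(eps_star)`, `q_of(eps_star)`, `lambda_of(eps_star)`
#'   (complex pair), `alpha1`, `alpha2` (real/imaginary part of
#'   \eqn{\lambda_1(0)}), and `modulus_derivative_at_0`.
#' @export
eigen_path <- function(a, delta) {
  check_ns_region(a, delta)
  e0 <- epsilon0(a, delta)
  p_of <- function(eps_star)
    1 + (1 - delta) * (a * (1 + delta) - delta * (eps_star + e0))
  q_of <- function(eps_star)
    a * (1 - delta) * (1 + delta - delta * (1 - delta) * (eps_star + e0))
  lambda_of <- function(eps_star) {
    pp <- p_of(eps_star); qq <- q_of(eps_star)
    disc <- 4 * qq - pp^2
    if (disc >= 0) {
      root <- complex(real = pp / 2, imaginary = sqrt(disc) / 2)
      c(root, Conj(root))
    } else {
      r <- sqrt(-disc)
      complex(real = c(pp + r, pp - r) / 2, imaginary = c(0, 0))
    }
  }
  l0 <- lambda_of(0)
  structure(list(a = a, delta = delta, eps0 = e0,
                 p_of = p_of, q_of = q_of, lambda_of = lambda_of,
                 alpha1 = Re(l0[1]), alpha2 = abs(Im(l0[1])),
                 modulus_derivative_at_0 = -a * delta * (1 - delta)^2 / 2),
            class = "sfpp_eigen_path")
}

#' Nondegeneracy (no strong resonance) check at criticality
#'
#' Verifies \eqn{\lambda^m(0) \ne 1} for \eqn{m = 1, \dots, 4}, i.e. the
#' critical eigenvalue is not a first-to-fourth root of unity (the strong
#' resonances excluded by the Neimark-Sacker theorem).
#'
#' @inheritParams epsilon0
#' @param tol Tolerance on \eqn{|\lambda^m - 1|}.
#' @return Named logical vector `m1..m4`; `TRUE` means the resonance is
#'   absent.
#' @export
nondegeneracy_check <- function(a, delta, tol = 1e-9) {
  ep <- eigen_path(a, delta)
  lam <- complex(real = ep$alpha1, imaginary = ep$alpha2)
  out <- vapply(1:4, function(m) Mod(lam^m - 1) > tol, logical(1))
  names(out) <- paste0("m", 1:4)
  out
}

#' Third-order Taylor coefficients of the shifted map at E2
#'
#' Series coefficients of the map shifted so E2 sits at the origin, computed
#' by exact symbolic differentiation, with `epsilon` pinned to the critical
#' value `epsilon0(a, delta)` (the normal form is only valid at criticality;
#' a differing user-supplied `epsilon` is ignored with a warning).  The
#' linear part reproduces [jacobian_at_e2()]:
#' `c10 = a(1-delta^2)`, `c01 = -a delta^2`, `d10 = eps (1-delta)^2`,
#' `d01 = 1 - delta eps (1-delta)`.
#'
#' @param p An [model_params()] object with `(a, delta)` inside the
#'   Neimark-Sacker region.
#' @return List with named numeric vectors `c` (prey component, names
#'   `c10`, `c01`, `c20`, `c11`, `c02`, `c30`, `c21`, `c12`, `c03`) and `d`
#'   (predator component, `d10` ... `d03`); `eps0`; `convention = "series"`.
#' @export
taylor_coefficients_e2 <- function(p) {
  stopifnot(inherits(p, "sfpp_params"))
  check_ns_region(p$a, p$delta)
  e0 <- epsilon0(p$a, p$delta)
  if (abs(p$epsilon - e0) > 1e-12)
    warning("epsilon = ", p$epsilon, " ignored: normal-form coefficients are ",
            "evaluated at the critical value epsilon0 = ", signif(e0, 10),
            call. = FALSE)
  x0 <- 1 - p$a + p$a * p$delta
  y0 <- x0 * (1 - p$delta) / p$delta
  ex <- e2_shifted_exprs()
  env <- list2env(list(a = p$a, delta = p$delta, eps = e0, x0 = x0, y0 = y0,
                       u = 0, v = 0))
  vars <- c("u", "v")
  idxs <- multi_indices(2L, 3L)
  grab <- function(expr, prefix) {
    vals <- vapply(idxs, function(ix) series_coef(expr, vars, ix, env), numeric(1))
    names(vals) <- vapply(idxs, function(ix) paste0(prefix, ix[1], ix[2]), character(1))
    vals
  }
  list(c = grab(ex$u, "c"), d = grab(ex$v, "d"),
       eps0 = e0, convention = "series")
}

#' Rotate the shifted map into Neimark-Sacker normal-form coordinates
#'
#' Applies the change of variables \eqn{(u, v)^T = T (X, Y)^T} with
#' \deqn{T = \begin{pmatrix} c_{01} & 0 \\ \alpha_1 - c_{10} & -\alpha_2 \end{pmatrix}}
#' to the cubic Taylor polynomial described by `coeffs`, bringing the linear
#' part to the rotation-scaling \eqn{[[\alpha_1, -\alpha_2], [\alpha_2,
#' \alpha_1]]}.  The nonlinear parts \eqn{\bar F, \bar G} of the transformed
#' map are returned both as series coefficient tables (`e`, `f`) and as the
#' partial derivatives consumed by the discriminant formulas
#' (\eqn{\bar F_{XX} = 2 e_{20}} etc.).
#'
#' @param coeffs Coefficient tables from [taylor_coefficients_e2()] (series
#'   convention).
#' @param alpha1,alpha2 Real and imaginary parts of the critical eigenvalue;
#'   `alpha2` must be nonzero (guaranteed inside the Neimark-Sacker region).
#' @return List with `e`, `f` (named series coefficients `e20`, `e11`, ...),
#'   `partials` (list `FXX`, `FXY`, `FYY`, `FXXX`, `FXXY`, `FXYY`, `FYYY` and
#'   the `G*` analogues), and `linear` (the transformed 2x2 linear part).
#' @export
normal_form_transform <- function(coeffs, alpha1, alpha2) {
  if (!is.list(coeffs) || is.null(coeffs$c) || is.null(coeffs$d))
    stop("'coeffs' must be a list with components 'c' and 'd'", call. = FALSE)
  if (!is.finite(alpha2) || alpha2 == 0)
    stop("alpha2 = 0: eigenvalues are real, not a Neimark-Sacker configuration",
         call. = FALSE)
  cc <- coeffs$c; dd <- coeffs$d
  # cubic Taylor polynomial of the shifted map
  term <- function(prefix, i, j) sprintf("%s%d%d*u^%d*v^%d", prefix, i, j, i, j)
  idxs <- multi_indices(2L, 3L)
  upoly <- paste(vapply(idxs, function(ix) term("c", ix[1], ix[2]), character(1)),
                 collapse = " + ")
  vpoly <- paste(vapply(idxs, function(ix) term("d", ix[1], ix[2]), character(1)),
                 collapse = " + ")
  uexpr <- str2lang(upoly)
  vexpr <- str2lang(vpoly)
  subs <- list(u = quote(c01 * X), v = quote((al1 - c10) * X - al2 * Y))
  uT <- subst_lang(uexpr, subs)
  vT <- subst_lang(vexpr, subs)
  # T^{-1} = [[1/c01, 0], [(al1 - c10)/(c01 al2), -1/al2]]
  Xp <- bquote(.(uT) / c01)
  Yp <- bquote(((al1 - c10) * .(uT) - c01 * .(vT)) / (c01 * al2))
  env <- as.list(c(cc, dd))
  env$al1 <- alpha1; env$al2 <- alpha2
  env$c10 <- cc[["c10"]]; env$c01 <- cc[["c01"]]
  env$X <- 0; env$Y <- 0
  env <- list2env(env)
  vars <- c("X", "Y")
  pa <- function(expr, i, j) partial_at(expr, vars, c(i, j), env)
  partials <- list(
    FXX = pa(Xp, 2L, 0L), FXY = pa(Xp, 1L, 1L), FYY = pa(Xp, 0L, 2L),
    FXXX = pa(Xp, 3L, 0L), FXXY = pa(Xp, 2L, 1L),
    FXYY = pa(Xp, 1L, 2L), FYYY = pa(Xp, 0L, 3L),
    GXX = pa(Yp, 2L, 0L), GXY = pa(Yp, 1L, 1L), GYY = pa(Yp, 0L, 2L),
    GXXX = pa(Yp, 3L, 0L), GXXY = pa(Yp, 2L, 1L),
    GXYY = pa(Yp, 1L, 2L), GYYY = pa(Yp, 0L, 3L))
  linear <- matrix(c(pa(Xp, 1L, 0L), pa(Xp, 0L, 1L),
                     pa(Yp, 1L, 0L), pa(Yp, 0L, 1L)), 2, 2, byrow = TRUE)
  e_tab <- c(e20 = partials$FXX / 2, e11 = partials$FXY, e02 = partials$FYY / 2,
             e30 = partials$FXXX / 6, e21 = partials$FXXY / 2,
             e12 = partials$FXYY / 2, e03 = partials$FYYY / 6)
  f_tab <- c(f20 = partials$GXX / 2, f11 = partials$GXY, f02 = partials$GYY / 2,
             f30 = partials$GXXX / 6, f21 = partials$GXXY / 2,
             f12 = partials$GXYY / 2, f03 = partials$GYYY / 6)
  list(e = e_tab, f = f_tab, partials = partials, linear = linear)
}

# zeta coefficients and discriminant L from the transformed partials.
# zeta_jk is the z^j zbar^k series coefficient of Fbar + i*Gbar in the
# complexified coordinate z = X + iY.
ns_zetas <- function(pt) {
  list(
    zeta20 = complex(real = (pt$FXX - pt$FYY + 2 * pt$GXY) / 8,
                     imaginary = (pt$GXX - pt$GYY - 2 * pt$FXY) / 8),
    zeta11 = complex(real = (pt$FXX + pt$FYY) / 4,
                     imaginary = (pt$GXX + pt$GYY) / 4),
    zeta02 = complex(real = (pt$FXX - pt$FYY - 2 * pt$GXY) / 8,
                     imaginary = (pt$GXX - pt$GYY + 2 * pt$FXY) / 8),
    zeta21 = complex(real = (pt$FXXX + pt$FXYY + pt$GXXY + pt$GYYY) / 16,
                     imaginary = (pt$GXXX + pt$GXYY - pt$FXXY - pt$FYYY) / 16))
}

ns_L_from_zetas <- function(z, lambda1) {
  lambda2 <- Conj(lambda1)
  if (Mod(1 - lambda1) < 1e-12)
    stop("lambda = 1 at criticality: excluded by nondegeneracy", call. = FALSE)
  -Re((1 - 2 * lambda1) * lambda2^2 / (1 - lambda1) * z$zeta20 * z$zeta11) -
    0.5 * Mod(z$zeta11)^2 - Mod(z$zeta02)^2 + Re(lambda2 * z$zeta21)
}

#' Neimark-Sacker normal-form coefficients and discriminant L
#'
#' Runs the full normal-form pipeline at criticality: third-order Taylor
#' expansion of the shifted map at E2 ([taylor_coefficients_e2()]), rotation
#' to normal-form coordinates ([normal_form_transform()]), the complex
#' resonance coefficients
#' \deqn{\zeta_{20}, \zeta_{11}, \zeta_{02}, \zeta_{21}}
#' assembled from the second and third partials of \eqn{\bar F, \bar G}, and
#' the direction discriminant
#' \deqn{L = -\mathrm{Re}\left(\frac{(1-2\lambda_1)\lambda_2^2}{1-\lambda_1}
#'   \zeta_{20}\zeta_{11}\right) - \tfrac12 |\zeta_{11}|^2 - |\zeta_{02}|^2
#'   + \mathrm{Re}(\lambda_2 \zeta_{21}).}
#'
#' @inheritParams taylor_coefficients_e2
#' @return Object of class `sfpp_ns_coefficients`: list with `alpha1`,
#'   `alpha2`, `e_table`, `f_table`, `zeta20`, `zeta11`, `zeta02`, `zeta21`,
#'   `L`.
#' @export
ns_discriminant <- function(p) {
  stopifnot(inherits(p, "sfpp_params"))
  co <- taylor_coefficients_e2(p)
  ep <- eigen_path(p$a, p$delta)
  nf <- normal_form_transform(co, ep$alpha1, ep$alpha2)
  z <- ns_zetas(nf$partials)
  lam1 <- complex(real = ep$alpha1, imaginary = ep$alpha2)
  L <- ns_L_from_zetas(z, lam1)
  structure(c(list(alpha1 = ep$alpha1, alpha2 = ep$alpha2,
                   e_table = nf$e, f_table = nf$f),
              z, list(L = L)),
            class = "sfpp_ns_coefficients")
}

#' Full Neimark-Sacker report at E2
#'
#' Assembles the bifurcation analysis for `(a, delta)` in the Neimark-Sacker
#' region: critical value \eqn{\epsilon_0}, transversality
#' (\eqn{d|\lambda|/d\epsilon^*|_0 = -a\delta(1-\delta)^2/2 \ne 0}),
#' nondegeneracy (no strong resonances), normal-form coefficients, and a
#' direction verdict.
#'
#' Since the modulus derivative is negative, the eigenvalue pair crosses the
#' unit circle *inward* as \eqn{\epsilon} increases through \eqn{\epsilon_0}:
#' E2 is a source for \eqn{\epsilon < \epsilon_0} and a sink above.  With
#' \eqn{L < 0} the bifurcation is supercritical on the unstable side, so the
#' attracting invariant closed curve exists for \eqn{\epsilon < \epsilon_0};
#' with \eqn{L > 0} a repelling curve exists for \eqn{\epsilon > \epsilon_0}.
#' The verdict is resolved from `sign(L)` combined with the crossing
#' direction.  `paper_statement_agrees` records whether this resolved
#' \eqn{\epsilon}-side matches the opposite-side convention sometimes quoted
#' for this family (curve for \eqn{\epsilon > \epsilon_0} when \eqn{L < 0});
#' it is computed, not assumed.
#'
#' @inheritParams epsilon0
#' @param tol_degenerate Scale-aware threshold below which `|L|` is reported
#'   as degenerate.
#' @return Object of class `sfpp_ns_report`.
#' @export
#' @examples
#' rep <- ns_report(16/11, 0.5)
#' rep$coefficients$L    # negative: attracting curve for epsilon < 0.5
ns_report <- function(a, delta, tol_degenerate = NULL) {
  ep <- eigen_path(a, delta)
  if (ep$eps0 <= 0 || ep$eps0 >= 1)
    stop("epsilon0 = ", ep$eps0, " outside (0,1); no admissible crossing",
         call. = FALSE)
  p <- model_params(a, delta, ep$eps0)   # epsilon pinned at criticality
  co <- ns_discriminant(p)
  nd <- nondegeneracy_check(a, delta)
  L <- co$L
  if (is.null(tol_degenerate))
    tol_degenerate <- 1e-10 * (1 + abs(co$zeta20 * co$zeta11))
  verdict <- if (abs(L) <= tol_degenerate) "degenerate"
  else if (L < 0) "supercritical_attracting_curve_for_eps_below"
  else "subcritical_repelling_curve_for_eps_above"
  # opposite-side convention: attracting curve for eps > eps0 when L < 0
  quoted_side <- if (L < 0) "above" else "below"
  resolved_side <- if (L < 0) "below" else "above"
  structure(list(params = p, eps0 = ep$eps0,
                 transversal_ok = ep$modulus_derivative_at_0 != 0,
                 modulus_derivative_at_0 = ep$modulus_derivative_at_0,
                 nondegenerate_ok = all(nd), nondegeneracy = nd,
                 coefficients = co, verdict = verdict,
                 paper_statement_agrees = !is.na(L) && verdict != "degenerate" &&
                   quoted_side == resolved_side),
            class = "sfpp_ns_report")
}

#' @export
print.sfpp_ns_report <- function(x, ...) {
  cat(sprintf("Neimark-Sacker report at E2: a = %.10g, delta = %.10g\n",
              x$params$a, x$params$delta))
  cat(sprintf("  critical epsilon0 = %.10g\n", x$eps0))
  cat(sprintf("  lambda(0) = %.8g %+.8gi (modulus 1)\n",
              x$coefficients$alpha1, x$coefficients$alpha2))
  cat(sprintf("  transversality d|lambda|/deps* = %.8g (ok: %s)\n",
              x$modulus_derivative_at_0, x$transversal_ok))
  cat(sprintf("  nondegeneracy lambda^m != 1, m=1..4: %s\n", x$nondegenerate_ok))
  cat(sprintf("  discriminant L = %.8g\n", x$coefficients$L))
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}
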