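# Transcritical bifurcation at the predator-free equilibrium E1 = (1, 0).
#
# The critical parameter value is delta0 = 1: there the second eigenvalue of
# J(E1) equals exp(epsilon(1 - delta)) = 1, E1 is non-hyperbolic, and the
# coexistence branch E2 collides with E1 (its predator coordinate vanishes as
# delta -> 1-).  The analysis extends the map by the parameter perturbation
# delta* = delta - delta0 treated as a third (frozen) state variable, reduces
# to a one-dimensional center manifold, and checks the transcritical
# conditions on the reduced map.

# quoted expressions for the extended map at E1; variables u, v, d
# (u = x - 1, v = y, d = delta - delta0); free parameters a, eps, delta0
e1_extended_exprs <- function() {
  list(u = quote((u + 1) * exp(-u - a * v / (u + 1 + v)) - 1),
       v = quote(v * exp(eps * ((u + 1) / (u + 1 + v) - d - delta0))))
}

#' Extended map at E1 in shifted coordinates
#'
#' The map in coordinates centred on E1, `u = x - 1`, `v = y`, extended by the
#' frozen parameter perturbation `d = delta - delta0`:
#' \deqn{u' = (u+1)e^{-u - av/(u+1+v)} - 1,\qquad
#'       v' = v\,e^{\epsilon((u+1)/(u+1+v) - d - \delta_0)},\qquad d' = d.}
#'
#' @param u,v Shifted coordinates; requires `u > -1` (so the prey density is
#'   positive) and `u + 1 + v != 0`.
#' @param delta_pert Parameter perturbation `d = delta - delta0`.
#' @param p An [model_params()] object supplying `a` and `epsilon` (its
#'   `delta` is not used; the effective mortality is `delta_pert + delta0`).
#' @param delta0 Critical mortality, fixed at 1 for this model.
#' @return Numeric vector `c(u', v', delta_pert)`.
#' @export
extended_map_e1 <- function(u, v, delta_pert, p, delta0 = 1) {
  stopifnot(inherits(p, "sfpp_params"))
  if (!all(is.finite(c(u, v, delta_pert))))
    stop("non-finite input to extended_map_e1", call. = FALSE)
  if (u <= -1) stop("extended_map_e1 requires u > -1 (positive prey density)",
                    call. = FALSE)
  if (u + 1 + v == 0) stop("u + 1 + v = 0: ratio term undefined", call. = FALSE)
  ex <- e1_extended_exprs()
  env <- list2env(list(a = p$a, eps = p$epsilon, delta0 = delta0,
                       u = u, v = v, d = delta_pert))
  c(eval(ex$u, env), eval(ex$v, env), delta_pert)
}

#' Taylor coefficients of the extended map at E1
#'
#' Series coefficients (partial derivatives divided by factorials) of the
#' extended map around the origin `(u, v, d) = (0, 0, 0)`, computed by exact
#' symbolic differentiation of the map expressions.  At `delta0 = 1` the
#' linear block is `[[0, -a, 0], [0, 1, 0], [0, 0, 1]]`: the unit eigenvalue
#' in the `v` direction confirms criticality.
#'
#' @inheritParams extended_map_e1
#' @param order Maximal total degree (at most 3).
#' @return List with named coefficient vectors `a` (first component) and `b`
#'   (second component); names encode degrees in `(u, v, d)`, e.g. `"010"` is
#'   the linear coefficient of `v`. `convention = "series"` is recorded.
#' @export
taylor_coefficients_e1 <- function(p, delta0 = 1, order = 3) {
  stopifnot(inherits(p, "sfpp_params"))
  if (order > 3) stop("order <= 3 supported", call. = FALSE)
  ex <- e1_extended_exprs()
  env <- list2env(list(a = p$a, eps = p$epsilon, delta0 = delta0,
                       u = 0, v = 0, d = 0))
  vars <- c("u", "v", "d")
  list(a = taylor_series(ex$u, vars, order, env),
       b = taylor_series(ex$v, vars, order, env),
       convention = "series")
}

#' Center-manifold coefficients at E1
#'
#' After the linear change of variables `(u, v, d) = T (X, Y, b)` with
#' `T = [[1, -a, 0], [0, 1, 0], [0, 0, 1]]` (diagonalizing the linear part at
#' criticality, so `X` carries the eigenvalue-0 direction and `Y` the
#' eigenvalue-1 center direction), the local center manifold is the graph
#' \deqn{X = h(Y, b) = h_{20} Y^2 + h_{11} Y b + h_{02} b^2 + O(3).}
#' Matching quadratic terms in the invariance equation
#' `h(Y', b) = X'(h(Y,b), Y, b)` gives the coefficients directly as the
#' quadratic series coefficients of the transformed first component at
#' `X = 0`.  They are computed here symbolically and reported as polynomial
#' (series) coefficients of the manifold graph; for this model
#' `h20 = a - a^2 - a*epsilon`, `h11 = -a*epsilon` and `h02 = 0`.
#'
#' @inheritParams extended_map_e1
#' @return List with `h20`, `h11`, `h02` and `convention = "polynomial"`.
#' @export
center_manifold_e1 <- function(p, delta0 = 1) {
  stopifnot(inherits(p, "sfpp_params"))
  ex <- e1_extended_exprs()
  subs <- list(u = quote(X - a * Y), v = quote(Y), d = quote(b))
  uX <- subst_lang(ex$u, subs)
  vX <- subst_lang(ex$v, subs)
  Xp <- bquote(.(uX) + a * .(vX))       # first row of T^{-1} = [[1, a, 0], ...]
  env <- list2env(list(a = p$a, eps = p$epsilon, delta0 = delta0,
                       X = 0, Y = 0, b = 0))
  vars <- c("X", "Y", "b")
  list(h20 = series_coef(Xp, vars, c(0L, 2L, 0L), env),
       h11 = series_coef(Xp, vars, c(0L, 1L, 1L), env),
       h02 = series_coef(Xp, vars, c(0L, 0L, 2L), env),
       convention = "polynomial")
}

#' Transcritical bifurcation conditions at E1
#'
#' Builds the one-dimensional map restricted to the center manifold,
#' \eqn{f(Y, b) = v'(h(Y,b) - aY,\ Y,\ b)}, by symbolic composition, and
#' evaluates its partial derivatives at the origin.  The transcritical
#' conditions are
#' \deqn{f(0,0) = 0,\quad f_Y = 1,\quad f_b = 0,\quad
#'       f_{Yb} = -\epsilon \ne 0,\quad f_{YY} = -2\epsilon \ne 0,}
#' all holding for every \eqn{\epsilon \in (0,1)}: the predator-free and
#' coexistence branches exchange stability as the mortality crosses
#' \eqn{\delta_0 = 1}.
#'
#' @inheritParams extended_map_e1
#' @param tol Tolerance used for the equality/nonzero condition checks.
#' @return Object of class `sfpp_transcritical`: list with `delta0`, the
#'   center-manifold coefficients `cm`, the reduced-map values `f_value`,
#'   `f_Y`, `f_delta`, `f_YY`, `f_Ydelta`, and `conditions_met`.
#' @export
#' @examples
#' transcritical_conditions(model_params(1.4, 0.5, 0.5))
transcritical_conditions <- function(p, delta0 = 1, tol = 1e-8) {
  stopifnot(inherits(p, "sfpp_params"))
  cm <- center_manifold_e1(p, delta0)
  ex <- e1_extended_exprs()
  # reduced map: v-component with u on the center manifold, v = Y, d = b
  fexpr <- subst_lang(ex$v, list(
    u = bquote((h20 * Y^2 + h11 * Y * b + h02 * b^2) - a * Y),
    v = quote(Y), d = quote(b)))
  env <- list2env(list(a = p$a, eps = p$epsilon, delta0 = delta0,
                       h20 = cm$h20, h11 = cm$h11, h02 = cm$h02,
                       Y = 0, b = 0))
  vars <- c("Y", "b")
  f_value  <- eval(fexpr, env)
  f_Y      <- partial_at(fexpr, vars, c(1L, 0L), env)
  f_delta  <- partial_at(fexpr, vars, c(0L, 1L), env)
  f_YY     <- partial_at(fexpr, vars, c(2L, 0L), env)
  f_Ydelta <- partial_at(fexpr, vars, c(1L, 1L), env)
  conditions_met <- abs(f_value) <= tol && abs(f_Y - 1) <= tol &&
    abs(f_delta) <= tol && abs(f_Ydelta) > tol && abs(f_YY) > tol
  structure(list(delta0 = delta0, cm = cm,
                 f_value = f_value, f_Y = f_Y, f_delta = f_delta,
                 f_YY = f_YY, f_Ydelta = f_Ydelta,
                 conditions_met = conditions_met, tol = tol),
            class = "sfpp_transcritical")
}

#' @export
print.sfpp_transcritical <- function(x, ...) {
  cat("Transcritical bifurcation report at E1 (critical delta0 =", x$delta0, ")\n")
  cat(sprintf("  center manifold (polynomial coeffs): h20 = %.10g, h11 = %.10g, h02 = %.10g\n",
              x$cm$h20, x$cm$h11, x$cm$h02))
  cat(sprintf("  reduced map at origin: f = %.3g, f_Y = %.10g, f_delta = %.3g\n",
              x$f_value, x$f_Y, x$f_delta))
  cat(sprintf("  f_YY = %.10g, f_Ydelta = %.10g\n", x$f_YY, x$f_Ydelta))
  cat("  transcritical conditions met:", x$conditions_met, "\n")
  invisible(x)
}
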