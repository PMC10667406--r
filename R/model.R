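#' One step of the slow-fast predator-prey map
#'
#' Advances a state \eqn{(x, y)} one generation:
#' \deqn{x' = x e^{1 - x - a y/(x+y)}, \qquad
#'       y' = y e^{\epsilon (x/(x+y) - \delta)}.}
#' The map is the exact one-unit-time solution of the fast time-scale
#' continuous system with rates frozen at integer times (piecewise constant
#' arguments), so no step-size parameter appears.
#'
#' At the origin the ratio \eqn{x/(x+y)} is undefined; by the continuity
#' convention adopted here `map_step(c(0, 0), p)` returns `c(0, 0)`, so the
#' extinction equilibrium E0 is representable.
#'
#' @param s Numeric vector `c(x, y)` with nonnegative, finite entries.
#' @param p An [model_params()] object.
#' @return The next state, a numeric vector `c(x, y)`.
#' @export
#' @examples
#' p <- model_params(1.4, 0.5, 0.5)
#' map_step(c(0.6, 0.2), p)   # (0.6 e^{0.05}, 0.2 e^{0.125})
map_step <- function(s, p) {
  stopifnot(inherits(p, "sfpp_params"))
  check_state(s)
  x <- s[[1]]; y <- s[[2]]
  if (x + y == 0) return(c(0, 0))
  rx <- x / (x + y)           # prey share, in [0, 1]
  ry <- y / (x + y)
  out <- c(x * exp(1 - x - p$a * ry),
           y * exp(p$epsilon * (rx - p$delta)))
  if (any(!is.finite(out)))
    stop("map_step produced a non-finite state from (", x, ", ", y, ")",
         call. = FALSE)
  out
}

#' Jacobian matrix of the map at a state
#'
#' Closed-form Jacobian
#' \deqn{J(x,y)=\begin{pmatrix}
#'  (1-x+\frac{axy}{(x+y)^2})\,e^{1-x-\frac{ay}{x+y}} &
#'  -\frac{ax^2}{(x+y)^2}\,e^{1-x-\frac{ay}{x+y}}\\
#'  \frac{\epsilon y^2}{(x+y)^2}\,e^{\epsilon(\frac{x}{x+y}-\delta)} &
#'  (1-\frac{\epsilon xy}{(x+y)^2})\,e^{\epsilon(\frac{x}{x+y}-\delta)}
#' \end{pmatrix}.}
#' The ratio terms are evaluated as shares \eqn{x/(x+y)}, \eqn{y/(x+y)} so the
#' entries stay finite even when one population has decayed to the underflow
#' threshold.  Evaluation at the origin is an error (the shares are undefined
#' there; the saddle character of E0 is established by limit analysis in
#' [classify_fixed_point()]).
#'
#' @inheritParams map_step
#' @return A 2x2 numeric matrix.
#' @export
map_jacobian <- function(s, p) {
  stopifnot(inherits(p, "sfpp_params"))
  check_state(s, allow_origin = FALSE)
  x <- s[[1]]; y <- s[[2]]
  rx <- x / (x + y); ry <- y / (x + y)
  E1 <- exp(1 - x - p$a * ry)
  E2 <- exp(p$epsilon * (rx - p$delta))
  matrix(c((1 - x + p$a * rx * ry) * E1, -p$a * rx^2 * E1,
           p$epsilon * ry^2 * E2,        (1 - p$epsilon * rx * ry) * E2),
         nrow = 2, byrow = TRUE)
}

#' Simplified Jacobian at the coexistence fixed point E2
#'
#' At \eqn{E_2 = (1-a+a\delta,\ (1-a+a\delta)(1-\delta)/\delta)} both
#' exponentials equal one and the Jacobian simplifies to
#' \deqn{J(E_2)=\begin{pmatrix} a(1-\delta^2) & -a\delta^2 \\
#'   \epsilon(1-\delta)^2 & 1-\epsilon\delta(1-\delta)\end{pmatrix},}
#' with trace \eqn{1+(1-\delta)(a(1+\delta)-\epsilon\delta)} and determinant
#' \eqn{a(1-\delta)[1+\delta-\epsilon\delta(1-\delta)]}.
#'
#' @inheritParams map_step
#' @return A 2x2 numeric matrix.
#' @export
jacobian_at_e2 <- function(p) {
  stopifnot(inherits(p, "sfpp_params"))
  if (!e2_exists(p))
    stop("E2 does not exist: requires max(0, (a-1)/a) < delta < 1 ",
         "(a = ", p$a, ", delta = ", p$delta, ")", call. = FALSE)
  a <- p$a; d <- p$delta; e <- p$epsilon
  matrix(c(a * (1 - d^2), -a * d^2,
           e * (1 - d)^2, 1 - e * d * (1 - d)),
         nrow = 2, byrow = TRUE)
}

#' Fixed points of the map
#'
#' Always returns the extinction equilibrium `E0 = (0, 0)` and the
#' predator-free equilibrium `E1 = (1, 0)`.  The coexistence equilibrium
#' \deqn{E_2 = \left(1-a+a\delta,\ \frac{(1-a+a\delta)(1-\delta)}{\delta}\right)}
#' is included iff `max(0, (a-1)/a) < delta < 1`.
#'
#' @inheritParams map_step
#' @return A named list of fixed points; each element is a list with fields
#'   `label` (`"E0"`, `"E1"` or `"E2"`) and `location` (numeric `c(x, y)`).
#' @export
#' @examples
#' fixed_points(model_params(16/11, 0.5, 0.5))$E2$location  # (3/11, 3/11)
fixed_points <- function(p) {
  stopifnot(inherits(p, "sfpp_params"))
  fp <- function(label, loc)
    structure(list(label = label, location = loc), class = "sfpp_fixed_point")
  out <- list(E0 = fp("E0", c(x = 0, y = 0)),
              E1 = fp("E1", c(x = 1, y = 0)))
  if (e2_exists(p)) {
    x0 <- 1 - p$a + p$a * p$delta
    y0 <- x0 * (1 - p$delta) / p$delta
    out$E2 <- fp("E2", c(x = x0, y = y0))
  }
  out
}

#' @export
print.sfpp_fixed_point <- function(x, ...) {
  cat(sprintf("%s = (%.10g, %.10g)\n", x$label, x$location[1], x$location[2]))
  invisible(x)
}
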