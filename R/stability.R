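#' Classify the roots of a quadratic relative to the unit circle
#'
#' Jury/Schur-Cohn-type classification of the roots of
#' \eqn{F(\lambda) = \lambda^2 + B\lambda + C} relative to the unit circle,
#' computed purely from the signs of \eqn{F(1)}, \eqn{F(-1)}, \eqn{C} vs 1 and
#' \eqn{B} vs \eqn{\pm 2} -- never from numerically solved roots.  This is the
#' standard root-location lemma for planar maps: with \eqn{F(\lambda) =
#' \lambda^2 - p\lambda + q} the characteristic polynomial of a Jacobian, take
#' `B = -p`, `C = q`.
#'
#' The case labels are
#' \describe{
#'   \item{both_inside}{\eqn{|\lambda_{1,2}| < 1} (sink when applied to a Jacobian)}
#'   \item{one_on_minus_one}{\eqn{\lambda_1 = -1}, \eqn{\lambda_2 \ne -1}}
#'   \item{split_inside_outside}{one root in \eqn{(-1,1)}, one in \eqn{(-\infty,-1)}}
#'   \item{both_outside}{\eqn{|\lambda_{1,2}| > 1}}
#'   \item{conjugate_on_unit_circle}{complex pair with \eqn{|\lambda_{1,2}| = 1}}
#'   \item{double_minus_one}{\eqn{\lambda_1 = \lambda_2 = -1}}
#'   \item{root_at_one_other_inside / _on / _outside}{\eqn{F(1) = 0}; the
#'     other root is \eqn{C} with \eqn{|C| <, =, > 1}}
#'   \item{one_beyond_one_other_below_minus_one / _at_minus_one / _inside}{%
#'     \eqn{F(1) < 0}: one root in \eqn{(1,\infty)}; the other
#'     \eqn{< -1}, \eqn{= -1}, or in \eqn{(-1,1)}}
#' }
#'
#' Equality cases are measure-zero, so all decisive comparisons use a
#' relative tolerance: a quantity within `tol * max(1, |F(1)|, |F(-1)|, |C|)`
#' of zero is treated as zero, the boundary case label is preferred, and
#' `boundary_flag` is raised.
#'
#' @param B,C Finite real coefficients.
#' @param tol Relative boundary tolerance (default `1e-9`).
#' @return An object of class `sfpp_root_class`: list with `case_label`,
#'   `boundary_flag`, and the decisive quantities `F1`, `Fm1`, `B`, `C`.
#' @export
#' @examples
#' classify_quadratic_roots(0, 0.25)$case_label   # both_inside (roots +-0.5i)
#' classify_quadratic_roots(-3, 2)$case_label     # root_at_one_other_outside
classify_quadratic_roots <- function(B, C, tol = 1e-9) {
  if (!is.finite(B) || !is.finite(C))
    stop("quadratic coefficients must be finite", call. = FALSE)
  F1  <- 1 + B + C
  Fm1 <- 1 - B + C
  scale <- max(1, abs(F1), abs(Fm1), abs(C))
  tl <- tol * scale
  near <- function(v) abs(v) <= tl

  boundary <- near(F1) || near(Fm1) || near(abs(C) - 1) || near(abs(B) - 2)

  label <-
    if (near(F1)) {
      # lambda = 1 is a root; the other root equals C (product of roots)
      if (near(abs(C) - 1)) "root_at_one_other_on"
      else if (abs(C) < 1)  "root_at_one_other_inside"
      else                  "root_at_one_other_outside"
    } else if (F1 > 0) {
      if (near(Fm1)) {
        if (near(B - 2)) "double_minus_one" else "one_on_minus_one"
      } else if (Fm1 < 0) {
        "split_inside_outside"
      } else if (near(C - 1)) {
        "conjugate_on_unit_circle"
      } else if (C < 1) {
        "both_inside"
      } else {
        "both_outside"
      }
    } else {
      if (near(Fm1)) "one_beyond_one_other_at_minus_one"
      else if (Fm1 < 0) "one_beyond_one_other_below_minus_one"
      else "one_beyond_one_other_inside"
    }

  structure(list(case_label = label, boundary_flag = boundary,
                 F1 = F1, Fm1 = Fm1, B = B, C = C),
            class = "sfpp_root_class")
}

#' Critical time-scale ratio for the Neimark-Sacker bifurcation at E2
#'
#' \deqn{\epsilon_0 = \frac{a(1-\delta^2) - 1}{a\,\delta\,(1-\delta)^2}.}
#' At \eqn{\epsilon = \epsilon_0} the Jacobian at E2 has determinant 1
#' (conjugate eigenvalues on the unit circle).  The value is returned raw even
#' outside (0, 1): \eqn{\epsilon_0 \le 0} iff \eqn{\delta^2 \ge (a-1)/a}, and
#' \eqn{\epsilon_0 \ge 1} iff \eqn{\delta \le \delta^*(a)}; callers interpret
#' those sign cases.
#'
#' @param a Positive real predation intensity.
#' @param delta Predator mortality ratio, strictly in (0, 1).
#' @return The critical value \eqn{\epsilon_0} (may be outside (0,1)).
#' @export
#' @examples
#' epsilon0(16/11, 0.5)   # exactly 0.5
#' epsilon0(1.4, 0.5)     # 2/7
epsilon0 <- function(a, delta) {
  if (!is.numeric(a) || a <= 0) stop("'a' must be > 0", call. = FALSE)
  if (!is.numeric(delta) || delta <= 0 || delta >= 1)
    stop("'delta' must lie strictly in (0, 1); epsilon0 divides by delta*(1-delta)^2",
         call. = FALSE)
  (a * (1 - delta^2) - 1) / (a * delta * (1 - delta)^2)
}

#' Critical mortality delta-star separating source and bifurcating regimes
#'
#' For `a > 1`, the unique positive root \eqn{\delta^*} of
#' \deqn{f(\delta) = \delta^3 - \delta^2 + \delta - \frac{a-1}{a}}
#' on \eqn{((a-1)/a, \sqrt{(a-1)/a})}.  Uniqueness holds because
#' \eqn{f'(\delta) = 3\delta^2 - 2\delta + 1 > 0} everywhere.  Located by
#' bracketed root finding ([stats::uniroot()]) and polished with Newton steps
#' until \eqn{|f(\delta^*)| \le} `tol`.
#'
#' @param a Predation intensity, must be > 1.
#' @param tol Residual tolerance on `f` (default `1e-12`).
#' @return The critical mortality \eqn{\delta^*(a)}.
#' @export
delta_star <- function(a, tol = 1e-12) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 1)
    stop("delta_star requires a > 1 (got a = ", a, ")", call. = FALSE)
  cc <- (a - 1) / a
  f <- function(d) d^3 - d^2 + d - cc
  lo <- cc; hi <- sqrt(cc)
  # f(lo) = cc^2 (cc - 1) < 0 and f(hi) = sqrt(cc) (sqrt(cc) - 1)^2 > 0
  root <- stats::uniroot(f, lower = lo, upper = hi, tol = 1e-12)$root
  for (i in 1:50) {                     # Newton polish to residual tolerance
    fv <- f(root)
    if (abs(fv) <= tol) break
    root <- root - fv / (3 * root^2 - 2 * root + 1)
  }
  root
}

#' Critical surfaces for the coexistence fixed point
#'
#' Convenience bundle of the three critical quantities governing the E2
#' stability classification: `epsilon0` (raw, may fall outside (0,1)),
#' `delta_star` and `delta_sqrt = sqrt((a-1)/a)` (both `NA` for `a <= 1`,
#' where E2 is a sink throughout its existence region).
#'
#' @inheritParams epsilon0
#' @return List with `epsilon0`, `delta_star`, `delta_sqrt`.
#' @export
critical_values <- function(a, delta) {
  list(epsilon0 = epsilon0(a, delta),
       delta_star = if (a > 1) delta_star(a) else NA_real_,
       delta_sqrt = if (a > 1) sqrt((a - 1) / a) else NA_real_)
}

#' Stability verdict for a fixed point
#'
#' Applies the model's stability classification:
#' \itemize{
#' \item E0 is always a saddle (limit analysis: the prey direction expands
#'   while the predator factor \eqn{e^{\epsilon(x/(x+y)-\delta)}} contracts
#'   along the invasion path).
#' \item E1 = (1, 0) has eigenvalues \eqn{0} and \eqn{e^{\epsilon(1-\delta)}}:
#'   a saddle for \eqn{\delta < 1}, non-hyperbolic at \eqn{\delta = 1}, a
#'   stable node for \eqn{\delta > 1}.
#' \item E2 is classified through the determinant identity
#'   \eqn{q \gtrless 1 \iff \epsilon \lessgtr \epsilon_0}: a source for
#'   \eqn{\epsilon < \epsilon_0}, non-hyperbolic at \eqn{\epsilon =
#'   \epsilon_0}, a sink for \eqn{\epsilon > \epsilon_0} (which subsumes the
#'   sink cases \eqn{a \le 1} and \eqn{\delta \ge \sqrt{(a-1)/a}}, where
#'   \eqn{\epsilon_0 \le 0}, and the source case \eqn{\delta \le \delta^*},
#'   where \eqn{\epsilon_0 \ge 1}).
#' }
#'
#' @param fp A fixed point as returned by [fixed_points()].
#' @param p An [model_params()] object.
#' @param tol Boundary tolerance for the non-hyperbolic comparisons.
#' @return List with `label` (one of `sink`, `source`, `saddle`,
#'   `stable_node`, `non_hyperbolic`), a human-readable `rationale`, and
#'   `boundary_flag` (TRUE when a decisive comparison was within `tol`).
#' @export
classify_fixed_point <- function(fp, p, tol = 1e-9) {
  stopifnot(inherits(p, "sfpp_params"))
  if (!is.list(fp) || is.null(fp$label))
    stop("'fp' must be a fixed point from fixed_points()", call. = FALSE)
  verdict <- function(label, rationale, boundary = FALSE)
    list(label = label, rationale = rationale, boundary_flag = boundary)

  switch(fp$label,
    E0 = verdict("saddle",
                 "E0: saddle for all admissible parameters (prey axis expands, predator share decays)"),
    E1 = {
      d <- p$delta
      if (abs(d - 1) <= tol)
        verdict("non_hyperbolic",
                "E1: second eigenvalue exp(epsilon(1-delta)) = 1 at delta = 1",
                boundary = TRUE)
      else if (d < 1)
        verdict("saddle", "E1: eigenvalues 0 and exp(epsilon(1-delta)) > 1 for delta < 1")
      else
        verdict("stable_node", "E1: eigenvalues 0 and exp(epsilon(1-delta)) < 1 for delta > 1")
    },
    E2 = {
      if (!e2_exists(p))
        stop("E2 does not exist for a = ", p$a, ", delta = ", p$delta,
             " (requires max(0, (a-1)/a) < delta < 1)", call. = FALSE)
      e0 <- epsilon0(p$a, p$delta)
      boundary <- abs(p$epsilon - e0) <= tol
      if (boundary)
        verdict("non_hyperbolic",
                sprintf("E2: epsilon = epsilon0 = %.10g, det J(E2) = 1 (conjugate pair on unit circle)", e0),
                boundary = TRUE)
      else if (p$epsilon < e0)
        verdict("source",
                sprintf("E2: epsilon < epsilon0 = %.10g so q = det J(E2) > 1 and both eigenvalue moduli exceed 1", e0))
      else
        verdict("sink",
                sprintf("E2: epsilon > epsilon0 = %.10g so q = det J(E2) < 1 (includes epsilon0 <= 0 cases a <= 1, delta >= sqrt((a-1)/a))", e0))
    },
    stop("unknown fixed point label: ", fp$label, call. = FALSE)
  )
}
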