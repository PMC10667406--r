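#' Parameters of the discrete slow-fast predator-prey map
#'
#' Bundles the parameter triple of the map
#' \deqn{x_{n+1} = x_n e^{1 - x_n - a y_n/(x_n+y_n)}, \qquad
#'       y_{n+1} = y_n e^{\epsilon (x_n/(x_n+y_n) - \delta)},}
#' validating admissibility at construction.
#'
#' @param a Positive real. Predation intensity (dimensionless).
#' @param delta Positive real. Predator mortality relative to its maximal
#'   growth rate (dimensionless).
#' @param epsilon Real in (0, 1). Fast/slow time-scale ratio: the predator's
#'   intrinsic rate relative to the prey's.
#'
#' @return An object of class `sfpp_params`: a list with elements `a`,
#'   `delta`, `epsilon`.
#' @seealso [e2_exists()], [in_ns_region()], [map_step()]
#' @export
#' @examples
#' p <- model_params(a = 16/11, delta = 0.5, epsilon = 0.45)
#' e2_exists(p)
#' in_ns_region(p)
model_params <- function(a, delta, epsilon) {
  for (nm in c("a", "delta", "epsilon")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
  }
  if (a <= 0) stop("parameter 'a' must be > 0, got ", a, call. = FALSE)
  if (delta <= 0) stop("parameter 'delta' must be > 0, got ", delta, call. = FALSE)
  if (epsilon <= 0 || epsilon >= 1)
    stop("parameter 'epsilon' must lie strictly in (0, 1), got ", epsilon,
         call. = FALSE)
  structure(list(a = a, delta = delta, epsilon = epsilon),
            class = "sfpp_params")
}

#' Does the coexistence fixed point E2 exist?
#'
#' E2 exists (with positive coordinates) iff
#' `max(0, (a-1)/a) < delta < 1`.
#'
#' @param p An [model_params()] object.
#' @return Logical scalar.
#' @export
e2_exists <- function(p) {
  stopifnot(inherits(p, "sfpp_params"))
  lo <- max(0, (p$a - 1) / p$a)
  p$delta > lo && p$delta < 1
}

#' Is the parameter point inside the Neimark-Sacker region?
#'
#' The Neimark-Sacker analysis at E2 applies on
#' \eqn{S_{E_+} = \{a > 1,\ \delta^*(a) < \delta < \sqrt{(a-1)/a},\
#' 0 < \epsilon < 1\}}, where \eqn{\delta^*(a)} is the unique positive root of
#' \eqn{\delta^3 - \delta^2 + \delta - (a-1)/a} (see [delta_star()]).
#'
#' @inheritParams e2_exists
#' @return Logical scalar.
#' @export
in_ns_region <- function(p) {
  stopifnot(inherits(p, "sfpp_params"))
  if (p$a <= 1) return(FALSE)
  p$delta > delta_star(p$a) && p$delta < sqrt((p$a - 1) / p$a)
}

#' @export
print.sfpp_params <- function(x, ...) {
  cat(sprintf("slow-fast predator-prey map parameters: a = %g, delta = %g, epsilon = %g\n",
              x$a, x$delta, x$epsilon))
  cat(sprintf("  E2 exists: %s;  in Neimark-Sacker region: %s\n",
              e2_exists(x), in_ns_region(x)))
  invisible(x)
}

# internal: validate a state vector
check_state <- function(s, allow_origin = TRUE) {
  if (!is.numeric(s) || length(s) != 2L)
    stop("state must be a numeric vector (x, y)", call. = FALSE)
  if (any(!is.finite(s)))
    stop("invalid state: non-finite coordinates (", s[1], ", ", s[2], ")",
         call. = FALSE)
  if (any(s < 0))
    stop("invalid state: densities must be nonnegative, got (",
         s[1], ", ", s[2], ")", call. = FALSE)
  if (!allow_origin && s[1] + s[2] == 0)
    stop("state (0, 0) not allowed here: ratio terms x/(x+y) are undefined",
         call. = FALSE)
  invisible(s)
}
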