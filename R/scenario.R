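# Scenario configuration (YAML/JSON), validation, and the assembled
# analysis report.

SCENARIO_KEYS <- c("name", "params", "initial_states", "sweep", "output")
PARAM_KEYS <- c("a", "delta", "epsilon")
SWEEP_KEYS <- c("eps_lo", "eps_hi", "n_eps")

#' Load and validate a scenario file
#'
#' Scenarios bundle the parameter triple, initial states and sweep ranges
#' for a numerical experiment.  JSON and YAML dialects are accepted
#' (selected by file extension).  Unknown keys are rejected by name;
#' omitted `initial_states` default to `(0.6, 0.2)` (logged to stderr).
#' `epsilon` may be omitted for purely analytical use (critical values,
#' Neimark-Sacker report), since those pin epsilon themselves.
#'
#' Two scenarios ship with the package under
#' `system.file("extdata", "scenarios", package = "slowfastpp")`:
#' `fig1_canonical.yaml` (a = 16/11, so epsilon0 = 0.5 exactly and
#' E2 = (3/11, 3/11)) and `fig1_literal.yaml` (a = 1.4, epsilon0 = 2/7).
#' The two readings of the predation intensity are mutually inconsistent in
#' the originating simulation study, so both ship.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Object of class `sfpp_scenario`.
#' @export
#' @examples
#' sc <- load_scenario(system.file("extdata", "scenarios",
#'                                 "fig1_canonical.yaml",
#'                                 package = "slowfastpp"))
#' sc$params$a * (1 - sc$params$delta)   # 1 - E2 abscissa
load_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE, simplifyMatrix = FALSE),
    stop("unsupported scenario format '.", ext, "' (use .yaml, .yml or .json)",
         call. = FALSE))
  validate_scenario(raw, path)
}

validate_scenario <- function(raw, path = "<in-memory>") {
  if (!is.list(raw)) stop("scenario must be a mapping/object", call. = FALSE)
  bad <- setdiff(names(raw), SCENARIO_KEYS)
  if (length(bad))
    stop("scenario '", path, "': unknown key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(raw$params)) stop("scenario missing 'params'", call. = FALSE)
  badp <- setdiff(names(raw$params), PARAM_KEYS)
  if (length(badp))
    stop("scenario params: unknown key(s): ", paste(badp, collapse = ", "),
         call. = FALSE)
  pr <- raw$params
  for (nm in c("a", "delta"))
    if (is.null(pr[[nm]]) || !is.numeric(pr[[nm]]))
      stop("scenario params: '", nm, "' missing or not numeric", call. = FALSE)
  if (pr$a <= 0) stop("scenario params: a must be > 0", call. = FALSE)
  if (pr$delta <= 0) stop("scenario params: delta must be > 0", call. = FALSE)
  if (!is.null(pr$epsilon) && (pr$epsilon <= 0 || pr$epsilon >= 1))
    stop("scenario params: epsilon must lie strictly in (0, 1), got ",
         pr$epsilon, call. = FALSE)
  inits <- raw$initial_states
  if (is.null(inits)) {
    message("scenario '", raw$name %||% path, "': no initial_states; ",
            "defaulting to (0.6, 0.2)")
    inits <- list(c(0.6, 0.2))
  }
  inits <- lapply(inits, function(s) {
    s <- as.numeric(unlist(s))
    if (length(s) != 2L || any(!is.finite(s)) || any(s < 0))
      stop("scenario initial_states: each entry must be a nonnegative pair",
           call. = FALSE)
    s
  })
  sw <- raw$sweep
  if (!is.null(sw)) {
    bads <- setdiff(names(sw), SWEEP_KEYS)
    if (length(bads))
      stop("scenario sweep: unknown key(s): ", paste(bads, collapse = ", "),
           call. = FALSE)
    if (!(is.numeric(sw$eps_lo) && is.numeric(sw$eps_hi) &&
          sw$eps_lo > 0 && sw$eps_lo < sw$eps_hi && sw$eps_hi < 1))
      stop("scenario sweep: need 0 < eps_lo < eps_hi < 1", call. = FALSE)
    if (is.null(sw$n_eps)) sw$n_eps <- 500L
  }
  structure(list(name = raw$name %||% basename(path),
                 params = list(a = pr$a, delta = pr$delta,
                               epsilon = pr$epsilon),
                 initial_states = inits, sweep = sw,
                 output = raw$output),
            class = "sfpp_scenario")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a scenario back to disk
#'
#' Inverse of [load_scenario()]; the dialect follows the file extension.
#' `load -> write -> load` is the identity on all scenario fields.
#'
#' @param scenario An `sfpp_scenario`.
#' @param path Destination (`.yaml`, `.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "sfpp_scenario"))
  x <- list(name = scenario$name,
            params = Filter(Negate(is.null), scenario$params),
            initial_states = scenario$initial_states)
  if (!is.null(scenario$sweep)) x$sweep <- scenario$sweep
  if (!is.null(scenario$output)) x$output <- scenario$output
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = , yml = yaml::write_yaml(x, path, precision = 17L),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA),
    stop("unsupported scenario format '.", ext, "'", call. = FALSE))
  invisible(path)
}

#' Run the full analysis suite for a scenario
#'
#' Orchestrates fixed points and their stability verdicts, the critical
#' surfaces, the transcritical report at E1, and (when `(a, delta)` lies in
#' the Neimark-Sacker region) the normal-form report at E2.  Sub-analysis
#' errors are collected per section as `error` fields; the run continues.
#' The report embeds the full effective configuration so every result is
#' reproducible from the report alone.
#'
#' @param scenario An `sfpp_scenario` from [load_scenario()], or a path.
#' @return Object of class `sfpp_analysis` (nested list, JSON-serializable
#'   via [analysis_to_json()]).
#' @export
analyze <- function(scenario) {
  if (is.character(scenario)) scenario <- load_scenario(scenario)
  stopifnot(inherits(scenario, "sfpp_scenario"))
  a <- scenario$params$a; delta <- scenario$params$delta
  eps <- scenario$params$epsilon
  section <- function(f) tryCatch(f, error = function(e) list(error = conditionMessage(e)))

  # a representative epsilon is needed for verdicts; prefer the scenario's
  eps_eff <- eps %||% 0.5
  p <- tryCatch(model_params(a, delta, eps_eff), error = function(e) NULL)

  fps <- section({
    stopifnot(!is.null(p))
    lapply(fixed_points(p), function(fp) {
      v <- section(classify_fixed_point(fp, p))
      list(label = fp$label, location = unname(fp$location),
           verdict = v$label %||% NULL, rationale = v$rationale %||% v$error)
    })
  })
  crit <- section(critical_values(a, delta))
  tc <- section({
    stopifnot(!is.null(p))
    r <- transcritical_conditions(p)
    list(delta0 = r$delta0,
         center_manifold = r$cm[c("h20", "h11", "h02")],
         f_value = r$f_value, f_Y = r$f_Y, f_delta = r$f_delta,
         f_YY = r$f_YY, f_Ydelta = r$f_Ydelta,
         conditions_met = r$conditions_met)
  })
  ns <- if (a > 1 && tryCatch(in_ns_region(model_params(a, delta, 0.5)),
                              error = function(e) FALSE)) {
    section({
      r <- ns_report(a, delta)
      list(eps0 = r$eps0,
           lambda0 = list(re = r$coefficients$alpha1,
                          im = r$coefficients$alpha2),
           modulus_derivative = r$modulus_derivative_at_0,
           transversal_ok = r$transversal_ok,
           nondegenerate_ok = r$nondegenerate_ok,
           L = r$coefficients$L, verdict = r$verdict,
           paper_statement_agrees = r$paper_statement_agrees)
    })
  } else {
    reason <- if (a <= 1) "a <= 1"
    else "delta outside (delta_star(a), sqrt((a-1)/a))"
    list(skipped = reason)
  }
  structure(list(name = scenario$name,
                 configuration = list(params = scenario$params,
                                      initial_states = scenario$initial_states,
                                      sweep = scenario$sweep),
                 fixed_points = fps, critical_values = crit,
                 transcritical = tc, neimark_sacker = ns,
                 provenance = list(
                   package = "slowfastpp",
                   version = as.character(utils::packageVersion("slowfastpp")),
                   r_version = as.character(getRversion()))),
            class = "sfpp_analysis")
}

# recursively make a structure JSON-friendly (complex -> {re, im})
json_ready <- function(x) {
  if (is.complex(x)) {
    if (length(x) == 1L) return(list(re = Re(x), im = Im(x)))
    return(lapply(as.list(x), function(z) list(re = Re(z), im = Im(z))))
  }
  if (is.list(x)) return(lapply(x, json_ready))
  x
}

#' Serialize an analysis report to JSON
#'
#' Complex numbers are emitted as `{re, im}` objects; numeric precision is
#' preserved.
#'
#' @param report An `sfpp_analysis` (or any report list).
#' @param path Optional file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when written to `path`).
#' @export
analysis_to_json <- function(report, path = NULL) {
  x <- json_ready(unclass(report))
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
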