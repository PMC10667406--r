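# Exact symbolic Taylor-coefficient machinery.
#
# All series coefficients used by the bifurcation modules are obtained by
# repeated application of base R's symbolic derivative `D()` to quoted map
# expressions, evaluated at the expansion point.  Nothing is transcribed from
# printed coefficient tables; the closed forms only ever appear in tests as
# oracles.

# Substitute symbols in a language object (used to compose maps with linear
# or polynomial changes of variables before differentiating).
subst_lang <- function(expr, subs) {
  if (is.symbol(expr)) {
    nm <- as.character(expr)
    if (nm %in% names(subs)) return(subs[[nm]])
    return(expr)
  }
  if (is.call(expr)) {
    for (i in seq_along(expr)[-1]) expr[[i]] <- subst_lang(expr[[i]], subs)
    return(expr)
  }
  expr
}

# Mixed partial derivative: differentiate `expr` idx[k] times w.r.t. vars[k].
dmulti <- function(expr, vars, idx) {
  for (k in seq_along(vars)) {
    if (idx[k] > 0) for (i in seq_len(idx[k])) expr <- stats::D(expr, vars[k])
  }
  expr
}

# Unnormalized partial derivative value at the point described by `env`.
partial_at <- function(expr, vars, idx, env) {
  eval(dmulti(expr, vars, idx), env)
}

# Taylor *series* coefficient (partial derivative divided by factorials).
series_coef <- function(expr, vars, idx, env) {
  partial_at(expr, vars, idx, env) / prod(factorial(idx))
}

# All multi-indices of `k` variables with total degree in [min_deg, max_deg].
multi_indices <- function(k, max_deg, min_deg = 1L) {
  grid <- do.call(expand.grid, rep(list(0:max_deg), k))
  deg <- rowSums(grid)
  grid <- grid[deg >= min_deg & deg <= max_deg, , drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
}

# Named vector of series coefficients of `expr` in `vars` around the point in
# `env`, with names like "210" (degrees per variable, in order).
taylor_series <- function(expr, vars, order, env, min_deg = 1L) {
  idxs <- multi_indices(length(vars), order, min_deg)
  vals <- vapply(idxs, function(ix) series_coef(expr, vars, ix, env), numeric(1))
  names(vals) <- vapply(idxs, paste, character(1), collapse = "")
  vals
}
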