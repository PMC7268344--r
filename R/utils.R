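#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed conditions so callers can distinguish failure modes.
# Classes used throughout: io, validation, format, degenerate_colony,
# alignment, interpolation.
cp_abort <- function(message, class) {
  stop(structure(
    list(message = message, call = NULL),
    class = c(paste0("colonyprof_", class, "_error"), "colonyprof_error",
              "error", "condition")
  ))
}

cp_warn <- function(message) {
  warning(structure(
    list(message = message, call = NULL),
    class = c("colonyprof_warning", "warning", "condition")
  ))
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    cp_abort(sprintf("`%s` must be a single positive finite number", name),
             "validation")
}
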