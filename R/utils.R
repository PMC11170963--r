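# Internal helpers shared across modules.

# Run code with a fixed RNG seed, restoring the caller's RNG state on exit.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

# Format numbers so that write -> read round-trips exactly in double precision.
format_repr <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
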