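`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `expr` under set.seed(seed) without disturbing the caller's RNG
# stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

msg <- function(..., verbose = getOption("mlrldacp.verbose", FALSE)) {
  if (isTRUE(verbose)) message(...)
  invisible(NULL)
}

stop_input <- function(...) stop(..., call. = FALSE)
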