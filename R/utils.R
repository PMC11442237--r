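`%||%` <- function(x, y) if (is.null(x)) y else x

# run code under a temporary RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

stop_hat <- function(msg, class) {
  stop(structure(class = c(class, "hatcat_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
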