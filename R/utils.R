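`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a local RNG state; the caller's stream is untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_stage <- function(stage, e) {
  stop(sprintf("stage '%s': %s", stage, conditionMessage(e)), call. = FALSE)
}
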