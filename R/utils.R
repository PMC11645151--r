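# run code under a temporary RNG seed, restoring the caller's RNG state;
# seed = NULL runs unseeded (generators refuse this, see gen_* functions)
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

require_seed <- function(seed) {
  if (is.null(seed) || !is.finite(seed))
    stop("an explicit integer seed is required for stochastic generation")
  as.integer(seed)
}
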