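# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a temporary RNG state; the global .Random.seed is restored
# afterwards so seeded generators behave as pure functions of (args, seed).
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-stage seed from a master seed; kept below 2^31 - 1.
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L)
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + offs) %% 2147483629)
}
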