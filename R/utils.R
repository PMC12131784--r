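# Internal RNG helpers.

# Run expr under a temporary RNG state seeded with `seed`; the caller's
# global RNG state is untouched. seed = NULL runs expr with the current RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic child seed from a master seed and a few integer tags, kept
# inside the 32-bit signed range. Used so that every (procedure, k, fold)
# combination gets its own reproducible stream.
child_seed <- function(master, ...) {
  tags <- c(...)
  s <- as.double(master) %% 2147483647
  for (t in tags) s <- (s * 48271 + as.double(t) * 8191 + 1) %% 2147483647
  as.integer(s)
}
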