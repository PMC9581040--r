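## Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
## the caller's stream afterwards. Used by the common-random-number fitting
## objectives so repeated evaluations inside an optimizer neither perturb
## nor are perturbed by the optimizer's own randomness.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
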