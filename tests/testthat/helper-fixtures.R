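# Shared fixtures, built in code.

# A small, fast law table: short phases so populations cycle within a few
# simulated hours.
fastLaws <- function() {
  phaseLawTable(
    location = rbind(G1 = c(2, 2), S = c(3, 3), G2 = c(1.5, 1.5),
                     M = c(1, 1)),
    scale = rbind(G1 = c(0.3, 0.3), S = c(0.4, 0.4), G2 = c(0.1, 0.1),
                  M = c(0.1, 0.1)))
}

# Laws whose support starts far beyond any simulated horizon: no cell can
# ever transition.
frozenLaws <- function(mu = 1e5) {
  phaseLawTable(location = matrix(mu, 4, 2), scale = matrix(1, 4, 2))
}

# An asynchronous two-round starting table.
mixedCpf0 <- function() {
  cpfTable(0, c("G1", "S", "G2", "M", "G1", "S"), c(0L, 0L, 0L, 0L, 1L, 1L),
           c(30, 25, 10, 5, 20, 10))
}

randomCpfTable <- function(time = 0, nBuckets = 6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  keys <- expand.grid(phase = CYCLE_PHASES, round = 0:3,
                      stringsAsFactors = FALSE)
  keys <- keys[sample(nrow(keys), nBuckets), ]
  p <- runif(nBuckets)
  cpfTable(time, keys$phase, keys$round, 100 * p / sum(p))
}

# Noise-free "experimental" cpF produced exactly the way the untreated
# objective re-simulates it (same seed handling), so the objective at the
# generating parameters under the same seed is exactly zero.
makeUntreatedExp <- function(v, cpf0, sched, simSeed, nCells,
                             initTimeMax = 25) {
  set.seed(simSeed)
  pop <- initializePopulation(cpf0, nCells = nCells,
                              initTimeMax = initTimeMax)
  sim <- simulatePopulation(pop, expandTied(v), sched = sched)
  sim@cpf
}
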