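## Synthetic cpF datasets with known ground truth, emulating the
## experimental design: an asynchronous Jurkat-like population observed at
## 0/32/48/72 h untreated, or with a drug added at 32 h and re-measured at
## 48 h, with up to 14% relative measurement error per cpF entry.

#' Reference residence-time law table for untreated Jurkat populations
#'
#' The replicate-averaged laws estimated from untreated Jurkat cpF data:
#' G1 7.11/0.18 h (round 0) and 14.76/2.33 h (rounds >= 1); S 14.76/0.37 h
#' and 8.14/3.91 h; G2 4.84 h and M 1.69 h for all rounds with scale fixed
#' at 0.1 h; shape 0.68 everywhere. The implied intermitotic time is
#' 28.40 h for division round 0 and 29.43 h for later rounds. The round-0
#' values absorb the arbitrary random initialization of times-in-phase and
#' should not be read as biology; the rounds->=1 values are the steady-state
#' interphase times.
#'
#' @return A [PhaseLawTable-class].
#' @examples
#' intermitoticTime(referenceLaws(), 1)
#' @export
referenceLaws <- function() {
  expandTied(c(7.11, 14.76, 14.76, 8.14, 4.84, 1.69,
               0.18, 2.33, 0.37, 3.91))
}

#' Default initial cpF for synthetic experiments
#'
#' An asynchronous starting population: all mass in division round 0,
#' spread over the four phases in proportion to their round-0 residence
#' locations (so phases in which cells spend longer hold more cells), as a
#' stand-in for an unprinted experimental time-0 measurement. Fully
#' overridable wherever it is used.
#'
#' @param laws Law table whose round-0 locations set the proportions;
#'   default [referenceLaws()].
#' @return A [CpfTable-class] at time 0.
#' @export
defaultCpf0 <- function(laws = referenceLaws()) {
  w <- laws@location[, "round0"]
  cpfTable(0, CYCLE_PHASES, 0L, 100 * w / sum(w))
}

#' Apply multiplicative measurement noise to a cpF table
#'
#' Each entry is multiplied by `1 + e` with `e ~ Normal(0, noisePct/100)`
#' independently per (time, phase, round) entry, truncated below at 0, and
#' the table is renormalized to sum to 100 at each time point. The default
#' experimental error assumption is a pessimistic uniform 14% relative
#' error for every phase.
#'
#' @param cpf A [CpfTable-class].
#' @param noisePct Relative standard deviation in percent (>= 0).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return A [CpfTable-class].
#' @export
addNoise <- function(cpf, noisePct = 14, seed = NULL) {
  stopifnot(is(cpf, "CpfTable"), noisePct >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (noisePct == 0) return(cpf)
  d <- cpfData(cpf)
  val <- pmax(0, d$cpf_percent * (1 + stats::rnorm(nrow(d), 0,
                                                   noisePct / 100)))
  out <- do.call(rbind, lapply(split(seq_len(nrow(d)), d$time_h), function(i) {
    di <- d[i, , drop = FALSE]
    di$cpf_percent <- 100 * val[i] / sum(val[i])
    di
  }))
  cpfTable(out$time_h, out$phase, out$division_round, out$cpf_percent)
}

#' Generate a synthetic untreated cpF dataset
#'
#' Simulates a population from known laws with no blocking, records cpF at
#' the schedule's observation times (by default 0, 32, 48 and 72 h) and
#' applies measurement noise. Regeneration with the same arguments and seed
#' is bit-identical.
#'
#' @param laws Ground-truth [PhaseLawTable-class]; default [referenceLaws()].
#' @param cpf0 Initial cpF; default [defaultCpf0()] of `laws`.
#' @param sched Simulation [Schedule-class].
#' @param nCells Cells to simulate; default 20000.
#' @param noisePct Relative measurement noise in percent; default 14. Use 0
#'   for noise-free recovery studies.
#' @param initTimeMax Upper bound of the initial time-in-phase draw.
#' @param seed Integer seed.
#' @return A [SyntheticExperiment-class].
#' @export
generateUntreatedDataset <- function(laws = referenceLaws(),
                                     cpf0 = defaultCpf0(laws),
                                     sched = schedule(), nCells = 20000,
                                     noisePct = 14, initTimeMax = 25,
                                     seed = 1) {
  stopifnot(is(laws, "PhaseLawTable"), is(cpf0, "CpfTable"))
  set.seed(seed)
  pop <- initializePopulation(cpf0, nCells = nCells,
                              initTimeMax = initTimeMax)
  sim <- simulatePopulation(pop, laws, blocking = NULL, sched = sched)
  obs <- addNoise(sim@cpf, noisePct)
  new("SyntheticExperiment", truthLaws = laws, truthBlocking = NULL,
      cpf0 = cpf0, observations = obs, noisePct = as.numeric(noisePct),
      seed = as.integer(seed))
}

#' Generate a synthetic drug-treated cpF dataset
#'
#' Simulates a population from known laws with a known blocking policy that
#' takes effect at the drug-addition time, records cpF at the drug time and
#' at the post-treatment observation time (by default 32 and 48 h), and
#' applies measurement noise. With all blocking probabilities 0 the
#' simulated trajectory is draw-for-draw identical to the untreated
#' generator at the same seed.
#'
#' @param laws Ground-truth [PhaseLawTable-class].
#' @param truthBlocking Ground-truth blocking probabilities: a
#'   [BlockingPolicy-class] or a numeric vector of four probabilities.
#' @param cpf0 Initial cpF; default [defaultCpf0()] of `laws`.
#' @param drugTime Drug-addition time in hours; default 32 (overrides the
#'   policy's slot when a bare vector is given).
#' @param observationTime Post-treatment observation in hours; default 48.
#' @param dT Step length in hours; default 0.36.
#' @inheritParams generateUntreatedDataset
#' @return A [SyntheticExperiment-class].
#' @export
generateTreatedDataset <- function(laws = referenceLaws(), truthBlocking,
                                   cpf0 = defaultCpf0(laws), drugTime = 32,
                                   observationTime = 48, dT = 0.36,
                                   nCells = 20000, noisePct = 14,
                                   initTimeMax = 25, seed = 1) {
  stopifnot(is(laws, "PhaseLawTable"), is(cpf0, "CpfTable"))
  if (!is(truthBlocking, "BlockingPolicy"))
    truthBlocking <- blockingPolicy(truthBlocking, drugTime)
  validObject(truthBlocking)
  sched <- schedule(dT = dT, tEnd = observationTime,
                    observationTimes = c(truthBlocking@drugTime,
                                         observationTime))
  set.seed(seed)
  pop <- initializePopulation(cpf0, nCells = nCells,
                              initTimeMax = initTimeMax)
  sim <- simulatePopulation(pop, laws, blocking = truthBlocking,
                            sched = sched)
  obs <- addNoise(sim@cpf, noisePct)
  new("SyntheticExperiment", truthLaws = laws, truthBlocking = truthBlocking,
      cpf0 = cpf0, observations = obs, noisePct = as.numeric(noisePct),
      seed = as.integer(seed))
}
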