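## Initialization, advancement and simulation of the agent-based ensemble.

#' Cyclic successor of a cell-cycle phase
#'
#' @param phase Character vector of phase labels (`"G1"`, `"S"`, `"G2"`,
#'   `"M"`).
#' @return The next phase in the cycle G1 -> S -> G2 -> M -> G1.
#' @examples
#' nextPhase("M")  # "G1"
#' @export
nextPhase <- function(phase) {
  idx <- match(phase, CYCLE_PHASES)
  if (anyNA(idx))
    stop("unknown phase label(s): ",
         paste(unique(phase[is.na(idx)]), collapse = ", "))
  CYCLE_PHASES[idx %% 4L + 1L]
}

## Largest-remainder apportionment of `total` units over quotas q >= 0.
largestRemainder <- function(q, total) {
  base <- floor(q)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(q - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Initialize an in-silico population from an observed cpF
#'
#' Allocates `nCells` cells over (phase, division round) buckets so that the
#' population's cpF matches `cpf0`: target counts are proportional to
#' `cpf_percent * 2^round` (undoing the precursor normalisation) and are
#' rounded to integers by largest-remainder apportionment, which keeps every
#' bucket within one cell of its exact quota. The time each cell has already
#' spent in its phase cannot be observed, so it is drawn uniformly from
#' `[0, initTimeMax]`; the default 25 h equals the upper bound placed on the
#' location parameters during fitting. Optionally a random subset of each
#' bucket is flagged arrested (cells that never transition for the whole
#' experiment).
#'
#' @param cpf0 A [CpfTable-class] at a single time point; percentages must
#'   sum to 100.
#' @param nCells Number of cells to create (default 20000).
#' @param initTimeMax Upper bound of the uniform time-in-phase draw (hours).
#' @param arrestedFractions `NULL` for none, or a `data.frame` with columns
#'   `phase`, `division_round`, `fraction` giving, per bucket, the fraction
#'   of its cells to arrest (each in `[0, 1]`).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return A [CellPopulation-class] with clock set to the `cpf0` time.
#' @examples
#' pop <- initializePopulation(cpfTable(0, c("G1", "S"), 0L, c(50, 50)),
#'                             nCells = 10, seed = 1)
#' table(CYCLE_PHASES[pop@phase])
#' @export
initializePopulation <- function(cpf0, nCells = 20000, initTimeMax = 25,
                                 arrestedFractions = NULL, seed = NULL) {
  stopifnot(is(cpf0, "CpfTable"))
  validObject(cpf0)
  d <- cpf0@data
  if (length(unique(d$time_h)) != 1L)
    stop("'cpf0' must contain a single time point")
  if (nCells < 1) stop("'nCells' must be at least 1")
  if (initTimeMax <= 0) stop("'initTimeMax' must be positive")
  if (!is.null(seed)) set.seed(seed)

  quota <- d$cpf_percent * 2^d$division_round
  quota <- nCells * quota / sum(quota)
  counts <- largestRemainder(quota, nCells)
  empty <- counts == 0L & d$cpf_percent > 0
  if (any(empty))
    warning(sprintf(
      "%d non-empty cpF bucket(s) received 0 cells at nCells = %d",
      sum(empty), nCells))

  phase <- rep(match(d$phase, CYCLE_PHASES), counts)
  round <- rep(d$division_round, counts)
  tt <- stats::runif(sum(counts), 0, initTimeMax)
  arrested <- rep(FALSE, sum(counts))

  if (!is.null(arrestedFractions)) {
    af <- arrestedFractions
    if (!all(c("phase", "division_round", "fraction") %in% names(af)))
      stop("'arrestedFractions' needs columns phase, division_round, fraction")
    if (any(af$fraction < 0 | af$fraction > 1))
      stop("arrested fractions must lie in [0, 1]")
    for (j in seq_len(nrow(af))) {
      bucket <- which(phase == match(af$phase[j], CYCLE_PHASES) &
                      round == af$division_round[j])
      k <- round(af$fraction[j] * length(bucket))
      if (k > 0)
        arrested[sample(bucket, k)] <- TRUE
    }
  }

  pop <- new("CellPopulation", phase = as.integer(phase),
             timeInPhase = tt, divisionRound = as.integer(round),
             arrested = arrested, clock = d$time_h[1L], initialMass = 0)
  pop@initialMass <- precursorMass(pop)
  validObject(pop)
  pop
}

#' Advance a population by one time step
#'
#' Performs one discrete step of length `dT`. Cells are processed in stable
#' index order; for each cell one uniform number is drawn and compared with
#' the transition hazard of its (phase, round) law evaluated at its current
#' time-in-phase. A cell whose draw falls below the hazard attempts a
#' transition, for which a second uniform is always drawn: if it falls below
#' the effective blocking probability of the cell's phase (0 before the
#' drug-addition time) the transition is blocked and the cell ages in place;
#' otherwise the cell enters the next phase with time-in-phase 0, and a
#' completed M -> G1 transition additionally increments the division round
#' and appends a daughter cell identical to the updated parent. All other
#' cells, and arrested cells, simply age by `dT`. Daughters appended during
#' a step are first processed in the following step.
#'
#' @param pop A [CellPopulation-class].
#' @param laws A [PhaseLawTable-class].
#' @param blocking A [BlockingPolicy-class], or `NULL` for no blocking
#'   machinery (equivalent, draw for draw, to a policy with all
#'   probabilities 0).
#' @param dT Step length (hours, > 0).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return The advanced [CellPopulation-class]; its clock is `pop@clock +
#'   dT`.
#' @export
advancePopulation <- function(pop, laws, blocking = NULL, dT = 0.36,
                              seed = NULL) {
  stopifnot(is(pop, "CellPopulation"), is(laws, "PhaseLawTable"))
  validObject(pop)
  validObject(laws)
  if (dT <= 0) stop("'dT' must be positive")
  if (!is.null(seed)) set.seed(seed)
  b <- numeric(4)
  active <- FALSE
  if (!is.null(blocking)) {
    stopifnot(is(blocking, "BlockingPolicy"))
    validObject(blocking)
    b <- unname(blocking@prob)
    active <- pop@clock >= blocking@drugTime - 1e-9
  }
  st <- cpp_advance(pop@phase, pop@timeInPhase, pop@divisionRound,
                    pop@arrested, laws@location, laws@scale, laws@shape,
                    b, active, dT, 1e-12)
  new("CellPopulation", phase = st$phase, timeInPhase = st$t,
      divisionRound = st$round, arrested = st$arrested,
      clock = pop@clock + dT, initialMass = pop@initialMass)
}

#' Simulate a population over a schedule
#'
#' Advances the population step by step from its current clock to the end of
#' the schedule, recording a cpF snapshot at every observation time.
#' Observation times and the drug-addition time are snapped to the nearest
#' step boundary (e.g. 32 h on the default 0.36 h grid becomes step 89 at
#' 32.04 h); snapshots are labelled with the requested times so they align
#' with experimental tables. When `tEnd` is not a multiple of `dT` the
#' simulation runs to the smallest multiple of `dT` at or beyond it.
#'
#' @param pop A [CellPopulation-class]; its clock defines the start time and
#'   observation times are interpreted on the same absolute axis.
#' @param laws A [PhaseLawTable-class].
#' @param blocking Optional [BlockingPolicy-class]; its probabilities apply
#'   to steps starting at or after the (snapped) drug time.
#' @param sched A [Schedule-class].
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @param keepPopulations Keep a [CellPopulation-class] copy per snapshot?
#'   Default `FALSE` (only cpF tables are kept).
#' @return A [SimulationResult-class].
#' @examples
#' pop <- initializePopulation(cpfTable(0, "G1", 0L, 100), 500, seed = 1)
#' res <- simulatePopulation(pop, referenceLaws(),
#'                           sched = schedule(tEnd = 36,
#'                                            observationTimes = c(0, 36)),
#'                           seed = 1)
#' cpfData(res@cpf)
#' @export
simulatePopulation <- function(pop, laws, blocking = NULL, sched = schedule(),
                               seed = NULL, keepPopulations = FALSE) {
  stopifnot(is(pop, "CellPopulation"), is(laws, "PhaseLawTable"),
            is(sched, "Schedule"))
  validObject(pop)
  validObject(laws)
  validObject(sched)
  if (!is.null(seed)) set.seed(seed)
  dT <- sched@dT
  t0 <- pop@clock
  total <- as.integer(ceiling((sched@tEnd - t0) / dT - 1e-9))
  if (total < 0) stop("'tEnd' precedes the population clock")
  obsStep <- as.integer(round((sched@observationTimes - t0) / dT))
  obsStep <- pmin(pmax(obsStep, 0L), max(total, 0L))
  b <- numeric(4)
  drugStep <- NA_integer_
  if (!is.null(blocking)) {
    stopifnot(is(blocking, "BlockingPolicy"))
    validObject(blocking)
    b <- unname(blocking@prob)
    drugStep <- as.integer(round((blocking@drugTime - t0) / dT))
  }

  res <- cpp_simulate(pop@phase, pop@timeInPhase, pop@divisionRound,
                      pop@arrested, laws@location, laws@scale, laws@shape,
                      b, if (is.na(drugStep)) -1L else max(drugStep, 0L),
                      dT, 1e-12, total, obsStep)
  wrap <- function(state, clock) {
    new("CellPopulation", phase = state$phase, timeInPhase = state$t,
        divisionRound = state$round, arrested = state$arrested,
        clock = clock, initialMass = pop@initialMass)
  }
  snaps <- vector("list", length(obsStep))
  pops <- list()
  for (j in seq_along(obsStep)) {
    p <- wrap(res$snapshots[[j]], t0 + obsStep[j] * dT)
    snaps[[j]] <- cpfData(computeCpf(p, time = sched@observationTimes[j]))
    if (keepPopulations)
      pops[[as.character(sched@observationTimes[j])]] <- p
  }
  cpf <- new("CpfTable", data = do.call(rbind, snaps))
  new("SimulationResult", cpf = cpf, populations = pops,
      finalPopulation = wrap(res$final, t0 + total * dT), schedule = sched)
}
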