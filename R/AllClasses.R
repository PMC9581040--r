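#' @import methods
NULL

#' Cell-cycle phase labels
#'
#' The four cell-cycle phases in their cyclic order. All phase-indexed
#' structures in the package (law tables, blocking vectors, populations)
#' use this order.
#'
#' @format Character vector of length four: `"G1"`, `"S"`, `"G2"`, `"M"`.
#' @export
CYCLE_PHASES <- c("G1", "S", "G2", "M")

## ---------------------------------------------------------------------------
## GevLaw
## ---------------------------------------------------------------------------

#' Generalized extreme value residence-time law
#'
#' A three-parameter generalized extreme value (GEV) distribution used as the
#' residence-time law of one cell-cycle phase. With shape `xi > 0` the
#' distribution is Fr\eqn{\'e}chet-type: it has a finite lower support
#' endpoint `location - scale/shape` and a heavy right tail, so a cell must
#' reside in a phase for a finite minimum time before it can exit and
#' long-resident cells become progressively less likely to leave.
#'
#' @slot location Location parameter \eqn{\mu} (hours).
#' @slot scale Scale parameter \eqn{\sigma} (hours), strictly positive.
#' @slot shape Shape parameter \eqn{\xi} (dimensionless), strictly positive.
#'
#' @seealso [gevCdf()], [hazardStep()]
#' @export
setClass("GevLaw",
  representation(location = "numeric", scale = "numeric", shape = "numeric"))

setValidity("GevLaw", function(object) {
  msg <- character()
  for (s in c("location", "scale", "shape")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, sprintf("'%s' must be a single finite number", s))
  }
  if (length(msg) == 0L) {
    if (object@scale <= 0) msg <- c(msg, "'scale' must be > 0")
    if (object@shape <= 0)
      msg <- c(msg, "'shape' must be > 0 (Frechet-type law)")
    else if (object@location - object@scale / object@shape < 0)
      msg <- c(msg,
        "lower support endpoint location - scale/shape must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GEV residence-time law
#'
#' @param location Location parameter \eqn{\mu} in hours.
#' @param scale Scale parameter \eqn{\sigma} in hours (> 0).
#' @param shape Shape parameter \eqn{\xi} (> 0). Defaults to 0.68, the value
#'   used for every phase law in the model; it is exposed for sensitivity
#'   studies but is never a fit parameter.
#' @return A [GevLaw-class] object.
#' @examples
#' law <- GevLaw(10, 1)
#' gevCdf(10, law)   # exp(-1)
#' @export
GevLaw <- function(location, scale, shape = 0.68) {
  new("GevLaw", location = as.numeric(location), scale = as.numeric(scale),
      shape = as.numeric(shape))
}

## ---------------------------------------------------------------------------
## PhaseLawTable
## ---------------------------------------------------------------------------

#' Per-phase, per-round table of residence-time laws
#'
#' Holds one GEV law per (phase, division round) with the tying structure
#' used throughout the model: G1 and S have a distinct law for division
#' round 0 and a single shared law for every round >= 1, while G2 and M use
#' one law for all rounds. The table is stored as two 4 x 2 matrices
#' (rows `G1,S,G2,M`; columns `round0`, `later`) plus the common shape
#' parameter.
#'
#' @slot location 4 x 2 matrix of location parameters (hours).
#' @slot scale 4 x 2 matrix of scale parameters (hours).
#' @slot shape Common shape parameter \eqn{\xi}.
#'
#' @seealso [phaseLawTable()], [lawFor()], [referenceLaws()], [expandTied()]
#' @export
setClass("PhaseLawTable",
  representation(location = "matrix", scale = "matrix", shape = "numeric"))

setValidity("PhaseLawTable", function(object) {
  msg <- character()
  for (s in c("location", "scale")) {
    m <- slot(object, s)
    if (!is.numeric(m) || !identical(dim(m), c(4L, 2L)))
      msg <- c(msg, sprintf("'%s' must be a numeric 4 x 2 matrix", s))
    else if (!identical(rownames(m), CYCLE_PHASES))
      msg <- c(msg, sprintf("rownames of '%s' must be G1, S, G2, M", s))
    else if (any(!is.finite(m)))
      msg <- c(msg, sprintf("'%s' must be finite", s))
  }
  if (length(object@shape) != 1L || !is.finite(object@shape) ||
      object@shape <= 0)
    msg <- c(msg, "'shape' must be a single positive number")
  if (length(msg) == 0L) {
    if (any(object@scale <= 0)) msg <- c(msg, "all scale entries must be > 0")
    if (any(object@location - object@scale / object@shape < 0))
      msg <- c(msg, "all laws must have support endpoint mu - sigma/xi >= 0")
    if (any(object@location[c("G2", "M"), 1L] !=
            object@location[c("G2", "M"), 2L]) ||
        any(object@scale[c("G2", "M"), 1L] != object@scale[c("G2", "M"), 2L]))
      msg <- c(msg, "G2 and M laws must be identical across division rounds")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a phase-law table
#'
#' @param location Numeric 4 x 2 matrix (or object coercible to one) of GEV
#'   location parameters, rows in phase order G1, S, G2, M and columns
#'   `round0` (division round 0) and `later` (rounds >= 1). G2 and M rows
#'   must be constant across the two columns.
#' @param scale Matching 4 x 2 matrix of scale parameters.
#' @param shape Common shape parameter, default 0.68.
#' @return A [PhaseLawTable-class].
#' @export
phaseLawTable <- function(location, scale, shape = 0.68) {
  fix <- function(m) {
    m <- matrix(as.numeric(m), nrow = 4L, ncol = 2L,
                dimnames = list(CYCLE_PHASES, c("round0", "later")))
    m
  }
  new("PhaseLawTable", location = fix(location), scale = fix(scale),
      shape = as.numeric(shape))
}

## ---------------------------------------------------------------------------
## BlockingPolicy
## ---------------------------------------------------------------------------

#' Therapeutic phase-transition blocking policy
#'
#' Per-phase probabilities that an attempted transition out of the phase is
#' blocked by a therapeutic, together with the time the drug is added. Before
#' `drugTime` the effective blocking probability is 0 for every phase; from
#' `drugTime` on each attempted exit from phase p is blocked with probability
#' `prob[p]` (a blocked cell stays in phase with its clock still advancing).
#'
#' @slot prob Named numeric vector (`G1`, `S`, `G2`, `M`) of blocking
#'   probabilities in `[0, 1]`.
#' @slot drugTime Time of drug addition (hours).
#' @seealso [blockingPolicy()], [advancePopulation()], [fitTreated()]
#' @export
setClass("BlockingPolicy",
  representation(prob = "numeric", drugTime = "numeric"))

setValidity("BlockingPolicy", function(object) {
  msg <- character()
  if (length(object@prob) != 4L || !identical(names(object@prob),
                                              CYCLE_PHASES))
    msg <- c(msg, "'prob' must be a numeric vector named G1, S, G2, M")
  else if (any(!is.finite(object@prob)) || any(object@prob < 0) ||
           any(object@prob > 1))
    msg <- c(msg, "blocking probabilities must lie in [0, 1]")
  if (length(object@drugTime) != 1L || !is.finite(object@drugTime) ||
      object@drugTime < 0)
    msg <- c(msg, "'drugTime' must be a single non-negative time in hours")
  if (length(msg)) msg else TRUE
})

#' Construct a blocking policy
#'
#' @param prob Numeric vector of four blocking probabilities in phase order
#'   G1, S, G2, M (names optional; they are enforced).
#' @param drugTime Hour at which the drug is added; default 32.
#' @return A [BlockingPolicy-class].
#' @export
blockingPolicy <- function(prob = c(0, 0, 0, 0), drugTime = 32) {
  prob <- as.numeric(prob)
  names(prob) <- CYCLE_PHASES
  new("BlockingPolicy", prob = prob, drugTime = as.numeric(drugTime))
}

## ---------------------------------------------------------------------------
## Schedule
## ---------------------------------------------------------------------------

#' Simulation schedule
#'
#' Discrete-time schedule of a simulation: step size, end time and the times
#' at which cpF snapshots are recorded. The default reproduces the standard
#' run of 200 steps of 0.36 h over a virtual period of 72 h with
#' observations at 0, 32, 48 and 72 h. Observation (and drug) times that do
#' not fall on the step grid are snapped to the nearest step boundary.
#'
#' @slot dT Time step (hours), > 0.
#' @slot tEnd End time (hours).
#' @slot observationTimes Times (hours) at which snapshots are recorded.
#' @seealso [schedule()], [simulatePopulation()]
#' @export
setClass("Schedule",
  representation(dT = "numeric", tEnd = "numeric",
                 observationTimes = "numeric"))

setValidity("Schedule", function(object) {
  msg <- character()
  if (length(object@dT) != 1L || !is.finite(object@dT) || object@dT <= 0)
    msg <- c(msg, "'dT' must be a single positive step in hours")
  if (length(object@tEnd) != 1L || !is.finite(object@tEnd) ||
      object@tEnd < 0)
    msg <- c(msg, "'tEnd' must be a single non-negative time in hours")
  if (length(object@observationTimes) < 1L ||
      any(!is.finite(object@observationTimes)))
    msg <- c(msg, "'observationTimes' must be finite times")
  else if (length(msg) == 0L &&
           (any(object@observationTimes < 0) ||
            any(object@observationTimes > object@tEnd + 1e-9)))
    msg <- c(msg, "'observationTimes' must lie within [0, tEnd]")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation schedule
#'
#' @param dT Time step in hours; default 0.36.
#' @param tEnd End of simulated time in hours; default 72 (200 steps).
#' @param observationTimes Snapshot times in hours; default
#'   `c(0, 32, 48, 72)`.
#' @return A [Schedule-class].
#' @export
schedule <- function(dT = 0.36, tEnd = 72,
                     observationTimes = c(0, 32, 48, 72)) {
  new("Schedule", dT = as.numeric(dT), tEnd = as.numeric(tEnd),
      observationTimes = sort(unique(as.numeric(observationTimes))))
}

#' @describeIn schedule Number of whole steps the schedule runs; `tEnd` is
#'   rounded up to the next step boundary when it is not a multiple of `dT`.
#' @param x A `Schedule`.
#' @export
nSteps <- function(x) {
  stopifnot(is(x, "Schedule"))
  as.integer(ceiling(x@tEnd / x@dT - 1e-9))
}

## ---------------------------------------------------------------------------
## CellPopulation
## ---------------------------------------------------------------------------

#' Agent-based cell population
#'
#' The in-silico ensemble. Each cell carries its current cell-cycle phase,
#' the time it has resided in that phase, the number of division rounds its
#' lineage has undergone, and an arrested flag (arrested cells never change
#' phase or round and never divide; they represent the experimentally
#' observed subpopulation stuck in division round 0). The population also
#' carries the global clock and its initial precursor mass
#' \eqn{\sum_i 2^{-N_i}}, which is conserved exactly through mitosis.
#'
#' @slot phase Integer vector, 1-4 indexing `CYCLE_PHASES`.
#' @slot timeInPhase Numeric vector, hours each cell has spent in its phase.
#' @slot divisionRound Integer vector of division rounds (0 = undivided).
#' @slot arrested Logical vector.
#' @slot clock Global time (hours).
#' @slot initialMass Precursor mass at initialization.
#' @seealso [initializePopulation()], [advancePopulation()], [computeCpf()]
#' @export
setClass("CellPopulation",
  representation(phase = "integer", timeInPhase = "numeric",
                 divisionRound = "integer", arrested = "logical",
                 clock = "numeric", initialMass = "numeric"))

setValidity("CellPopulation", function(object) {
  n <- length(object@phase)
  msg <- character()
  if (length(object@timeInPhase) != n || length(object@divisionRound) != n ||
      length(object@arrested) != n)
    msg <- c(msg, "per-cell slots must have equal length")
  if (n == 0L) msg <- c(msg, "population must contain at least one cell")
  if (length(msg) == 0L) {
    if (any(object@phase < 1L) || any(object@phase > 4L))
      msg <- c(msg, "'phase' must index the four cycle phases (1-4)")
    if (any(object@timeInPhase < 0)) msg <- c(msg, "'timeInPhase' must be >= 0")
    if (any(object@divisionRound < 0L))
      msg <- c(msg, "'divisionRound' must be >= 0")
  }
  if (length(object@clock) != 1L || !is.finite(object@clock) ||
      object@clock < 0)
    msg <- c(msg, "'clock' must be a single non-negative time")
  if (length(msg)) msg else TRUE
})

#' Construct a cell population from per-cell state
#'
#' Low-level constructor; most populations are created with
#' [initializePopulation()].
#'
#' @param phase Phase labels (`"G1"`, `"S"`, `"G2"`, `"M"`) or integer codes
#'   1-4, one per cell.
#' @param timeInPhase Hours in current phase, one per cell (default 0).
#' @param divisionRound Division round, one per cell (default 0).
#' @param arrested Logical, one per cell (default `FALSE`).
#' @param clock Global clock in hours (default 0).
#' @return A [CellPopulation-class].
#' @export
cellPopulation <- function(phase, timeInPhase = 0, divisionRound = 0L,
                           arrested = FALSE, clock = 0) {
  if (is.character(phase)) {
    idx <- match(phase, CYCLE_PHASES)
    if (anyNA(idx)) stop("unknown phase label(s): ",
                         paste(unique(phase[is.na(idx)]), collapse = ", "))
    phase <- idx
  }
  n <- length(phase)
  pop <- new("CellPopulation",
    phase = as.integer(phase),
    timeInPhase = rep_len(as.numeric(timeInPhase), n),
    divisionRound = rep_len(as.integer(divisionRound), n),
    arrested = rep_len(as.logical(arrested), n),
    clock = as.numeric(clock),
    initialMass = 0)
  pop@initialMass <- precursorMass(pop)
  pop
}

## ---------------------------------------------------------------------------
## CpfTable
## ---------------------------------------------------------------------------

#' Precursor-normalised phase-frequency table (cpF)
#'
#' The model's observable: for each observation time, the percentage of the
#' precursor-normalised population in each (cell-cycle phase, division round)
#' bucket. Counts in division round n are weighted by 2^-n so that every
#' founding precursor contributes equal weight regardless of how many
#' descendants it has; percentages then sum to 100 at each time point.
#'
#' @slot data `data.frame` with columns `time_h`, `phase`, `division_round`,
#'   `cpf_percent`.
#' @seealso [cpfTable()], [computeCpf()], [cpfSsq()], [readCpfCsv()]
#' @export
setClass("CpfTable", representation(data = "data.frame"))

setValidity("CpfTable", function(object) {
  d <- object@data
  msg <- character()
  need <- c("time_h", "phase", "division_round", "cpf_percent")
  if (!identical(names(d), need))
    return(paste("columns must be", paste(need, collapse = ", ")))
  if (nrow(d) == 0L) return("cpF table must contain at least one row")
  if (!all(d$phase %in% CYCLE_PHASES))
    msg <- c(msg, "phase labels must be G1, S, G2 or M")
  if (any(d$division_round < 0L) || any(d$division_round != floor(d$division_round)))
    msg <- c(msg, "division rounds must be non-negative integers")
  if (any(!is.finite(d$cpf_percent)) || any(d$cpf_percent < 0))
    msg <- c(msg, "percentages must be finite and >= 0")
  if (anyDuplicated(d[c("time_h", "phase", "division_round")]))
    msg <- c(msg, "(time, phase, round) keys must be unique")
  if (length(msg) == 0L) {
    sums <- tapply(d$cpf_percent, d$time_h, sum)
    bad <- abs(sums - 100) > 1e-6
    if (any(bad))
      msg <- c(msg, sprintf(
        "percentages must sum to 100 at every time point (off at t = %s)",
        paste(names(sums)[bad], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a cpF table
#'
#' @param time_h Observation time(s) in hours (recycled).
#' @param phase Phase labels.
#' @param division_round Division rounds.
#' @param cpf_percent Percentages; must sum to 100 per time point.
#' @return A [CpfTable-class].
#' @examples
#' cpfTable(0, c("G1", "S"), 0L, c(60, 40))
#' @export
cpfTable <- function(time_h, phase, division_round, cpf_percent) {
  d <- data.frame(time_h = as.numeric(time_h),
                  phase = as.character(phase),
                  division_round = as.integer(division_round),
                  cpf_percent = as.numeric(cpf_percent))
  d <- d[order(d$time_h, d$division_round, match(d$phase, CYCLE_PHASES)), ,
         drop = FALSE]
  rownames(d) <- NULL
  new("CpfTable", data = d)
}

## ---------------------------------------------------------------------------
## SimulationResult
## ---------------------------------------------------------------------------

#' Result of a population simulation
#'
#' @slot cpf A [CpfTable-class] stacking the snapshots at every requested
#'   observation time (labelled with the requested, not the grid-snapped,
#'   times so they align with experimental tables).
#' @slot populations Named list of [CellPopulation-class] snapshots (present
#'   only when the simulation was run with `keepPopulations = TRUE`).
#' @slot finalPopulation State of the ensemble after the last step.
#' @slot schedule The [Schedule-class] that was run.
#' @seealso [simulatePopulation()]
#' @export
setClass("SimulationResult",
  representation(cpf = "CpfTable", populations = "list",
                 finalPopulation = "CellPopulation", schedule = "Schedule"))

## ---------------------------------------------------------------------------
## SyntheticExperiment
## ---------------------------------------------------------------------------

#' Synthetic cpF dataset with known ground truth
#'
#' A simulated counterpart of the flow-cytometry experiment: cpF observations
#' generated from known residence-time laws (and optionally a known blocking
#' policy), with multiplicative per-entry measurement noise. Used to validate
#' the fitting machinery by parameter recovery.
#'
#' @slot truthLaws The generating [PhaseLawTable-class].
#' @slot truthBlocking The generating [BlockingPolicy-class], or `NULL` for
#'   untreated datasets.
#' @slot cpf0 The exact initial cpF the population was matched to.
#' @slot observations [CpfTable-class] of (noisy) observations.
#' @slot noisePct Relative measurement noise in percent.
#' @slot seed Integer seed the dataset was generated from.
#' @seealso [generateUntreatedDataset()], [generateTreatedDataset()]
#' @export
setClass("SyntheticExperiment",
  representation(truthLaws = "PhaseLawTable", truthBlocking = "ANY",
                 cpf0 = "CpfTable", observations = "CpfTable",
                 noisePct = "numeric", seed = "integer"))

## ---------------------------------------------------------------------------
## CycleFit
## ---------------------------------------------------------------------------

#' Replicate-averaged fit result
#'
#' Summary of repeated differential-evolution fits: per-parameter mean and
#' standard error over replicates, box-plot-ready quantiles, and the best
#' objective value reached in each replicate.
#'
#' @slot estimate Named per-parameter means over replicates.
#' @slot stderr Named per-parameter standard errors (sd/sqrt(n); 0 for a
#'   single replicate).
#' @slot replicates Replicates x parameters matrix of per-replicate optima.
#' @slot objectives Best objective value of each replicate.
#' @slot seeds Integer simulation seeds used by the replicates.
#' @slot quantiles 3 x parameters matrix of the 25/50/75 percent quantiles.
#' @slot kind `"untreated"` or `"treated"` (or `"summary"` for plain
#'   replicate matrices).
#' @slot diagnostics List of optimizer diagnostics (generations used,
#'   convergence flags).
#' @seealso [fitUntreated()], [fitTreated()], [summarizeReplicates()]
#' @export
setClass("CycleFit",
  representation(estimate = "numeric", stderr = "numeric",
                 replicates = "matrix", objectives = "numeric",
                 seeds = "integer", quantiles = "matrix", kind = "character",
                 diagnostics = "list"))
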