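## Two-stage differential-evolution estimation: stage 1 fits the tied
## 10-parameter mu/sigma vector to untreated cpF data; stage 2 fits the four
## per-phase blocking probabilities to treated data with stage-1 laws frozen.

#' Names of the tied 10-parameter vector
#'
#' Order of the tied interphase-time parameter vector used for fitting:
#' G1 and S each get a division-round-0 and a rounds->=1 location, G2 and M
#' one location each, and G1/S get round-0 and rounds->=1 scales. The G2/M
#' scales are fixed at 0.1 h and the shape at 0.68, so they never appear.
#'
#' @format Character vector of length 10.
#' @export
TIED_PARAM_NAMES <- c("mu_G1_0", "mu_G1_r", "mu_S_0", "mu_S_r",
                      "mu_G2", "mu_M",
                      "sigma_G1_0", "sigma_G1_r", "sigma_S_0", "sigma_S_r")

#' Expand a tied parameter vector into a full law table
#'
#' Applies the tying scheme: G1 and S use their `_0` entries for division
#' round 0 and their `_r` entries for every round >= 1; G2 and M use a
#' single location for all rounds with scale fixed at `sigmaG2M`; the shape
#' is common to all laws.
#'
#' @param v Numeric vector of length 10 in [TIED_PARAM_NAMES] order.
#' @param shape Common GEV shape; default 0.68.
#' @param sigmaG2M Fixed G2/M scale in hours; default 0.1.
#' @return A [PhaseLawTable-class]. Vectors implying a law with negative
#'   support endpoint are rejected.
#' @examples
#' expandTied(flattenLaws(referenceLaws()))
#' @export
expandTied <- function(v, shape = 0.68, sigmaG2M = 0.1) {
  if (!is.numeric(v) || length(v) != 10L)
    stop("'v' must be a numeric vector of length 10")
  v <- unname(v)
  loc <- rbind(G1 = c(v[1L], v[2L]), S = c(v[3L], v[4L]),
               G2 = c(v[5L], v[5L]), M = c(v[6L], v[6L]))
  sc <- rbind(G1 = c(v[7L], v[8L]), S = c(v[9L], v[10L]),
              G2 = c(sigmaG2M, sigmaG2M), M = c(sigmaG2M, sigmaG2M))
  phaseLawTable(loc, sc, shape = shape)
}

#' Flatten a law table into the tied 10-parameter vector
#'
#' Inverse of [expandTied()] (the fixed G2/M scales and the shape are
#' dropped).
#'
#' @param laws A [PhaseLawTable-class].
#' @return Named numeric vector of length 10.
#' @export
flattenLaws <- function(laws) {
  stopifnot(is(laws, "PhaseLawTable"))
  v <- c(laws@location["G1", ], laws@location["S", ],
         laws@location["G2", 1L], laws@location["M", 1L],
         laws@scale["G1", ], laws@scale["S", ])
  names(v) <- TIED_PARAM_NAMES
  v
}

#' Number of free parameters under each tying scheme
#'
#' With four phases and `nRounds` division rounds, the fully free scheme has
#' one location and one scale per (phase, round); fixing the G2/M scales
#' removes one scale per round for each of the two phases; the tied scheme
#' shares laws across rounds as in [expandTied()], leaving 10 parameters.
#'
#' @param scheme One of `"full"`, `"sigma_fixed"`, `"tied"`.
#' @param nRounds Number of division rounds modelled; default 4
#'   (rounds 0-3).
#' @return Integer count: 32, 24 and 10 respectively at the default
#'   `nRounds`.
#' @export
parameterCount <- function(scheme = c("full", "sigma_fixed", "tied"),
                           nRounds = 4L) {
  scheme <- match.arg(scheme)
  switch(scheme,
    full = 2L * 4L * as.integer(nRounds),
    sigma_fixed = 2L * 4L * as.integer(nRounds) - 2L * as.integer(nRounds),
    tied = 10L)
}

#' Default fitting bounds for the tied parameter vector
#'
#' Locations are bounded in `[0.5, 25]` h and the free G1/S scales in
#' `[0.05, 8]` h, bracketing all plausible Jurkat phase times with margin.
#' The upper location bound doubles as the default `initTimeMax` of
#' [initializePopulation()], since the random initial time-in-phase is drawn
#' up to the largest location the fit may propose.
#'
#' @return List with named numeric vectors `lower` and `upper`.
#' @export
defaultFitBounds <- function() {
  lower <- c(rep(0.5, 6), rep(0.05, 4))
  upper <- c(rep(25, 6), rep(8, 4))
  names(lower) <- names(upper) <- TIED_PARAM_NAMES
  list(lower = lower, upper = upper)
}

#' Differential-evolution settings
#'
#' Settings for the population-based global minimizer. Under the default
#' `"best/1/bin"` strategy, trial vectors are built from the current best
#' member as `x_best + F (x_r1 - x_r2)`; under `"rand/1/bin"` the base is a
#' random third member. `F` is dithered: when `mutation` has two entries a
#' fresh `F` is drawn uniformly from that range each generation, which
#' speeds convergence while preserving diversity. Trials are crossed over
#' binomially with the target and replace it when not worse. The population
#' holds `popSize * d` members for a `d`-dimensional problem. Iteration
#' stops after `maxGen` generations or when the population's objective
#' spread falls below `tol` relative to its mean; the returned optimum is
#' then refined by a short derivative-free Nelder-Mead polish (the
#' objectives used here are deterministic under common random numbers, so
#' local refinement is meaningful).
#'
#' @param popSize Population size multiplier per dimension; default 15.
#' @param mutation Differential weight F: a single value, or a range of two
#'   values to dither over; default `c(0.5, 1)`.
#' @param crossover Crossover probability CR in `[0, 1]`; default 0.9.
#' @param maxGen Maximum generations; default 100.
#' @param tol Relative convergence tolerance; default 1e-3.
#' @param strategy `"best/1/bin"` (default) or `"rand/1/bin"`.
#' @param polish Number of Nelder-Mead iterations applied to the DE optimum
#'   (0 disables); default 150.
#' @return A list of class `"deControl"`.
#' @export
deControl <- function(popSize = 15, mutation = c(0.5, 1), crossover = 0.9,
                      maxGen = 100, tol = 1e-3,
                      strategy = c("best/1/bin", "rand/1/bin"),
                      polish = 150) {
  strategy <- match.arg(strategy)
  stopifnot(popSize > 0, length(mutation) %in% 1:2, all(mutation > 0),
            crossover >= 0, crossover <= 1, maxGen >= 1, tol >= 0,
            polish >= 0)
  structure(list(popSize = popSize, mutation = range(mutation),
                 crossover = crossover, maxGen = maxGen, tol = tol,
                 strategy = strategy, polish = as.integer(polish)),
            class = "deControl")
}

#' Differential-evolution minimizer (rand/1/bin)
#'
#' Minimizes `fn` over a box. Deterministic given `seed` (the objective must
#' itself be deterministic, as the common-random-number objectives used for
#' fitting are).
#'
#' @param fn Objective function of a numeric vector.
#' @param lower,upper Numeric bound vectors of equal length.
#' @param control A [deControl()] list.
#' @param seed Optional integer seed for the optimizer's own randomness.
#' @return List with `par`, `value`, `generations`, `converged` and the
#'   per-generation best-objective `trace`.
#' @export
differentialEvolution <- function(fn, lower, upper, control = deControl(),
                                  seed = NULL) {
  stopifnot(length(lower) == length(upper), all(lower < upper))
  if (!is.null(seed)) set.seed(seed)
  d <- length(lower)
  np <- max(4L, as.integer(round(control$popSize * d)))
  pop <- matrix(stats::runif(np * d, rep(lower, each = np),
                             rep(upper, each = np)), nrow = np)
  cost <- apply(pop, 1L, fn)
  trace <- numeric(control$maxGen)
  gen <- 0L
  converged <- FALSE
  useBest <- control$strategy == "best/1/bin"
  for (gen in seq_len(control$maxGen)) {
    Fw <- if (control$mutation[1L] == control$mutation[2L])
      control$mutation[1L]
    else stats::runif(1L, control$mutation[1L], control$mutation[2L])
    for (i in seq_len(np)) {
      r <- sample.int(np, 3L)
      while (any(r == i)) r <- sample.int(np, 3L)
      base <- if (useBest) pop[which.min(cost), ] else pop[r[3L], ]
      mutant <- base + Fw * (pop[r[1L], ] - pop[r[2L], ])
      mutant <- pmin(pmax(mutant, lower), upper)
      jrand <- sample.int(d, 1L)
      cross <- stats::runif(d) < control$crossover
      cross[jrand] <- TRUE
      trial <- ifelse(cross, mutant, pop[i, ])
      fc <- fn(trial)
      if (fc <= cost[i]) {
        pop[i, ] <- trial
        cost[i] <- fc
      }
    }
    trace[gen] <- min(cost)
    if (stats::sd(cost) <= control$tol * (abs(mean(cost)) + 1e-12)) {
      converged <- TRUE
      break
    }
  }
  best <- which.min(cost)
  par <- pop[best, ]
  value <- cost[best]
  if (control$polish > 0L) {
    pol <- stats::optim(par, function(x) fn(pmin(pmax(x, lower), upper)),
                        method = "Nelder-Mead",
                        control = list(maxit = control$polish))
    if (pol$value <= value) {
      par <- pmin(pmax(pol$par, lower), upper)
      value <- pol$value
    }
  }
  list(par = par, value = value, generations = gen,
       converged = converged, trace = trace[seq_len(gen)])
}

#' Objective for the untreated stage-1 fit
#'
#' Expands the tied vector into a law table, initializes a population from
#' `cpf0` (with the given arrested fractions), simulates it with no blocking
#' over the schedule, and returns the cpF sum of squares against the
#' experimental table at the experimental observation times. All randomness
#' (initial times-in-phase, arrest selection, transitions) is drawn from a
#' stream seeded with `simSeed`, so for a fixed seed the objective is a
#' deterministic function of `v` (common random numbers); in particular it
#' is exactly 0 at the parameters that generated the data under the same
#' seed. Vectors outside the bounds, or implying an invalid law, return the
#' finite penalty `1e9` rather than raising, so population-based search can
#' proceed.
#'
#' @param v Tied parameter vector (length 10).
#' @param expCpf Experimental [CpfTable-class]; its time points define the
#'   observation times.
#' @param cpf0 Initial cpF at the start time.
#' @param simSeed Integer seed for the common-random-number stream.
#' @param nCells Cells to simulate.
#' @param sched A [Schedule-class]; its observation times are replaced by
#'   the experimental ones.
#' @param arrestedFractions Passed to [initializePopulation()].
#' @param initTimeMax Passed to [initializePopulation()].
#' @param bounds Bound list as from [defaultFitBounds()].
#' @param shape,sigmaG2M Fixed law parameters, as in [expandTied()].
#' @return A non-negative number (squared percent units), or `1e9` for
#'   invalid `v`.
#' @export
objectiveUntreated <- function(v, expCpf, cpf0, simSeed, nCells = 2000,
                               sched = schedule(), arrestedFractions = NULL,
                               initTimeMax = 25, bounds = defaultFitBounds(),
                               shape = 0.68, sigmaG2M = 0.1) {
  if (any(v < bounds$lower) || any(v > bounds$upper)) return(1e9)
  laws <- tryCatch(expandTied(v, shape = shape, sigmaG2M = sigmaG2M),
                   error = function(e) NULL)
  if (is.null(laws)) return(1e9)
  times <- sort(unique(cpfData(expCpf)$time_h))
  sched <- schedule(dT = sched@dT, tEnd = max(times),
                    observationTimes = times)
  sim <- withSeed(simSeed, {
    pop <- initializePopulation(cpf0, nCells = nCells,
                                initTimeMax = initTimeMax,
                                arrestedFractions = arrestedFractions)
    simulatePopulation(pop, laws, blocking = NULL, sched = sched)
  })
  cpfSsq(sim@cpf, expCpf)
}

#' Objective for the treated stage-2 fit
#'
#' Same construction as [objectiveUntreated()] but over the four blocking
#' probabilities with the law table frozen: the population is initialized
#' from `cpf0` at time 0, simulated with the candidate blocking policy
#' (inactive before the drug-addition time, active after), and compared with
#' the treated experimental cpF at its observation times.
#'
#' @param b Numeric vector of four blocking probabilities (G1, S, G2, M).
#' @param expCpf Treated experimental [CpfTable-class] (typically at 48 h).
#' @param cpf0 Initial cpF at time 0.
#' @param laws Frozen [PhaseLawTable-class] from the untreated fit.
#' @param drugTime Drug-addition time in hours; default 32.
#' @inheritParams objectiveUntreated
#' @return A non-negative number, or `1e9` for invalid `b`.
#' @export
objectiveTreated <- function(b, expCpf, cpf0, laws, simSeed, drugTime = 32,
                             nCells = 2000, sched = schedule(),
                             arrestedFractions = NULL, initTimeMax = 25) {
  if (length(b) != 4L || any(!is.finite(b)) || any(b < 0) || any(b > 1))
    return(1e9)
  times <- sort(unique(cpfData(expCpf)$time_h))
  sched <- schedule(dT = sched@dT, tEnd = max(times),
                    observationTimes = times)
  sim <- withSeed(simSeed, {
    pop <- initializePopulation(cpf0, nCells = nCells,
                                initTimeMax = initTimeMax,
                                arrestedFractions = arrestedFractions)
    simulatePopulation(pop, laws,
                       blocking = blockingPolicy(b, drugTime),
                       sched = sched)
  })
  cpfSsq(sim@cpf, expCpf)
}

#' Estimate arrested fractions from the final observation
#'
#' The arrested subpopulation is visible as the cpF mass still in division
#' round 0 at the final observation time. For each phase the residual
#' round-0 percentage at the last time point, relative to that phase's
#' round-0 percentage at initialization, is interpreted as the fraction of
#' the initial bucket to arrest. Fractions are clipped to `[0, 1]` and
#' phases absent at initialization are skipped. These fractions are fixed
#' before fitting; they are never optimizer parameters.
#'
#' @param expCpf Experimental [CpfTable-class] covering the final time.
#' @param cpf0 Initial cpF.
#' @return `data.frame(phase, division_round, fraction)` suitable for
#'   [initializePopulation()], or `NULL` when no residual mass is present.
#' @export
estimateArrestedFractions <- function(expCpf, cpf0) {
  stopifnot(is(expCpf, "CpfTable"), is(cpf0, "CpfTable"))
  de <- cpfData(expCpf)
  d0 <- cpfData(cpf0)
  fin <- de[de$time_h == max(de$time_h) & de$division_round == 0L, ,
            drop = FALSE]
  base <- d0[d0$division_round == 0L, , drop = FALSE]
  if (nrow(fin) == 0L || nrow(base) == 0L) return(NULL)
  m <- merge(fin, base, by = "phase", suffixes = c("_fin", "_init"))
  if (nrow(m) == 0L) return(NULL)
  frac <- pmin(pmax(m$cpf_percent_fin / m$cpf_percent_init, 0), 1)
  data.frame(phase = m$phase, division_round = 0L, fraction = frac)
}

#' Summarize replicate fits
#'
#' Per-parameter mean and standard error (sd/sqrt(n); 0 for a single
#' replicate) over replicate optima, plus the 25/50/75 percent quantiles
#' used for box-plot style reporting. The summary is invariant under
#' permutation of the replicates.
#'
#' @param replicates Numeric matrix, one row per replicate, one column per
#'   parameter (a single replicate may be given as a vector).
#' @param objectives Optional best objective value per replicate.
#' @param seeds Optional integer seeds per replicate.
#' @param kind Label stored in the result.
#' @param diagnostics Optional list of optimizer diagnostics.
#' @return A [CycleFit-class].
#' @examples
#' summarizeReplicates(rbind(1, 2, 3))
#' @export
summarizeReplicates <- function(replicates, objectives = numeric(),
                                seeds = integer(), kind = "summary",
                                diagnostics = list()) {
  if (is.null(dim(replicates))) replicates <- matrix(replicates, nrow = 1L)
  n <- nrow(replicates)
  if (n < 1L) stop("at least one replicate is required")
  est <- colMeans(replicates)
  se <- if (n == 1L) rep(0, ncol(replicates))
        else apply(replicates, 2L, stats::sd) / sqrt(n)
  q <- apply(replicates, 2L, stats::quantile, probs = c(0.25, 0.5, 0.75))
  q <- matrix(q, nrow = 3L,
              dimnames = list(c("q25", "median", "q75"),
                              colnames(replicates)))
  names(se) <- names(est) <- colnames(replicates)
  new("CycleFit", estimate = est, stderr = se, replicates = replicates,
      objectives = as.numeric(objectives), seeds = as.integer(seeds),
      quantiles = q, kind = kind, diagnostics = diagnostics)
}

## Derive independent sub-seeds (< 2^31) from one master seed.
deriveSeeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

#' Fit interphase-time parameters to untreated cpF data
#'
#' Stage 1 of the estimation scheme: repeated differential-evolution
#' minimizations of [objectiveUntreated()] over the tied 10-parameter
#' vector. Each replicate uses its own simulation seed, held fixed across
#' every objective evaluation of that replicate (common random numbers), so
#' each replicate solves a deterministic problem and the replicate-to-
#' replicate spread reflects simulation stochasticity. Results are averaged
#' over replicates as in [summarizeReplicates()].
#'
#' @param expCpf Experimental untreated [CpfTable-class] (observation times
#'   after the start, e.g. 32/48/72 h).
#' @param cpf0 Initial cpF at the start time.
#' @param bounds Box bounds, default [defaultFitBounds()].
#' @param control DE settings, default `deControl(maxGen = 40)` (desk-scale;
#'   raise `maxGen` for production fits).
#' @param nReplicates Number of independent fits; default 3 (the production
#'   setting in the experimental analysis is 100).
#' @param nCells Cells per simulation; default 2000 (production: 20000).
#' @param sched Simulation [Schedule-class].
#' @param arrestedFractions `"auto"` (default) estimates them with
#'   [estimateArrestedFractions()]; otherwise passed through.
#' @param initTimeMax Upper bound of the initial time-in-phase draw.
#' @param seed Master seed from which replicate simulation and optimizer
#'   seeds are derived.
#' @return A [CycleFit-class] over [TIED_PARAM_NAMES].
#' @export
fitUntreated <- function(expCpf, cpf0, bounds = defaultFitBounds(),
                         control = deControl(maxGen = 40), nReplicates = 3,
                         nCells = 2000, sched = schedule(),
                         arrestedFractions = "auto", initTimeMax = 25,
                         seed = 1) {
  stopifnot(is(expCpf, "CpfTable"), is(cpf0, "CpfTable"))
  if (identical(arrestedFractions, "auto"))
    arrestedFractions <- estimateArrestedFractions(expCpf, cpf0)
  simSeeds <- deriveSeeds(seed, nReplicates)
  deSeeds <- deriveSeeds(seed + 1L, nReplicates)
  reps <- matrix(NA_real_, nReplicates, 10L,
                 dimnames = list(NULL, TIED_PARAM_NAMES))
  objs <- numeric(nReplicates)
  diag <- vector("list", nReplicates)
  for (r in seq_len(nReplicates)) {
    fn <- function(v) objectiveUntreated(v, expCpf, cpf0,
                                         simSeed = simSeeds[r],
                                         nCells = nCells, sched = sched,
                                         arrestedFractions = arrestedFractions,
                                         initTimeMax = initTimeMax,
                                         bounds = bounds)
    res <- differentialEvolution(fn, bounds$lower, bounds$upper,
                                 control = control, seed = deSeeds[r])
    reps[r, ] <- res$par
    objs[r] <- res$value
    diag[[r]] <- res[c("generations", "converged")]
    if (res$value >= 1e9)
      warning(sprintf("replicate %d never left the penalty region", r))
  }
  summarizeReplicates(reps, objectives = objs, seeds = simSeeds,
                      kind = "untreated", diagnostics = diag)
}

#' Fit per-phase blocking probabilities to treated cpF data
#'
#' Stage 2 of the estimation scheme: with the residence-time laws frozen
#' (from [fitUntreated()] or [referenceLaws()]), repeated differential-
#' evolution minimizations of [objectiveTreated()] recover the four blocking
#' probabilities from the treated cpF. The simulation starts at time 0 with
#' all blocking probabilities effectively 0 and the candidate policy takes
#' effect at the drug-addition time.
#'
#' @param expCpf Treated experimental [CpfTable-class] (typically the 48 h
#'   observation).
#' @param cpf0 Initial cpF at time 0.
#' @param laws Frozen [PhaseLawTable-class].
#' @param drugTime Drug-addition time in hours; default 32.
#' @inheritParams fitUntreated
#' @return A [CycleFit-class] over `b_G1, b_S, b_G2, b_M`.
#' @export
fitTreated <- function(expCpf, cpf0, laws, drugTime = 32,
                       control = deControl(maxGen = 40), nReplicates = 3,
                       nCells = 2000, sched = schedule(),
                       arrestedFractions = NULL, initTimeMax = 25,
                       seed = 1) {
  stopifnot(is(expCpf, "CpfTable"), is(cpf0, "CpfTable"),
            is(laws, "PhaseLawTable"))
  validObject(laws)
  simSeeds <- deriveSeeds(seed, nReplicates)
  deSeeds <- deriveSeeds(seed + 1L, nReplicates)
  pnames <- paste0("b_", CYCLE_PHASES)
  reps <- matrix(NA_real_, nReplicates, 4L, dimnames = list(NULL, pnames))
  objs <- numeric(nReplicates)
  diag <- vector("list", nReplicates)
  for (r in seq_len(nReplicates)) {
    fn <- function(b) objectiveTreated(b, expCpf, cpf0, laws,
                                       simSeed = simSeeds[r],
                                       drugTime = drugTime, nCells = nCells,
                                       sched = sched,
                                       arrestedFractions = arrestedFractions,
                                       initTimeMax = initTimeMax)
    res <- differentialEvolution(fn, rep(0, 4), rep(1, 4),
                                 control = control, seed = deSeeds[r])
    reps[r, ] <- res$par
    objs[r] <- res$value
    diag[[r]] <- res[c("generations", "converged")]
  }
  summarizeReplicates(reps, objectives = objs, seeds = simSeeds,
                      kind = "treated", diagnostics = diag)
}
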