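## The cpF observable, the fitting metric, and intermitotic-time arithmetic.

#' Precursor mass of a population
#'
#' The sum \eqn{\sum_i 2^{-N_i}} over all cells, where `N_i` is the division
#' round. Mitosis replaces one weight `2^-N` by two weights `2^-(N+1)`, so
#' this quantity is conserved exactly through any simulation; it is the
#' natural conservation diagnostic for the 2^n cpF normalisation. The sum is
#' accumulated over per-round counts in ascending round order, so for any
#' realistic population (counts x 2^(rounds) well below 2^53) it is exact in
#' double precision.
#'
#' @param pop A [CellPopulation-class].
#' @return A single number.
#' @export
precursorMass <- function(pop) {
  stopifnot(is(pop, "CellPopulation"))
  counts <- tabulate(pop@divisionRound + 1L)
  rounds <- seq_along(counts) - 1L
  sum(counts * 2^(-rounds))
}

#' Compute the cpF table of a population
#'
#' Counts cells per (phase, division round) bucket, weights each bucket by
#' `2^-round` so that every founding precursor contributes equal weight, and
#' expresses the weights as percentages of their total. Only occupied
#' buckets are reported.
#'
#' @param pop A [CellPopulation-class]; must be non-empty.
#' @param time Time label (hours) for the resulting rows; defaults to the
#'   population clock.
#' @return A [CpfTable-class] at a single time point.
#' @examples
#' pop <- cellPopulation(c("G1", "G1", "S", "S"), divisionRound = c(0, 0, 1, 1))
#' computeCpf(pop)  # weights 2 and 1 -> 66.67% and 33.33%
#' @export
computeCpf <- function(pop, time = pop@clock) {
  stopifnot(is(pop, "CellPopulation"))
  validObject(pop)
  key <- pop@divisionRound * 4L + pop@phase
  counts <- tabulate(key)
  idx <- which(counts > 0L)
  phase <- (idx - 1L) %% 4L + 1L
  round <- (idx - 1L) %/% 4L
  w <- counts[idx] * 2^(-round)
  cpfTable(time_h = time,
           phase = CYCLE_PHASES[phase],
           division_round = round,
           cpf_percent = 100 * w / sum(w))
}

#' Sum of squared cpF differences
#'
#' The fitting objective distance: tables are aligned on
#' (time, phase, division round), a bucket absent from one side counts as
#' 0%, and the squared percentage differences are summed over all aligned
#' keys. Only time points present in both tables enter the sum; it is an
#' error for the tables to share none.
#'
#' @param a,b [CpfTable-class] objects.
#' @return A non-negative number (squared percent units); 0 iff the tables
#'   agree on their common time points.
#' @examples
#' x <- cpfTable(0, "G1", 0L, 100)
#' y <- cpfTable(0, "S", 0L, 100)
#' cpfSsq(x, y)  # 100^2 + 100^2
#' @export
cpfSsq <- function(a, b) {
  stopifnot(is(a, "CpfTable"), is(b, "CpfTable"))
  da <- a@data
  db <- b@data
  common <- intersect(unique(da$time_h), unique(db$time_h))
  if (length(common) == 0L)
    stop("the two cpF tables share no time points")
  da <- da[da$time_h %in% common, , drop = FALSE]
  db <- db[db$time_h %in% common, , drop = FALSE]
  m <- merge(da, db, by = c("time_h", "phase", "division_round"),
             all = TRUE, suffixes = c("_a", "_b"))
  pa <- ifelse(is.na(m$cpf_percent_a), 0, m$cpf_percent_a)
  pb <- ifelse(is.na(m$cpf_percent_b), 0, m$cpf_percent_b)
  sum((pa - pb)^2)
}

#' Intermitotic time of a division round
#'
#' The total cell-cycle duration implied by a law table for one division
#' round: the sum of the four phase location parameters
#' \eqn{\mu_{G1} + \mu_S + \mu_{G2} + \mu_M}, interpreting each location as
#' the phase's interphase time.
#'
#' @param laws A [PhaseLawTable-class].
#' @param round Division round (non-negative integer).
#' @return Hours.
#' @examples
#' intermitoticTime(referenceLaws(), 1)  # 29.43
#' @export
intermitoticTime <- function(laws, round) {
  stopifnot(is(laws, "PhaseLawTable"))
  validObject(laws)
  if (!is.numeric(round) || length(round) != 1L || round < 0 ||
      round != floor(round))
    stop("'round' must be a single non-negative integer")
  col <- if (round == 0) 1L else 2L
  sum(laws@location[, col])
}

#' Subset a cpF table by time point
#'
#' @param cpf A [CpfTable-class].
#' @param times Numeric times (hours) to keep; must all be present.
#' @return A [CpfTable-class] restricted to `times`.
#' @export
cpfAt <- function(cpf, times) {
  stopifnot(is(cpf, "CpfTable"))
  d <- cpfData(cpf)
  missing <- setdiff(times, d$time_h)
  if (length(missing))
    stop("time point(s) not in table: ", paste(missing, collapse = ", "))
  d <- d[d$time_h %in% times, , drop = FALSE]
  cpfTable(d$time_h, d$phase, d$division_round, d$cpf_percent)
}
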