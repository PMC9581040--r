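## GEV distribution functions and the discrete-time transition hazard.
## Closed form for xi > 0: F(t) = exp(-[1 + xi (t - mu)/sigma]^(-1/xi))
## for t above the support endpoint mu - sigma/xi, and 0 below it.

#' GEV cumulative distribution function
#'
#' Evaluates the cumulative distribution function of a [GevLaw-class] at the
#' given times. For shape `xi > 0` the CDF is exactly 0 at and below the
#' lower support endpoint `mu - sigma/xi` and tends to 1 as `t` grows.
#'
#' @param t Numeric vector of times (hours); must be finite.
#' @param law A [GevLaw-class].
#' @return Probabilities in `[0, 1]`, one per element of `t`.
#' @examples
#' law <- GevLaw(10, 1, 0.68)
#' gevCdf(c(8, 10, 12), law)
#' @export
gevCdf <- function(t, law) {
  stopifnot(is(law, "GevLaw"))
  validObject(law)
  if (!is.numeric(t) || length(t) == 0L || any(!is.finite(t)))
    stop("'t' must be finite numeric time(s)")
  z <- 1 + law@shape * (t - law@location) / law@scale
  out <- numeric(length(t))
  pos <- z > 0
  out[pos] <- exp(-z[pos]^(-1 / law@shape))
  out
}

#' GEV quantile function (internal)
#'
#' Inverse of [gevCdf()] for `0 < p < 1`.
#' @noRd
gevQuantile <- function(p, law) {
  law@location + law@scale / law@shape * ((-log(p))^(-law@shape) - 1)
}

#' Discrete-time transition hazard
#'
#' Probability that a cell which has resided in its phase for time `t`
#' without transitioning does so within the next step of length `dT`:
#' \deqn{P(\delta T, t) = \frac{F(t + \delta T) - F(t)}{1 - F(t)}}
#' where `F` is the phase law's CDF. The hazard is 0 while `t + dT` is below
#' the law's support endpoint (cells must reside in a phase for a finite
#' minimum duration before exiting) and, because the laws are heavy-tailed
#' (`xi > 0`), it eventually decreases in `t`: the longer a cell has resided
#' in a phase the less likely it becomes to exit in the next step.
#'
#' @param t Time(s) already spent in the phase (hours, >= 0).
#' @param dT Step length (hours, >= 0).
#' @param law A [GevLaw-class].
#' @param guard Numeric guard: when the survival `1 - F(t)` falls below
#'   `guard` the hazard is reported as 1 (transition certain) instead of
#'   risking division blow-up. Default `1e-12`.
#' @return Probabilities in `[0, 1]`, one per element of `t`.
#' @examples
#' hazardStep(10, 2, GevLaw(10, 1, 0.68))
#' @export
hazardStep <- function(t, dT, law, guard = 1e-12) {
  stopifnot(is(law, "GevLaw"))
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stop("'t' must be finite non-negative time(s)")
  if (!is.numeric(dT) || length(dT) != 1L || !is.finite(dT) || dT < 0)
    stop("'dT' must be a single non-negative step length")
  if (dT == 0) return(numeric(length(t)))
  f0 <- gevCdf(t, law)
  f1 <- gevCdf(t + dT, law)
  surv <- 1 - f0
  p <- ifelse(surv < guard, 1, (f1 - f0) / surv)
  pmin(pmax(p, 0), 1)
}

#' Sample phase residence times through the discrete hazard chain
#'
#' Starts `n` cells at time 0 in a single phase governed by `law` and steps
#' them through the same simulation kernel used by [simulatePopulation()]
#' (no blocking, no further transitions after the exit) until they leave the
#' phase. A cell exiting during the step from `t` to `t + dT` is recorded at
#' the step midpoint `t + dT/2`. As `dT` shrinks the empirical distribution
#' of these exit times converges to the law itself, which makes this the
#' standard check that the hazard chain samples the intended residence-time
#' distribution.
#'
#' @param law A [GevLaw-class].
#' @param n Number of cells.
#' @param dT Step length in hours.
#' @param tMax Censoring horizon; cells still resident at `tMax` are
#'   recorded there. Defaults to the law's 1 - 1e-4 quantile, so at most a
#'   fraction 1e-4 of cells are expected to be censored.
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` exit times (hours).
#' @examples
#' x <- residenceTimes(GevLaw(10, 1), n = 500, dT = 0.1, seed = 1)
#' @export
residenceTimes <- function(law, n, dT, tMax = NULL, seed = NULL) {
  stopifnot(is(law, "GevLaw"), n >= 1, dT > 0)
  validObject(law)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tMax)) tMax <- gevQuantile(1 - 1e-4, law)
  far <- 1e6  # parking laws for the other phases, never reached
  loc <- matrix(far, 4, 2, dimnames = list(CYCLE_PHASES, NULL))
  sc <- matrix(1, 4, 2)
  loc["G1", 2L] <- law@location
  sc[1L, 2L] <- law@scale
  exit <- rep(tMax, n)
  ids <- seq_len(n)   # indices of cells still resident
  tt <- numeric(n)
  b <- numeric(4)
  step <- 0L
  while (length(ids) > 0L && step * dT < tMax) {
    k <- length(ids)
    st <- cpp_advance(rep(1L, k), tt, rep(1L, k), rep(FALSE, k),
                      loc, sc, law@shape, b, FALSE, dT, 1e-12)
    step <- step + 1L
    left <- st$phase != 1L
    exit[ids[left]] <- (step - 0.5) * dT
    ids <- ids[!left]
    tt <- st$t[!left]
  }
  exit
}
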