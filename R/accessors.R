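## Accessors and show methods.

#' @rdname CpfTable-class
#' @param x A `CpfTable`.
#' @return `cpfData` returns the underlying `data.frame` with columns
#'   `time_h`, `phase`, `division_round`, `cpf_percent`.
#' @export
cpfData <- function(x) {
  stopifnot(is(x, "CpfTable"))
  x@data
}

#' @export
#' @describeIn CpfTable-class Coerce to `data.frame`.
#' @param row.names,optional,... Passed on for the `as.data.frame` generic.
as.data.frame.CpfTable <- function(x, row.names = NULL, optional = FALSE,
                                   ...) {
  x@data
}

#' Look up the residence-time law of one (phase, round)
#'
#' @param laws A [PhaseLawTable-class].
#' @param phase Phase label (`"G1"`, `"S"`, `"G2"`, `"M"`).
#' @param round Division round (>= 0); all rounds >= 1 share one law.
#' @return A [GevLaw-class].
#' @examples
#' lawFor(referenceLaws(), "G1", 2)
#' @export
lawFor <- function(laws, phase, round) {
  stopifnot(is(laws, "PhaseLawTable"))
  if (!phase %in% CYCLE_PHASES) stop("unknown phase label: ", phase)
  if (round < 0) stop("'round' must be >= 0")
  col <- if (round == 0) 1L else 2L
  GevLaw(laws@location[phase, col], laws@scale[phase, col], laws@shape)
}

#' @rdname CellPopulation-class
#' @param x A `CellPopulation`.
#' @return `cellCount` returns the number of cells.
#' @export
cellCount <- function(x) {
  stopifnot(is(x, "CellPopulation"))
  length(x@phase)
}

#' @rdname CellPopulation-class
#' @return `cellStates` returns a per-cell `data.frame` with columns
#'   `cell_id`, `phase`, `t_hours`, `division_round`, `arrested`.
#' @export
cellStates <- function(x) {
  stopifnot(is(x, "CellPopulation"))
  data.frame(cell_id = seq_along(x@phase),
             phase = CYCLE_PHASES[x@phase],
             t_hours = x@timeInPhase,
             division_round = x@divisionRound,
             arrested = x@arrested)
}

setMethod("show", "GevLaw", function(object) {
  cat(sprintf(
    "GevLaw: location %.4g h, scale %.4g h, shape %.3g (support from %.4g h)\n",
    object@location, object@scale, object@shape,
    object@location - object@scale / object@shape))
})

setMethod("show", "PhaseLawTable", function(object) {
  cat("PhaseLawTable (shape", object@shape, ")\n")
  df <- data.frame(mu_round0 = object@location[, 1L],
                   mu_later = object@location[, 2L],
                   sigma_round0 = object@scale[, 1L],
                   sigma_later = object@scale[, 2L])
  print(df)
  cat(sprintf("intermitotic time: %.4g h (round 0), %.4g h (rounds >= 1)\n",
              intermitoticTime(object, 0), intermitoticTime(object, 1)))
})

setMethod("show", "BlockingPolicy", function(object) {
  cat("BlockingPolicy: drug at", object@drugTime, "h; b =",
      paste(sprintf("%s %.3g", names(object@prob), object@prob),
            collapse = ", "), "\n")
})

setMethod("show", "CellPopulation", function(object) {
  cat(sprintf(
    "CellPopulation: %d cells at T = %.3g h (%d arrested), precursor mass %.6g\n",
    length(object@phase), object@clock, sum(object@arrested),
    precursorMass(object)))
  print(table(phase = CYCLE_PHASES[object@phase],
              round = object@divisionRound))
})

setMethod("show", "CpfTable", function(object) {
  times <- unique(object@data$time_h)
  cat(sprintf("CpfTable: %d rows at %d time point(s) (%s h)\n",
              nrow(object@data), length(times),
              paste(times, collapse = ", ")))
  print(utils::head(object@data, 12L))
  if (nrow(object@data) > 12L) cat("...\n")
})

setMethod("show", "SimulationResult", function(object) {
  cat("SimulationResult over", nSteps(object@schedule), "steps of",
      object@schedule@dT, "h\n")
  show(object@cpf)
})

setMethod("show", "SyntheticExperiment", function(object) {
  cat(sprintf("SyntheticExperiment (seed %d, noise %.3g%%, %s)\n",
              object@seed, object@noisePct,
              if (is.null(object@truthBlocking)) "untreated" else "treated"))
  show(object@observations)
})

setMethod("show", "CycleFit", function(object) {
  cat(sprintf("CycleFit (%s): %d replicate(s)\n", object@kind,
              nrow(object@replicates)))
  print(data.frame(estimate = object@estimate, stderr = object@stderr))
  if (length(object@objectives))
    cat("best objectives:", paste(signif(object@objectives, 4),
                                  collapse = ", "), "\n")
})
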