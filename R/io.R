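## File formats: the cpF CSV and the parameter JSON, plus run presets.

CPF_HEADER <- c("time_h", "phase", "division_round", "cpf_percent")

#' Write a cpF table to CSV
#'
#' Comma-separated UTF-8 with header `time_h,phase,division_round,
#' cpf_percent`, `.` decimal separator, percentages serialized with 6
#' significant digits (far below the 14% experimental error). Zero-count
#' buckets are omitted; [cpfSsq()] treats absent buckets as 0%.
#'
#' @param cpf A [CpfTable-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeCpfCsv <- function(cpf, path) {
  stopifnot(is(cpf, "CpfTable"))
  validObject(cpf)
  d <- cpfData(cpf)
  d$cpf_percent <- formatC(signif(d$cpf_percent, 6), format = "g",
                           digits = 6)
  d$time_h <- formatC(d$time_h, format = "g", digits = 6)
  utils::write.table(d, path, sep = ",", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cpF table from CSV
#'
#' Validates the header, phase labels, division rounds and percentages, and
#' that percentages sum to 100 at every time point within a tolerance of
#' 1e-3 (loose enough for files rounded to 6 significant digits); each
#' failure is reported with the offending line numbers or time points.
#' After validation the percentages are rescaled to sum to exactly 100.
#'
#' @param path Input file path.
#' @return A [CpfTable-class].
#' @export
readCpfCsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("'%s' does not exist", path))
  if (file.size(path) == 0L) stop(sprintf("'%s' contains no rows", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(d), CPF_HEADER))
    stop(sprintf("malformed header in '%s': expected %s", path,
                 paste(CPF_HEADER, collapse = ",")))
  if (nrow(d) == 0L) stop(sprintf("'%s' contains no rows", path))
  if (!is.numeric(d$division_round)) d$division_round <- suppressWarnings(
    as.numeric(d$division_round))
  if (!is.numeric(d$cpf_percent)) d$cpf_percent <- suppressWarnings(
    as.numeric(d$cpf_percent))
  d$division_round[is.na(d$division_round)] <- -1
  d$cpf_percent[is.na(d$cpf_percent)] <- NaN
  line <- seq_len(nrow(d)) + 1L  # header is line 1
  bad <- !d$phase %in% CYCLE_PHASES
  if (any(bad))
    stop("unknown phase label(s) on line(s) ",
         paste(line[bad], collapse = ", "))
  bad <- !is.finite(d$division_round) | d$division_round < 0 |
    d$division_round != floor(d$division_round)
  if (any(bad))
    stop("invalid division round on line(s) ",
         paste(line[bad], collapse = ", "))
  bad <- !is.finite(d$cpf_percent) | d$cpf_percent < 0
  if (any(bad))
    stop("negative or non-numeric percentage on line(s) ",
         paste(line[bad], collapse = ", "))
  sums <- tapply(d$cpf_percent, d$time_h, sum)
  off <- abs(sums - 100) > 1e-3
  if (any(off))
    stop("percentages do not sum to 100 at time point(s) ",
         paste(names(sums)[off], collapse = ", "))
  scale <- 100 / sums[as.character(d$time_h)]
  cpfTable(d$time_h, d$phase, as.integer(d$division_round),
           d$cpf_percent * as.numeric(scale))
}

#' Write laws (and optional blocking/config) to a parameter JSON file
#'
#' The JSON makes the tying structure explicit: each of G1 and S carries a
#' `round0` and a `later` (rounds >= 1) law, G2 and M one law for all
#' rounds; the shape and the G2/M scales are listed under `fixed` to record
#' that they are never fit parameters.
#'
#' @param laws A [PhaseLawTable-class].
#' @param blocking Optional [BlockingPolicy-class].
#' @param config Optional run-configuration list (see [runConfig()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeParamsJson <- function(laws, path, blocking = NULL, config = NULL) {
  stopifnot(is(laws, "PhaseLawTable"))
  validObject(laws)
  lawOf <- function(p, col) list(mu = laws@location[p, col],
                                 sigma = laws@scale[p, col])
  x <- list(
    shape = laws@shape,
    fixed = list(shape = TRUE, sigma_G2 = TRUE, sigma_M = TRUE),
    phases = list(
      G1 = list(round0 = lawOf("G1", 1L), later = lawOf("G1", 2L)),
      S = list(round0 = lawOf("S", 1L), later = lawOf("S", 2L)),
      G2 = list(round0 = lawOf("G2", 1L), later = lawOf("G2", 2L)),
      M = list(round0 = lawOf("M", 1L), later = lawOf("M", 2L))))
  if (!is.null(blocking)) {
    stopifnot(is(blocking, "BlockingPolicy"))
    validObject(blocking)
    x$blocking <- c(as.list(blocking@prob),
                    list(drug_time_h = blocking@drugTime))
  }
  if (!is.null(config)) x$config <- config
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a parameter JSON file
#'
#' Validates the schema written by [writeParamsJson()]: the shape and every
#' per-phase `round0`/`later` law must be present, scales must be positive,
#' supports non-negative, and blocking probabilities (when present) must lie
#' in `[0, 1]`. Missing or out-of-range fields are reported by name.
#'
#' @param path Input file path.
#' @return List with elements `laws` ([PhaseLawTable-class]), `blocking`
#'   ([BlockingPolicy-class] or `NULL`) and `config` (list or `NULL`).
#' @export
readParamsJson <- function(path) {
  if (!file.exists(path)) stop(sprintf("'%s' does not exist", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$shape)) stop("parameter file is missing field 'shape'")
  if (is.null(x$phases)) stop("parameter file is missing field 'phases'")
  loc <- matrix(NA_real_, 4, 2)
  sc <- matrix(NA_real_, 4, 2)
  for (i in seq_along(CYCLE_PHASES)) {
    p <- CYCLE_PHASES[i]
    ph <- x$phases[[p]]
    if (is.null(ph)) stop("parameter file is missing phase '", p, "'")
    for (j in 1:2) {
      entry <- ph[[c("round0", "later")[j]]]
      if (is.null(entry) || is.null(entry$mu) || is.null(entry$sigma))
        stop(sprintf("phase '%s' is missing the '%s' law (mu, sigma)", p,
                     c("round0", "later")[j]))
      loc[i, j] <- entry$mu
      sc[i, j] <- entry$sigma
    }
  }
  laws <- phaseLawTable(loc, sc, shape = x$shape)
  validObject(laws)
  blocking <- NULL
  if (!is.null(x$blocking)) {
    b <- unlist(x$blocking[CYCLE_PHASES])
    if (length(b) != 4L || anyNA(b))
      stop("'blocking' must give probabilities for G1, S, G2 and M")
    if (any(b < 0 | b > 1))
      stop("blocking probabilities for ",
           paste(CYCLE_PHASES[b < 0 | b > 1], collapse = ", "),
           " are outside [0, 1]")
    dt <- x$blocking$drug_time_h
    blocking <- blockingPolicy(b, if (is.null(dt)) 32 else dt)
  }
  list(laws = laws, blocking = blocking, config = x$config)
}

#' Run-configuration presets
#'
#' Bundles the settings of a complete analysis run. The `"production"`
#' preset is the full experimental-analysis configuration: 20000 cells, 200
#' steps of 0.36 h over 72 h, observations at 0/32/48/72 h, drug at 32 h,
#' 100 fit replicates and 100 DE generations. The `"test"` preset keeps the
#' same model but shrinks the budget to desk scale: 2000 cells, 3
#' replicates, 40 generations.
#'
#' @param preset `"production"` or `"test"`.
#' @return List with elements `nCells`, `schedule`, `drugTime`,
#'   `nReplicates`, `deControl`, `bounds`, `initTimeMax`, `noisePct`.
#' @export
runConfig <- function(preset = c("production", "test")) {
  preset <- match.arg(preset)
  base <- list(schedule = schedule(dT = 0.36, tEnd = 72,
                                   observationTimes = c(0, 32, 48, 72)),
               drugTime = 32, bounds = defaultFitBounds(),
               initTimeMax = 25, noisePct = 14)
  if (preset == "production")
    c(base, list(nCells = 20000, nReplicates = 100,
                 deControl = deControl(maxGen = 100)))
  else
    c(base, list(nCells = 2000, nReplicates = 3,
                 deControl = deControl(maxGen = 40)))
}
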