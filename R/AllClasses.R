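#' PopulationSnapshot: census of a world at one update
#'
#' Holds the occupied cells of a world at a given update: the genome of
#' every organism (a 120-character instruction string), its lattice cell,
#' merit, facing direction and lifetime task counts, together with the
#' condition metadata of the run that produced it.
#'
#' @slot genomes character vector of 120-character genome strings.
#' @slot cell integer vector, 1-based lattice cell index of each organism.
#' @slot merit numeric vector of merits (execution-speed weights).
#' @slot facing integer vector in 0..7, the faced neighbor direction.
#' @slot taskCounts integer matrix (organisms x 9) of lifetime task
#'   performances, columns in task-table order.
#' @slot update integer, the update at which the census was taken.
#' @slot condition named list of run metadata (mutationRate, resource,
#'   worldSize, replicate, ...).
#'
#' @seealso [genomes()], [merits()], [taskCounts()], [runSimulation()]
#' @export
setClass("PopulationSnapshot",
  representation(
    genomes = "character",
    cell = "integer",
    merit = "numeric",
    facing = "integer",
    taskCounts = "matrix",
    update = "integer",
    condition = "list"
  ),
  prototype(
    genomes = character(), cell = integer(), merit = numeric(),
    facing = integer(), taskCounts = matrix(0L, 0, 9), update = 0L,
    condition = list()
  )
)

setValidity("PopulationSnapshot", function(object) {
  n <- length(object@genomes)
  msg <- character()
  if (n > 0 && any(nchar(object@genomes) != 120L))
    msg <- c(msg, "all genomes must be exactly 120 instruction codes long")
  if (length(object@cell) != n || length(object@merit) != n ||
      length(object@facing) != n)
    msg <- c(msg, "cell, merit and facing must match the number of genomes")
  if (nrow(object@taskCounts) != n || ncol(object@taskCounts) != 9L)
    msg <- c(msg, "taskCounts must be an organisms x 9 matrix")
  if (anyDuplicated(object@cell))
    msg <- c(msg, "each organism must occupy a distinct cell")
  if (length(msg)) msg else TRUE
})

#' EvolutionRun: a complete evolutionary run
#'
#' The result of [runSimulation()]: the per-update event log, the final
#' population census, any periodic censuses, and the configuration used.
#'
#' @slot log data.frame with columns update, births, deaths, population
#'   (organisms at the start of the update, i.e. the scheduler census),
#'   meanMerit, cycles (CPU cycles executed, exactly 30 x population).
#' @slot snapshot the final [PopulationSnapshot-class].
#' @slot snapshots list of periodic intermediate snapshots (may be empty).
#' @slot config named list of run parameters.
#' @slot extinct logical, whether the population died out before the end.
#'
#' @seealso [eventLog()], [finalSnapshot()]
#' @export
setClass("EvolutionRun",
  representation(
    log = "data.frame",
    snapshot = "PopulationSnapshot",
    snapshots = "list",
    config = "list",
    extinct = "logical"
  ),
  prototype(extinct = FALSE)
)

setValidity("EvolutionRun", function(object) {
  need <- c("update", "births", "deaths", "population", "meanMerit", "cycles")
  if (!all(need %in% names(object@log)))
    return("log must have update, births, deaths, population, meanMerit, cycles")
  if (any(object@log$births < 0) || any(object@log$deaths < 0))
    return("births and deaths must be nonnegative")
  TRUE
})

setMethod("show", "PopulationSnapshot", function(object) {
  cat("PopulationSnapshot:", length(object@genomes), "organisms at update",
      object@update, "\n")
  if (length(object@genomes)) {
    ng <- length(unique(object@genomes))
    cat("  distinct genotypes:", ng, "\n")
    cat("  merit range: [", format(min(object@merit), digits = 4), ", ",
        format(max(object@merit), digits = 4), "]\n", sep = "")
  }
  if (length(object@condition)) {
    cat("  condition:",
        paste(names(object@condition),
              vapply(object@condition, format, ""), sep = "=",
              collapse = ", "), "\n")
  }
})

setMethod("show", "EvolutionRun", function(object) {
  n <- nrow(object@log)
  cat("EvolutionRun:", n, "updates,",
      length(object@snapshot@genomes), "organisms at the end\n")
  cat("  total births:", sum(object@log$births),
      " deaths:", sum(object@log$deaths),
      if (object@extinct) " [EXTINCT]" else "", "\n")
})
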