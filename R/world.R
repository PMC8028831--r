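#' Near-square world dimensions for a given site count
#'
#' @param n total number of lattice sites.
#' @return Integer vector \code{c(width, height)} with \code{width *
#'   height == n}, as close to square as the factorization allows.
#' @examples
#' worldDims(50)   # 5 x 10
#' @export
worldDims <- function(n) {
  stopifnot(n >= 1)
  w <- floor(sqrt(n))
  while (n %% w != 0) w <- w - 1
  as.integer(c(w, n / w))
}

#' Eight toroidal neighbors of a lattice cell
#'
#' @param width,height world dimensions.
#' @param cell 1-based cell index (row-major).
#' @return Integer vector of the 8 neighbor cell indices (1-based), in
#'   the facing order N, NE, E, SE, S, SW, W, NW.
#' @export
neighborCells <- function(width, height, cell) {
  stopifnot(cell >= 1, cell <= width * height)
  cpp_neighbors(as.integer(width), as.integer(height), as.integer(cell - 1)) + 1L
}

.asSnapshot <- function(fin, condition = list()) {
  new("PopulationSnapshot",
      genomes = as.character(fin$genome),
      cell = as.integer(fin$cell) + 1L,
      merit = as.numeric(fin$merit),
      facing = as.integer(fin$facing),
      taskCounts = {
        m <- fin$taskCounts
        colnames(m) <- taskTable()$task
        m
      },
      update = as.integer(fin$update),
      condition = condition)
}

#' Run an evolutionary simulation
#'
#' Seeds one or more organisms in a toroidal world and iterates updates.
#' Per update, 30 x N CPU cycles (N the population size at the start of
#' the update) are allocated across organisms proportionally to merit by
#' largest-remainder rounding, so the total is exact; the per-cell quota
#' is inherited by an offspring that replaces an occupant mid-update.
#' Organisms die only by replacement.  Messages are collected during the
#' update and delivered at its end; the chemostat then relaxes every
#' resource toward its target level and diffuses it laterally.  Mutation
#' is a whole-genome substitution pass applied to the offspring at divide.
#'
#' @param ancestor genome string(s) to seed; defaults to [buildAncestor()].
#' @param worldSize total number of lattice sites (factorized near-square),
#'   used when \code{dims} is not given.
#' @param updates number of updates to run.
#' @param mutationRate per-site substitution probability on divide.
#' @param resource target steady-state resource level per site.
#' @param env environment parameter list from [defaultEnvironment()];
#'   \code{resource} overrides its level.
#' @param seed integer seed; when non-NULL, \code{set.seed} is called so
#'   the run is fully reproducible.
#' @param dims optional explicit \code{c(width, height)}.
#' @param startCell 1-based cell(s) for the seeded organisms; defaults to
#'   cell 1 (and subsequent cells for multiple seeds).
#' @param startFacing initial facing(s) 0..7, or -1 for a seeded random
#'   draw.
#' @param cyclesPerOrganism mean CPU cycles per organism per update.
#' @param snapshotEvery record an intermediate census every this many
#'   updates (0 = none).
#' @param condition optional named list of metadata stored in the
#'   snapshots (replicate id, treatment labels, ...).
#' @return An [EvolutionRun-class] object.
#' @examples
#' run <- runSimulation(updates = 50, worldSize = 25, mutationRate = 0,
#'                      resource = 100, seed = 1)
#' eventLog(run)[1:5, ]
#' @export
runSimulation <- function(ancestor = buildAncestor(), worldSize = 50,
                          updates = 1000, mutationRate = 7.5e-4,
                          resource = 100, env = defaultEnvironment(resource),
                          seed = NULL, dims = NULL, startCell = NULL,
                          startFacing = -1L, cyclesPerOrganism = 30,
                          snapshotEvery = 0, condition = list()) {
  parseGenome(ancestor)
  stopifnot(mutationRate >= 0, mutationRate <= 1, updates >= 0)
  if (is.null(dims)) dims <- worldDims(worldSize)
  n <- as.integer(dims[1] * dims[2])
  if (!is.null(seed)) set.seed(seed)
  k <- length(ancestor)
  if (is.null(startCell)) startCell <- seq_len(k)
  stopifnot(length(startCell) == k, all(startCell >= 1), all(startCell <= n))
  startFacing <- rep_len(as.integer(startFacing), k)

  res <- cpp_run_world(dims[1], dims[2], as.integer(startCell - 1L),
                       ancestor, startFacing, rep(120, k),
                       as.integer(updates), mutationRate, env$resource,
                       env$uptake, env$cmax, env$delta, env$diffusion,
                       as.integer(cyclesPerOrganism), as.integer(snapshotEvery))

  cond <- c(condition,
            list(mutationRate = mutationRate, resource = env$resource,
                 worldSize = n))
  new("EvolutionRun",
      log = res$log,
      snapshot = .asSnapshot(res$final, cond),
      snapshots = lapply(res$snapshots, .asSnapshot, condition = cond),
      config = list(dims = dims, updates = updates,
                    mutationRate = mutationRate, env = env, seed = seed,
                    cyclesPerOrganism = cyclesPerOrganism),
      extinct = isTRUE(res$extinct))
}

#' Most frequent genotype of a snapshot
#'
#' @param x a [PopulationSnapshot-class] (or [EvolutionRun-class], whose
#'   final snapshot is used).
#' @return The most frequent genome string (ties: first in cell order).
#' @export
dominantGenotype <- function(x) {
  if (is(x, "EvolutionRun")) x <- finalSnapshot(x)
  g <- genomes(x)
  if (!length(g)) return(NA_character_)
  names(which.max(table(factor(g, levels = unique(g)))))
}
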