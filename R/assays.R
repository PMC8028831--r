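# Per-genotype measurement procedures: population fitness assay, isolation
# merit/gestation, viability, phenotype profile, marginal utility, task
# complexity.

.ancestorGestationCache <- new.env(parent = emptyenv())

#' Gestation of the ancestor in isolation (cycles)
#'
#' Used as the unit for assay cycle budgets (default budget: 10x this).
#' @return Number of cycles from birth to first divide of the ancestor.
#' @export
ancestorGestation <- function() {
  if (is.null(.ancestorGestationCache$g)) {
    r <- cpp_isolation_run(buildAncestor(), 100000L, 0, 1e4, 0.0025, 1,
                           TRUE, FALSE)
    stopifnot(r$divided)
    .ancestorGestationCache$g <- r$gestation
  }
  .ancestorGestationCache$g
}

#' Population fitness assay (births per update)
#'
#' Places 200 copies of a genotype in a dedicated assay world, lets the
#' population stabilize for 100 updates, and returns the mean number of
#' births per update over the following 400 updates.  The mutation rate is
#' zero throughout, so the genotype cannot evolve; because the world is
#' monoclonal, the assay captures fitness benefits of signaling between
#' organisms of the same genotype.
#'
#' @param x character vector of genome strings.
#' @param copies number of copies seeded.
#' @param dims assay world dimensions (default 15 x 15 = 225 cells).
#' @param resource steady-state resource level of the assay environment.
#' @param stabilize updates discarded before measuring.
#' @param measure updates measured.
#' @param seed integer seed; each genome is assayed from the same seed so
#'   that genotypes are compared under identical conditions.
#' @return Numeric vector of fitness values (births/update), one per
#'   genome.
#' @export
fitnessAssay <- function(x, copies = 200, dims = c(15, 15), resource = 10000,
                         stabilize = 100, measure = 400, seed = 1) {
  parseGenome(x)
  n <- prod(dims)
  stopifnot(copies <= n)
  env <- defaultEnvironment(resource)
  vapply(x, function(g) {
    set.seed(seed)
    cells <- sample.int(n, copies) - 1L
    r <- cpp_run_world(dims[1], dims[2], cells, rep(g, copies),
                       rep(-1L, copies), rep(120, copies),
                       as.integer(stabilize + measure), 0, env$resource,
                       env$uptake, env$cmax, env$delta, env$diffusion,
                       30L, 0L)
    if (nrow(r$log) < stabilize + measure) return(0)
    mean(r$log$births[(stabilize + 1):(stabilize + measure)])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Merit, gestation and internal fitness in isolation
#'
#' Runs each genotype alone with saturating resources and no neighbors.
#' Merit is measured at the first divide (base 120 times one plus the
#' accumulated task bonus); gestation is the number of CPU cycles to that
#' divide.  The platform-internal fitness metric is merit/gestation;
#' non-replicators get gestation Inf and fitness 0.
#'
#' @param x character vector of genome strings.
#' @param resource resource level of the isolation environment.
#' @param budget cycle budget (default 10x the ancestor gestation).
#' @param seed integer seed for the environmental input stream.
#' @return data.frame with columns \code{merit}, \code{gestation},
#'   \code{fitness} (merit/gestation), \code{divided}, \code{faithful}
#'   (offspring identical to parent).
#' @export
isolationAssay <- function(x, resource = 10000, budget = NULL, seed = 1) {
  parseGenome(x)
  if (is.null(budget)) budget <- 10 * ancestorGestation()
  env <- defaultEnvironment(resource)
  rows <- lapply(x, function(g) {
    set.seed(seed)
    r <- cpp_isolation_run(g, as.integer(budget), 0, env$resource,
                           env$uptake, env$cmax, TRUE, FALSE)
    data.frame(merit = r$merit, gestation = r$gestation,
               fitness = if (r$divided) r$merit / r$gestation else 0,
               divided = r$divided,
               faithful = isTRUE(r$divided) && identical(r$offspring, g))
  })
  do.call(rbind, rows)
}

#' Viability of a set of genotypes
#'
#' The fraction of genomes able to replicate faithfully under high
#' resource conditions within the cycle budget: a genome is viable when
#' it divides at least once in isolation and the offspring genome is
#' identical to its own (a partially copied, largely nop-X offspring does
#' not count).
#'
#' @param x character vector of genome strings.
#' @param resource resource level (high-resource by definition).
#' @param budget cycle budget (default 10x the ancestor gestation).
#' @param seed integer seed.
#' @return Fraction in [0, 1].
#' @export
viability <- function(x, resource = 10000, budget = NULL, seed = 1) {
  stopifnot(length(x) >= 1)
  a <- isolationAssay(x, resource = resource, budget = budget, seed = seed)
  mean(a$faithful)
}

#' Phenotype profile of a genotype
#'
#' Executes the genome once through gestation (or the cycle budget) in an
#' isolated test harness with a seeded environmental input stream, and
#' records which of the nine tasks were performed and how many times.
#' With nine binary task states there are 512 possible phenotypes.
#'
#' @param x character vector of genome strings.
#' @param budget cycle budget (default 10x the ancestor gestation).
#' @param seed integer seed for the scripted input stream.
#' @return A list with \code{counts} (genomes x 9 integer matrix),
#'   \code{performs} (logical matrix), and \code{class} (integer phenotype
#'   class, 1..512).
#' @export
phenotypeProfile <- function(x, budget = NULL, seed = 1) {
  parseGenome(x)
  if (is.null(budget)) budget <- 10 * ancestorGestation()
  counts <- t(vapply(x, function(g) {
    set.seed(seed)
    r <- cpp_isolation_run(g, as.integer(budget), 0, 1e4, 0.0025, 1,
                           TRUE, FALSE)
    as.integer(r$taskCounts)
  }, integer(9), USE.NAMES = FALSE))
  colnames(counts) <- taskTable()$task
  performs <- counts > 0
  list(counts = counts, performs = performs,
       class = phenotypeClass(performs))
}

#' Phenotype class index
#'
#' Maps a 9-long logical task vector (or a matrix of them) to its class
#' in 1..512; class 1 performs nothing, class 512 performs all nine.
#'
#' @param performs logical vector of length 9, or a matrix with 9 columns.
#' @return Integer class index/indices.
#' @export
phenotypeClass <- function(performs) {
  if (is.null(dim(performs))) performs <- matrix(performs, nrow = 1)
  stopifnot(ncol(performs) == 9)
  as.integer(performs %*% 2^(0:8)) + 1L
}

#' Marginal utility of a process for a genotype
#'
#' The fractional fitness lost when all instructions enabling the process
#' are replaced by the null instruction nop-X:
#' \deqn{U = (F - F_{ko}) / F}
#' with both fitness values measured by [fitnessAssay()] under the same
#' seed and configuration.  By contract the utility is 0 when the genome
#' contains no instruction of the process, and 1 when the knockout is
#' lethal; it is NA (flagged) when the intact genotype itself has zero
#' fitness.
#'
#' @param x character vector of genome strings.
#' @param process preset (\code{"messaging"}, \code{"copying"},
#'   \code{"rotation"}) or instruction-name vector; see
#'   [knockoutInstructions()].
#' @param seed,resource,copies,dims assay configuration, passed to
#'   [fitnessAssay()].
#' @return Numeric vector of utilities.
#' @export
marginalUtility <- function(x, process = "messaging", seed = 1,
                            resource = 10000, copies = 200, dims = c(15, 15)) {
  parseGenome(x)
  codes <- .processCodes(process)
  pat <- paste0("[", paste(codes, collapse = ""), "]")
  vapply(x, function(g) {
    if (!grepl(pat, g)) return(0)          # process absent
    f <- fitnessAssay(g, copies = copies, dims = dims, resource = resource,
                      seed = seed)
    if (f == 0) return(NA_real_)           # undefined for dead genotypes
    ko <- knockoutInstructions(g, process)
    fko <- fitnessAssay(ko, copies = copies, dims = dims,
                        resource = resource, seed = seed)
    (f - fko) / f
  }, numeric(1), USE.NAMES = FALSE)
}

.complexityCache <- new.env(parent = emptyenv())

#' Minimum NAND-gate complexity of a task
#'
#' The complexity of a task is the minimum number of two-input NAND gates
#' needed to compute its logic from the two inputs.  Because all task
#' logic is bitwise, the search reduces to Boolean functions of two bits:
#' a breadth-first enumeration over the 16 such functions, starting from
#' the projections A and B and closing under NAND, yields the exact
#' minimum.  The table is computed once and cached.
#'
#' @param task optional task name; when NULL the full named vector is
#'   returned in task-table order.
#' @return Integer complexity (or named vector of all nine).
#' @examples
#' taskComplexity("EQU")  # 5
#' @export
taskComplexity <- function(task = NULL) {
  if (is.null(.complexityCache$tab)) {
    # Boolean functions of (A, B) as 4-bit truth tables, ids 0..15.
    # Gate sharing is allowed, so the search runs over *sets* of computed
    # functions: a state is the set of truth tables available so far, and
    # one step adds the NAND of any two available functions.
    tt <- function(f) sum(f * c(1L, 2L, 4L, 8L))
    A <- c(0L, 1L, 0L, 1L)                  # (A,B) = 00, 10, 01, 11
    B <- c(0L, 0L, 1L, 1L)
    idA <- tt(A); idB <- tt(B)
    nandTab <- outer(0:15, 0:15, function(i, j)
      bitwAnd(15L, bitwNot(bitwAnd(i, j))))
    bit <- 2L^(0:15)
    logic <- list(
      NOT = 1L - A, NAND = 1L - (A & B), AND = A & B, ORN = A | (1L - B),
      OR = A | B, ANDN = A & (1L - B), NOR = 1L - (A | B),
      XOR = as.integer(xor(A, B)), EQU = 1L - as.integer(xor(A, B)))
    needed <- vapply(logic, function(f) tt(as.integer(f)) + 1L, integer(1))
    start <- bit[idA + 1] + bit[idB + 1]
    firstSeen <- rep(NA_integer_, 16)
    firstSeen[c(idA, idB) + 1] <- 0L
    frontier <- start
    seen <- new.env(parent = emptyenv())
    assign(as.character(start), TRUE, envir = seen)
    gates <- 0L
    while (length(frontier) && anyNA(firstSeen[needed])) {
      gates <- gates + 1L
      nxt <- integer(0)
      for (mask in frontier) {
        avail <- which(bitwAnd(mask, bit) != 0L)  # 1-based function ids
        for (i in avail) for (j in avail) {
          k <- nandTab[i, j] + 1L
          nm <- bitwOr(mask, bit[k])
          if (is.na(firstSeen[k])) firstSeen[k] <- gates
          key <- as.character(nm)
          if (nm != mask && !exists(key, envir = seen, inherits = FALSE)) {
            assign(key, TRUE, envir = seen)
            nxt <- c(nxt, nm)
          }
        }
      }
      frontier <- nxt
      if (gates > 8) break  # every 2-input function needs at most a few gates
    }
    .complexityCache$tab <- setNames(firstSeen[needed], names(needed))
  }
  tab <- .complexityCache$tab
  if (is.null(task)) tab else {
    stopifnot(task %in% names(tab))
    unname(tab[task])
  }
}

#' Joint phenotype of two genotypes sharing a world
#'
#' Places the two genomes in adjacent cells of a small world (facing each
#' other), runs with mutation zero, and accumulates the task performances
#' of each seeded genotype and its faithful descendants.  Cooperative
#' phenotypes appear here as tasks with positive counts that neither
#' genotype performs in isolation.
#'
#' @param a,b genome strings.
#' @param updates number of updates to run.
#' @param dims world dimensions.
#' @param resource resource level.
#' @param seed integer seed.
#' @return 2 x 9 integer matrix of task performance totals (rows a, b).
#' @export
jointPhenotype <- function(a, b, updates = 150, dims = c(5, 5),
                           resource = 10000, seed = 1) {
  parseGenome(c(a, b))
  env <- defaultEnvironment(resource)
  set.seed(seed)
  # adjacent cells in one row; a faces east (2) toward b, b faces west (6)
  r <- cpp_run_world(dims[1], dims[2], c(0L, 1L), c(a, b), c(2L, 6L),
                     c(120, 120), as.integer(updates), 0, env$resource,
                     env$uptake, env$cmax, env$delta, env$diffusion, 30L, 0L)
  m <- r$genotypeTaskTotals
  dimnames(m) <- list(c("a", "b"), taskTable()$task)
  m
}
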