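# Condition-grid experiment driver, snapshot/event-log file formats, seed
# derivation, and the archetype fixture generator.

#' Archetype genotypes for assay testing and calibration
#'
#' Hand-constructed genomes that exemplify the replication and signaling
#' strategies that evolve in this system, used in place of evolved
#' genotypes when exercising the assays:
#' \describe{
#'   \item{ancestor}{single h-copy loop, if-label validated; performs NOT.}
#'   \item{loop-2x-with-iflabel}{two h-copy instructions per loop pass,
#'     if-label validated (fast, faithful).}
#'   \item{loop-2x-no-iflabel}{two h-copy instructions, no label check:
#'     divide is gated on the write head returning to its origin.}
#'   \item{loop-4x}{four h-copy instructions per pass, position-gated; the
#'     fastest replicator.}
#'   \item{loop-no-iflabel}{ancestor with the if-label knocked out: divide
#'     fires every loop pass, offspring are partial copies (non-viable).}
#'   \item{messenger}{broadcasts a jump hint that lets receivers skip an
#'     execution detour: messaging shortens gestation, so knocking out
#'     the messaging instructions costs roughly 20\% of assayed fitness.}
#'   \item{messenger-pair-A}{computes and outputs OR, broadcasts the
#'     result, and outputs a retrieved reply (NOR of its own inputs when
#'     partnered with messenger-pair-B).}
#'   \item{messenger-pair-B}{pure responder: NOTs retrieved values and
#'     broadcasts them back; performs no task alone.}
#'   \item{dead}{all nop-X; never replicates.}
#' }
#'
#' @return data.frame with columns \code{name}, \code{genome},
#'   \code{loopHCopies} (h-copy count in the located copy-loop),
#'   \code{ifLabel}, \code{messaging} and \code{viable} (expected
#'   properties, verified by the package's own tests).
#' @export
makeFixtures <- function() {
  M <- "yrayopcurocraopcupcu"  # OR circuit: BX <- in1 | in2
  g <- c(
    "ancestor" = buildAncestor(),
    "loop-2x-with-iflabel" =
      paste0("wEyopcuyA", strrep("c", 101), "zvvfcaxgab"),
    "loop-2x-no-iflabel" =
      paste0("wEyopcuyA", strrep("c", 103), "zvvicdgx"),
    "loop-4x" =
      paste0("wEyopcuyA", strrep("c", 101), "zvvvvicdgx"),
    "loop-no-iflabel" =
      paste0("wEyopcuyA", strrep("c", 102), "zvAcaxgab"),
    "messenger" = paste0(
      "w", "yopcuy",                      # alloc; NOT task
      "qpcq", "mc", strrep("lc", 5), "D", # CX=32; bcast (BX, 32)
      strrep("A", 40),                    # delay before the retrieve
      "qppcq", "C", "h",                  # zero BX/CX; retrieve; jump CX
      "ma", strrep("la", 5), "znadag",    # burn loop, skipped by the jump
      strrep("A", 19),
      "d", "y",                           # echo output only if a message came
      "zvvfcaxgab"),
    "messenger-pair-A" = paste0(
      "w", M, "oyp", "D", strrep("A", 69),
      "qppcq", "Cdy", strrep("A", 9), "zvfcaxgab"),
    "messenger-pair-B" = paste0(
      "w", strrep("qpqCopcuD", 3), strrep("A", 83), "zvfcaxgab"),
    "dead" = strrep("A", 120))
  parseGenome(unname(g))
  loopH <- vapply(g, function(x) {
    reg <- locateCopyLoop(x)
    if (reg$role != "copy-loop") return(0L)
    sum(strsplit(substr(x, reg$start, reg$end), "")[[1]] == "v")
  }, integer(1))
  data.frame(
    name = names(g), genome = unname(g),
    loopHCopies = unname(loopH),
    ifLabel = grepl("f", g, fixed = TRUE),
    messaging = grepl("[BCD]", g),
    viable = !(names(g) %in% c("loop-no-iflabel", "dead")),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Condition grid for replicate evolutionary runs
#'
#' The full study grid crosses two mutation rates with resource levels in
#' decade steps and several world sizes; the desk-scale default keeps two
#' sizes, three resource levels, 10 replicates and 20,000 updates.
#'
#' @param mutationRates,resources,worldSizes condition levels.
#' @param replicates replicate populations per condition cell.
#' @param updates updates per run.
#' @return data.frame of condition cells with a \code{cell} index column;
#'   \code{replicates} and \code{updates} are carried as attributes-free
#'   columns for the runner.
#' @export
conditionGrid <- function(mutationRates = c(7.5e-4, 7.5e-3),
                          resources = c(0.1, 100, 10000),
                          worldSizes = c(50, 200),
                          replicates = 10, updates = 20000) {
  g <- expand.grid(mutationRate = mutationRates, resource = resources,
                   worldSize = worldSizes, KEEP.OUT.ATTRS = FALSE)
  g$cell <- seq_len(nrow(g))
  g$replicates <- replicates
  g$updates <- updates
  g
}

#' @rdname conditionGrid
#' @details \code{paperGrid} returns the full-scale grid: resource levels
#'   0.1 to 10,000 in decade steps, world sizes 50 to 500, 100 replicates
#'   and 100,000 updates per run.
#' @export
paperGrid <- function() {
  conditionGrid(resources = 10^seq(-1, 4), worldSizes = c(50, 100, 200, 500),
                replicates = 100, updates = 100000)
}

#' Deterministic seed for a (cell, replicate) pair
#'
#' Injective over cell indices up to 94 and replicate indices up to 210,
#' and always below 2^31.
#'
#' @param base base seed of the experiment.
#' @param cell condition-cell index (1-based).
#' @param replicate replicate index (1-based).
#' @return Integer seed.
#' @export
deriveSeed <- function(base, cell, replicate) {
  stopifnot(cell >= 1, cell <= 94, replicate >= 1, replicate <= 210)
  as.integer((base %% 100000) * 20011 + cell * 211 + replicate)
}

#' Run a condition grid of replicate simulations
#'
#' Executes [runSimulation()] for every (cell, replicate) pair with a
#' seed derived by [deriveSeed()], writing one final-snapshot file per run
#' plus a manifest.  A rerun with the same arguments reuses the manifest
#' and skips runs whose snapshot files already exist, so interrupted
#' grids are resumable; failed replicates are flagged in the manifest,
#' never dropped.
#'
#' @param grid data.frame from [conditionGrid()].
#' @param outDir output directory (created if needed).
#' @param baseSeed base seed for [deriveSeed()].
#' @param ancestor seed genome.
#' @return The manifest data.frame (invisibly written to
#'   \code{manifest.tsv}).
#' @export
runGrid <- function(grid, outDir, baseSeed = 1, ancestor = buildAncestor()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifestFile <- file.path(outDir, "manifest.tsv")
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    for (rep in seq_len(grid$replicates[i])) {
      fn <- sprintf("snapshot_cell%02d_rep%03d.tsv", grid$cell[i], rep)
      path <- file.path(outDir, fn)
      seed <- deriveSeed(baseSeed, grid$cell[i], rep)
      status <- "ok"
      if (!file.exists(path)) {
        run <- tryCatch(
          runSimulation(ancestor = ancestor,
                        worldSize = grid$worldSize[i],
                        updates = grid$updates[i],
                        mutationRate = grid$mutationRate[i],
                        resource = grid$resource[i],
                        seed = seed,
                        condition = list(cell = grid$cell[i],
                                         replicate = rep)),
          error = function(e) e)
        if (inherits(run, "error")) {
          status <- paste("failed:", conditionMessage(run))
        } else {
          writeSnapshot(finalSnapshot(run), path)
          if (run@extinct) status <- "extinct"
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        cell = grid$cell[i], replicate = rep,
        mutationRate = grid$mutationRate[i], resource = grid$resource[i],
        worldSize = grid$worldSize[i], updates = grid$updates[i],
        seed = seed, status = status, file = fn,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write.table(manifest, manifestFile, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(manifest)
}

.snapshotVersion <- "avidula-snapshot v1"

#' Read and write population snapshot files
#'
#' Tab-separated with a versioned header line carrying the update and the
#' condition metadata; one organism per row (cell index, genome string,
#' merit, facing, nine task-count columns).  Round trips are exact.
#'
#' @param x a [PopulationSnapshot-class].
#' @param file path.
#' @return \code{readSnapshot} returns a [PopulationSnapshot-class].
#' @export
writeSnapshot <- function(x, file) {
  stopifnot(is(x, "PopulationSnapshot"))
  cond <- x@condition
  hdr <- paste0("# ", .snapshotVersion, "\tupdate=", x@update,
                if (length(cond))
                  paste0("\t", paste(names(cond),
                                     vapply(cond, format, ""),
                                     sep = "=", collapse = "\t")))
  d <- data.frame(cell = x@cell, genome = x@genomes, merit = x@merit,
                  facing = x@facing, stringsAsFactors = FALSE)
  d <- cbind(d, as.data.frame(x@taskCounts))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  suppressWarnings(write.table(d, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(file)
}

#' @rdname writeSnapshot
#' @export
readSnapshot <- function(file) {
  hdr <- readLines(file, n = 1)
  if (!startsWith(hdr, paste0("# ", .snapshotVersion)))
    stop("not an ", .snapshotVersion, " file: ", file)
  fields <- strsplit(sub("^# [^\t]*\t?", "", hdr), "\t")[[1]]
  cond <- list()
  update <- 0L
  for (f in fields) {
    kv <- strsplit(f, "=", fixed = TRUE)[[1]]
    val <- suppressWarnings(as.numeric(kv[2]))
    if (is.na(val)) val <- kv[2]
    if (kv[1] == "update") update <- as.integer(val) else cond[[kv[1]]] <- val
  }
  d <- read.delim(file, skip = 1, stringsAsFactors = FALSE)
  tc <- as.matrix(d[, taskTable()$task, drop = FALSE])
  colnames(tc) <- taskTable()$task
  new("PopulationSnapshot", genomes = d$genome, cell = as.integer(d$cell),
      merit = d$merit, facing = as.integer(d$facing), taskCounts = tc,
      update = update, condition = cond)
}

#' Read and write event-log files
#'
#' @param log data.frame as in the \code{log} slot of
#'   [EvolutionRun-class].
#' @param file path.
#' @return \code{readEventLog} returns the log data.frame.
#' @export
writeEventLog <- function(log, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("# avidula-eventlog v1", con)
  suppressWarnings(write.table(log, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(file)
}

#' @rdname writeEventLog
#' @export
readEventLog <- function(file) {
  hdr <- readLines(file, n = 1)
  if (!startsWith(hdr, "# avidula-eventlog v1"))
    stop("not an avidula-eventlog v1 file: ", file)
  read.delim(file, skip = 1, stringsAsFactors = FALSE)
}
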