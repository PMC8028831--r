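#' Accessors for snapshot and run objects
#'
#' @param x a [PopulationSnapshot-class] or [EvolutionRun-class] object.
#' @return \code{genomes} returns the character vector of genome strings;
#'   \code{merits} the numeric merit vector; \code{taskCounts} the
#'   organisms x 9 task-count matrix; \code{runCondition} the condition
#'   metadata list; \code{eventLog} the per-update log data.frame;
#'   \code{finalSnapshot} the final [PopulationSnapshot-class].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genomes", function(x) standardGeneric("genomes"))

#' @rdname accessors
#' @export
setGeneric("merits", function(x) standardGeneric("merits"))

#' @rdname accessors
#' @export
setGeneric("taskCounts", function(x) standardGeneric("taskCounts"))

#' @rdname accessors
#' @export
setGeneric("runCondition", function(x) standardGeneric("runCondition"))

#' @rdname accessors
#' @export
setGeneric("eventLog", function(x) standardGeneric("eventLog"))

#' @rdname accessors
#' @export
setGeneric("finalSnapshot", function(x) standardGeneric("finalSnapshot"))

#' @rdname accessors
#' @export
setMethod("genomes", "PopulationSnapshot", function(x) x@genomes)

#' @rdname accessors
#' @export
setMethod("merits", "PopulationSnapshot", function(x) x@merit)

#' @rdname accessors
#' @export
setMethod("taskCounts", "PopulationSnapshot", function(x) x@taskCounts)

#' @rdname accessors
#' @export
setMethod("runCondition", "PopulationSnapshot", function(x) x@condition)

#' @rdname accessors
#' @export
setMethod("genomes", "EvolutionRun", function(x) x@snapshot@genomes)

#' @rdname accessors
#' @export
setMethod("eventLog", "EvolutionRun", function(x) x@log)

#' @rdname accessors
#' @export
setMethod("finalSnapshot", "EvolutionRun", function(x) x@snapshot)
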