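#' The nine metabolic tasks and their merit rewards
#'
#' An organism performs a task by outputting the value of the task's 5-bit
#' logic function applied to recently taken environmental inputs.  Reward
#' weights double with rough circuit complexity, from NOT/NAND at 1 up to
#' EQU at 16.
#'
#' @return A data.frame with columns \code{task}, \code{operation}
#'   (human-readable logic), and \code{value} (merit reward weight).
#' @examples
#' taskTable()
#' @export
taskTable <- function() {
  data.frame(
    task = c("NOT", "NAND", "AND", "ORN", "OR", "ANDN", "NOR", "XOR", "EQU"),
    operation = c("~A", "~(A & B)", "A & B", "A | ~B", "A | B", "A & ~B",
                  "~(A | B)", "A xor B", "~(A xor B)"),
    value = c(1, 1, 2, 2, 4, 4, 8, 8, 16),
    stringsAsFactors = FALSE)
}

#' Classify an output value against recent inputs
#'
#' Returns every task whose 5-bit logic function, applied to a single
#' buffer entry (NOT) or to some ordered pair of distinct buffer entries
#' (all two-input tasks), equals the output.  All arithmetic is in 5-bit
#' space; an empty buffer matches nothing.
#'
#' @param output integer output value (only the low 5 bits are used).
#' @param inputs integer vector of the most recent environmental inputs,
#'   oldest first (the virtual CPU keeps at most 3).
#' @return Character vector of matched task names (possibly empty).
#' @examples
#' classifyOutput(27, c(22, 5))   # NAND: ~(22 & 5) = 27 in 5 bits
#' classifyOutput(12, c(22, 5))   # EQU
#' @export
classifyOutput <- function(output, inputs) {
  stopifnot(length(output) == 1, is.finite(output))
  if (length(inputs) == 0) return(character())
  if (any(inputs < 0 | inputs > 31))
    stop("inputs must be 5-bit values in [0, 31]")
  idx <- cpp_classify_output(as.integer(output), as.integer(inputs))
  taskTable()$task[idx]
}

#' Default environment parameters
#'
#' The chemostat holds each of the nine task resources at a target
#' steady-state level \code{resource} per lattice site, with per-update
#' inflow/outflow fraction \code{delta} and lateral diffusion toward the
#' 8-neighborhood mean with coefficient \code{diffusion}.  A task
#' performance consumes \code{min(uptake * level, cmax)} resource and adds
#' \code{value * consumed} to the organism's pending merit bonus, applied
#' at the next divide as \code{merit = 120 * (1 + sum(bonus))}.
#'
#' @param resource target steady-state resource level per site.
#' @param uptake fraction of the local level consumed per performance.
#' @param cmax cap on consumption per performance.
#' @param delta chemostat inflow/outflow fraction per update.
#' @param diffusion lateral mixing coefficient per update.
#' @return Named list of environment parameters.
#' @export
defaultEnvironment <- function(resource = 10000, uptake = 0.0025, cmax = 1,
                               delta = 0.01, diffusion = 0.5) {
  stopifnot(resource >= 0, uptake >= 0, cmax >= 0,
            delta >= 0, delta <= 1, diffusion >= 0, diffusion <= 1)
  list(resource = resource, uptake = uptake, cmax = cmax,
       delta = delta, diffusion = diffusion)
}

#' One chemostat update of a resource field
#'
#' Pure-R reference of the per-update resource dynamics used inside the
#' world loop: relaxation toward the target level followed by lateral
#' diffusion toward the 8-neighborhood mean on the torus.  Exposed for
#' direct inspection of the resource model.
#'
#' @param levels numeric matrix (height x width) of per-cell levels for
#'   one resource.
#' @param resource target steady-state level.
#' @param delta inflow/outflow fraction per update.
#' @param diffusion mixing coefficient per update.
#' @return Matrix of updated levels.
#' @export
chemostatStep <- function(levels, resource, delta = 0.01, diffusion = 0.5) {
  stopifnot(is.matrix(levels), all(levels >= 0))
  lv <- levels + delta * (resource - levels)
  if (diffusion > 0) {
    up <- rbind(lv[-1, , drop = FALSE], lv[1, , drop = FALSE])
    dn <- rbind(lv[nrow(lv), , drop = FALSE], lv[-nrow(lv), , drop = FALSE])
    shift <- function(m) cbind(m[, -1, drop = FALSE], m[, 1, drop = FALSE])
    unshift <- function(m) cbind(m[, ncol(m), drop = FALSE], m[, -ncol(m), drop = FALSE])
    nbMean <- (up + dn + shift(lv) + unshift(lv) +
               shift(up) + unshift(up) + shift(dn) + unshift(dn)) / 8
    lv <- (1 - diffusion) * lv + diffusion * nbMean
  }
  lv
}
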