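#' Validate and parse genome strings
#'
#' Genomes are serialized as letter strings: exactly 120 characters from
#' the 32-symbol instruction alphabet, one genome per line in files, with
#' \code{#} comment lines.  \code{parseGenome} validates a string and
#' returns it; \code{serializeGenome} is its (validating) inverse so that
#' round trips are bit-exact.
#'
#' @param x character vector of genome strings.
#' @return The validated character vector.
#' @examples
#' parseGenome(buildAncestor())
#' @export
parseGenome <- function(x) {
  stopifnot(is.character(x))
  alpha <- strsplit(instructionAlphabet(), "")[[1]]
  for (k in seq_along(x)) {
    if (nchar(x[k]) != 120L)
      stop("genome ", k, " has length ", nchar(x[k]), ", expected 120")
    codes <- strsplit(x[k], "")[[1]]
    bad <- which(!(codes %in% alpha))
    if (length(bad))
      stop("genome ", k, ": invalid instruction code '", codes[bad[1]],
           "' at site ", bad[1])
  }
  x
}

#' @rdname parseGenome
#' @export
serializeGenome <- function(x) parseGenome(x)

#' Read and write genome files
#'
#' One 120-character genome per line; lines starting with \code{#} are
#' comments.
#'
#' @param file path to a genome file.
#' @param x character vector of genome strings.
#' @param comment optional comment line(s) written at the top of the file.
#' @return \code{readGenomes} returns a validated character vector.
#' @export
readGenomes <- function(file) {
  lines <- readLines(file)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parseGenome(lines)
}

#' @rdname readGenomes
#' @export
writeGenomes <- function(x, file, comment = NULL) {
  parseGenome(x)
  out <- c(if (!is.null(comment)) paste0("# ", comment), x)
  writeLines(out, file)
  invisible(file)
}

#' Construct the ancestral genome
#'
#' The seed organism of every evolutionary run: a 120-site genome with a
#' short metabolic segment that performs the simplest task (NOT) once per
#' gestation, a single rotation instruction, nop-C filler, and a terminal
#' copy-loop with one h-copy and an if-label-guarded h-divide.  Its
#' gestation in isolation is 471 cycles and it replicates faithfully.
#'
#' Layout: \code{w} allocates offspring memory (write head to site 120);
#' \code{E} rotates once; \code{y o p c u y} takes an input, computes its
#' 5-bit complement via NAND and outputs it (the NOT task); \code{A} is a
#' nop-X barrier so the filler does not modify the final IO; then nop-C
#' filler; the loop \code{z v f c a x g} copies one site per iteration and
#' divides when the end label \code{a b} (complement of the \code{c a}
#' template) has just been copied.
#'
#' @return A single genome string.
#' @export
buildAncestor <- function() {
  paste0("wEyopcuyA", strrep("c", 102), "zvfcaxgab")
}

#' Whole-genome substitution mutations applied on divide
#'
#' Each site is independently selected with probability \code{rate}; a
#' selected site is rewritten with a uniform draw over all 32 codes, so
#' the configured rate is the substitution \emph{event} rate (a draw may
#' reproduce the same code).  Length is always conserved.
#'
#' @param x character vector of genome strings.
#' @param rate per-site substitution probability in [0, 1].
#' @param detail if TRUE, also return the per-genome substitution event
#'   counts.
#' @return The mutated genome vector, or (with \code{detail}) a list with
#'   elements \code{genomes} and \code{events}.
#' @examples
#' set.seed(1)
#' applyDivideMutations(buildAncestor(), 7.5e-3)
#' @export
applyDivideMutations <- function(x, rate, detail = FALSE) {
  stopifnot(rate >= 0, rate <= 1)
  parseGenome(x)
  alpha <- strsplit(instructionAlphabet(), "")[[1]]
  events <- integer(length(x))
  out <- x
  for (k in seq_along(x)) {
    hit <- which(runif(120L) < rate)
    events[k] <- length(hit)
    if (length(hit)) {
      codes <- strsplit(x[k], "")[[1]]
      codes[hit] <- alpha[sample.int(32L, length(hit), replace = TRUE)]
      out[k] <- paste(codes, collapse = "")
    }
  }
  if (detail) list(genomes = out, events = events) else out
}

# flow-head target of the h-search at 1-based site s (NA when unresolvable)
.searchTarget <- function(codes, s) {
  lab <- character()
  p <- s
  while (p < length(codes) && codes[p + 1] %in% c("a", "b", "c")) {
    lab <- c(lab, codes[p + 1])
    p <- p + 1
  }
  if (length(lab) == 0) return(s + 1)
  pos <- cpp_find_label(paste(codes, collapse = ""), p %% length(codes),
                        paste(lab, collapse = ""))
  if (pos < 0) s else pos + 1
}

#' Locate the terminal copy-loop of a genome
#'
#' Structural scan for the replicative region: the smallest suffix-anchored
#' region starting at the last h-search whose flow target precedes the
#' final h-divide.  Genomes with no such structure (replication
#' relinquished to interior elements, or none at all) yield an empty
#' region with role \code{"other"}.
#'
#' @param x a single genome string.
#' @return A list with 1-based \code{start}, \code{end} (inclusive; both 0
#'   for an empty region) and \code{role} (\code{"copy-loop"} or
#'   \code{"other"}).
#' @export
locateCopyLoop <- function(x) {
  parseGenome(x)
  codes <- strsplit(x, "")[[1]]
  divides <- which(codes == "x")
  if (length(divides)) {
    d <- max(divides)
    searches <- which(codes == "z")
    searches <- searches[searches < d]
    for (s in rev(searches)) {
      if (.searchTarget(codes, s) < d)
        return(list(start = s, end = 120L, role = "copy-loop"))
    }
  }
  list(start = 0L, end = 0L, role = "other")
}

#' Transplant a copy-loop between genomes
#'
#' Replaces the recipient's terminal copy-loop region with the donor's.
#' Both regions are suffix-anchored, so the result is deterministic: the
#' recipient keeps its first \code{120 - L} sites (\code{L} the donor loop
#' length) and the donor loop fills the tail.  A recipient without a
#' recognizable loop has the donor loop written over its terminal sites.
#' Self-transplant is the identity.
#'
#' @param recipient,donor genome strings; the donor must have a nonempty
#'   copy-loop region.
#' @return The chimeric genome string (length 120).
#' @export
transplantCopyLoop <- function(recipient, donor) {
  parseGenome(c(recipient, donor))
  reg <- locateCopyLoop(donor)
  if (reg$role != "copy-loop")
    stop("donor has no recognizable copy-loop region")
  loop <- substr(donor, reg$start, reg$end)
  keep <- 120L - nchar(loop)
  out <- paste0(substr(recipient, 1L, keep), loop)
  stopifnot(nchar(out) == 120L)
  out
}

#' Replace all instructions of a process with the null instruction
#'
#' Substitutes every occurrence of the named instructions with nop-X,
#' preserving length; the standard way to measure the marginal utility of
#' a process.  Idempotent.
#'
#' @param x character vector of genome strings.
#' @param process a preset name (\code{"messaging"}, \code{"copying"},
#'   \code{"rotation"}) or a character vector of instruction names from
#'   [instructionTable()].
#' @return The knocked-out genome vector.
#' @examples
#' knockoutInstructions(buildAncestor(), "messaging")  # identity: no B/C/D
#' @export
knockoutInstructions <- function(x, process) {
  parseGenome(x)
  names_ <- .resolveProcess(process)
  tab <- instructionTable()
  bad <- setdiff(names_, tab$name)
  if (length(bad)) stop("unknown instruction name(s): ", paste(bad, collapse = ", "))
  codes <- tab$code[tab$name %in% names_]
  chartr(paste(codes, collapse = ""),
         strrep("A", length(codes)), x)
}

.resolveProcess <- function(process) {
  presets <- .processPresets()
  if (length(process) == 1 && process %in% names(presets))
    presets[[process]]
  else process
}

.processCodes <- function(process) {
  tab <- instructionTable()
  tab$code[tab$name %in% .resolveProcess(process)]
}
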