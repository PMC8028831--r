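#' The 32-symbol instruction set
#'
#' Each genome site holds one of 32 instructions, written as a single
#' character: \code{a}-\code{z} carry the canonical heads instruction set
#' (nops, conditionals, head movement, stack and register arithmetic, and
#' the replication instructions h-copy/h-alloc/h-divide/h-search), and
#' \code{A}-\code{F} add the null instruction nop-X, the three messaging
#' instructions and the two rotations.
#'
#' The same table ships as a machine-readable file at
#' \code{system.file("extdata", "instruction_set.tsv", package = "avidula")}.
#'
#' @return A data.frame with columns \code{code} (the genome character),
#'   \code{name}, \code{operand} (register/head selected by a following
#'   nop, or \code{"-"}), and \code{contract} (one-line semantics).
#' @examples
#' instructionTable()[instructionTable()$name == "h-copy", ]
#' @export
instructionTable <- function() {
  tab <- .instructionTableData()
  stopifnot(identical(paste(tab$code, collapse = ""), instructionAlphabet()))
  tab
}

#' @rdname instructionTable
#' @return \code{instructionAlphabet} returns the 32-character alphabet
#'   string in opcode order.
#' @export
instructionAlphabet <- function() cpp_alphabet()

.instructionTableData <- function() {
  d <- rbind(
    c("a", "nop-A", "-", "no-op; operand modifier (AX/IP) and label symbol"),
    c("b", "nop-B", "-", "no-op; operand modifier (BX/read head) and label symbol"),
    c("c", "nop-C", "-", "no-op; operand modifier (CX/write head) and label symbol"),
    c("d", "if-n-equ", "?BX?", "execute next instruction only if ?BX? != its complement register"),
    c("e", "if-less", "?BX?", "execute next instruction only if ?BX? < its complement register"),
    c("f", "if-label", "label", "execute next instruction only if the complement of the following label was just copied"),
    c("g", "mov-head", "?IP?", "move ?IP? to the flow head position"),
    c("h", "jmp-head", "?IP?", "advance ?IP? by CX positions (modulo memory size)"),
    c("i", "get-head", "?IP?", "CX <- position of ?IP?"),
    c("j", "set-flow", "?CX?", "flow head <- value of ?CX? (modulo memory size)"),
    c("k", "shift-r", "?BX?", "?BX? <- ?BX? >> 1"),
    c("l", "shift-l", "?BX?", "?BX? <- ?BX? << 1"),
    c("m", "inc", "?BX?", "?BX? <- ?BX? + 1"),
    c("n", "dec", "?BX?", "?BX? <- ?BX? - 1"),
    c("o", "push", "?BX?", "push ?BX? onto the active stack"),
    c("p", "pop", "?BX?", "pop the active stack into ?BX? (0 when empty)"),
    c("q", "swap-stk", "-", "toggle the active stack"),
    c("r", "swap", "?BX?", "swap ?BX? with its complement register"),
    c("s", "add", "?BX?", "?BX? <- BX + CX"),
    c("t", "sub", "?BX?", "?BX? <- BX - CX"),
    c("u", "nand", "?BX?", "?BX? <- bitwise NAND of BX and CX"),
    c("v", "h-copy", "-", "copy one instruction from the read head to the write head (may mutate); advance both"),
    c("w", "h-alloc", "-", "extend memory to 240 sites (nop-X filled); write head to site 120"),
    c("x", "h-divide", "-", "split off sites 120-239 as the offspring genome; reset parent state"),
    c("y", "IO", "?BX?", "output ?BX? for task checking, then load a fresh 5-bit input into ?BX?"),
    c("z", "h-search", "label", "find the complement of the following label; flow head to its start, BX=distance, CX=size; empty label: flow head to next site"),
    c("A", "nop-X", "-", "null instruction: no operation, not a label symbol"),
    c("B", "send-msg", "-", "send (BX, CX) to the faced neighbor"),
    c("C", "retrieve-msg", "-", "pop the oldest queued message into (BX, CX); no-op when empty"),
    c("D", "bcast1", "-", "send (BX, CX) to all eight neighbors"),
    c("E", "rotate-left-one", "-", "rotate facing one step anticlockwise"),
    c("F", "rotate-right-one", "-", "rotate facing one step clockwise"))
  data.frame(code = d[, 1], name = d[, 2], operand = d[, 3],
             contract = d[, 4], stringsAsFactors = FALSE)
}

# instruction names for knockout presets
.processPresets <- function() {
  list(
    messaging = c("send-msg", "retrieve-msg", "bcast1"),
    copying = c("h-copy", "h-alloc", "h-divide", "h-search"),
    rotation = c("rotate-left-one", "rotate-right-one")
  )
}
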