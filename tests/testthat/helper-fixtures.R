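# Shared fixtures and oracles used across the test files.

.fx <- makeFixtures()

fixtureGenome <- function(name) {
  stopifnot(name %in% .fx$name)
  .fx$genome[.fx$name == name]
}

# Independent R oracle for task classification: which tasks match an
# output given the input buffer, computed directly from the truth tables.
oracleClassify <- function(output, inputs) {
  m <- 31L
  o <- bitwAnd(as.integer(output), m)
  hits <- character()
  for (A in inputs) {
    if (bitwAnd(bitwNot(A), m) == o) { hits <- c(hits, "NOT"); break }
  }
  n <- length(inputs)
  if (n >= 2) {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      A <- as.integer(inputs[i]); B <- as.integer(inputs[j])
      two <- c(
        NAND = bitwAnd(bitwNot(bitwAnd(A, B)), m),
        AND  = bitwAnd(A, B),
        ORN  = bitwAnd(bitwOr(A, bitwAnd(bitwNot(B), m)), m),
        OR   = bitwOr(A, B),
        ANDN = bitwAnd(A, bitwAnd(bitwNot(B), m)),
        NOR  = bitwAnd(bitwNot(bitwOr(A, B)), m),
        XOR  = bitwXor(A, B),
        EQU  = bitwAnd(bitwNot(bitwXor(A, B)), m))
      hits <- c(hits, names(two)[two == o])
    }
  }
  intersect(taskTable()$task, unique(hits))  # task-table order
}

# isolation harness shortcut with saturating resources
isoRun <- function(genome, budget = 8000, copyMut = 0, seed = 1,
                   stopAtDivide = TRUE, trace = FALSE) {
  set.seed(seed)
  avidula:::cpp_isolation_run(genome, as.integer(budget), copyMut,
                              1e4, 0.0025, 1, stopAtDivide, trace)
}
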