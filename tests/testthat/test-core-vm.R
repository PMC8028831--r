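# Virtual CPU semantics: instruction contracts, label search, copying,
# division, IO, and determinism.

test_that("inc and IO contracts: emitted value reflects register state", {
  # 'm' increments BX, 'y' outputs BX then loads a fresh 5-bit input
  g <- paste0("my", strrep("A", 118))
  r <- isoRun(g, budget = 4, stopAtDivide = FALSE)
  expect_equal(r$outputs[1], 1)          # BX was incremented from 0
  # a bare IO first outputs the initial register value 0
  g2 <- paste0("y", strrep("A", 119))
  r2 <- isoRun(g2, budget = 2, stopAtDivide = FALSE)
  expect_equal(r2$outputs[1], 0)
})

test_that("IO loads fresh 5-bit inputs and outputs are classified from the buffer", {
  # three IOs in a row: inputs accumulate; all loaded values are in [0, 31]
  g <- paste0(strrep("y", 6), strrep("A", 114))
  r <- isoRun(g, budget = 6, stopAtDivide = FALSE)
  expect_equal(length(r$outputs), 6)
  # outputs 2..6 echo the previously loaded input: all 5-bit values
  expect_true(all(r$outputs[-1] >= 0 & r$outputs[-1] <= 31))
})

test_that("find_label locates the nearest complement with wraparound", {
  mem <- paste0(strrep("A", 57), "bc", strrep("A", 61))   # "bc" at sites 58-59
  # complement of "ab" is "bc"
  expect_equal(avidula:::cpp_find_label(mem, 0, "ab"), 57)  # 0-based
  # nearer occurrence in scan direction wins
  mem2 <- paste0(strrep("A", 10), "bc", strrep("A", 30), "bc", strrep("A", 76))
  expect_equal(avidula:::cpp_find_label(mem2, 0, "ab"), 10)
  expect_equal(avidula:::cpp_find_label(mem2, 20, "ab"), 42)
  # wraparound: scanning from past the only occurrence comes back to it
  expect_equal(avidula:::cpp_find_label(mem, 100, "ab"), 57)
  # absent label
  expect_equal(avidula:::cpp_find_label(strrep("A", 120), 0, "ab"), -1)
})

test_that("ancestor copy-loop: 120 copy events, one divide, hand-traced gestation", {
  r <- isoRun(buildAncestor(), trace = TRUE)
  expect_true(r$divided)
  expect_equal(r$copies, 120)
  expect_equal(sum(r$trace$event == 3), 1)
  # hand trace: 7 prologue cycles (w E y o p+c u y), 1 nop-X barrier,
  # 102 filler nops, 1 h-search, then 120 loop iterations of 3 cycles
  # (h-copy; if-label consuming its 2-nop template; mov-head or h-divide)
  expect_equal(r$gestation, 7 + 1 + 102 + 1 + 120 * 3)
  expect_identical(r$offspring, buildAncestor())
})

test_that("h-copy substitution draws match the configured event rate", {
  # aggregate over fresh single-gestation runs: a long-lived parent would
  # eventually be corrupted once a mutated end label lets the write head
  # wrap into the parent region
  set.seed(42)
  for (rate in c(7.5e-3, 7.5e-4)) {
    copies <- 0; events <- 0
    for (i in 1:850) {
      r <- avidula:::cpp_isolation_run(buildAncestor(), 5000L, rate,
                                       1e4, 0.0025, 1, TRUE, FALSE)
      copies <- copies + r$copies
      events <- events + r$copyMutEvents
    }
    expect_gte(copies, 1e5)
    phat <- events / copies
    se <- sqrt(rate * (1 - rate) / copies)
    expect_lt(abs(phat - rate), 3 * se)
  }
})

test_that("h-divide requires a prior h-alloc and permits partial copies", {
  # divide without allocation is a no-op: never divides
  r <- isoRun(paste0(strrep("x", 120)))
  expect_false(r$divided)
  # divide right after alloc: offspring is all nop-X and non-viable
  r2 <- isoRun(paste0("wx", strrep("A", 118)))
  expect_true(r2$divided)
  expect_equal(r2$gestation, 2)
  expect_identical(r2$offspring, strrep("A", 120))
  expect_equal(viability(r2$offspring), 0)
})

test_that("if-label gates division on copy completion", {
  # intact ancestor divides only after the full copy
  anc <- isoRun(buildAncestor())
  expect_equal(anc$copies, 120)
  # with if-label removed, divide fires on the first loop pass
  broken <- fixtureGenome("loop-no-iflabel")
  r <- isoRun(broken)
  expect_true(r$divided)
  expect_lt(r$copies, 120)
  expect_false(identical(r$offspring, broken))
})

test_that("rotation changes facing by one step", {
  # ancestor contains a single rotate-left-one; from facing 0 it ends at 7
  run <- runSimulation(updates = 1, worldSize = 9, mutationRate = 0,
                       resource = 100, seed = 1, startFacing = 0L)
  expect_equal(finalSnapshot(run)@facing, 7L)
})

test_that("identical genome, seed and config give bit-identical runs", {
  r1 <- runSimulation(updates = 200, worldSize = 25, mutationRate = 7.5e-3,
                      resource = 100, seed = 11)
  r2 <- runSimulation(updates = 200, worldSize = 25, mutationRate = 7.5e-3,
                      resource = 100, seed = 11)
  expect_identical(eventLog(r1), eventLog(r2))
  expect_identical(genomes(r1), genomes(r2))
  expect_identical(merits(finalSnapshot(r1)), merits(finalSnapshot(r2)))
})

test_that("genome length is conserved through evolution", {
  run <- runSimulation(updates = 500, worldSize = 25, mutationRate = 7.5e-3,
                       resource = 100, seed = 3)
  expect_true(all(nchar(genomes(run)) == 120L))
})
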