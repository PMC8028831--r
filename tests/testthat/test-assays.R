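# Per-genotype assays: fitness, isolation, viability, phenotype, marginal
# utility, task complexity, joint profiling.

test_that("fitness assay: dead genotypes score 0; the log recount matches", {
  expect_equal(fitnessAssay(strrep("A", 120), measure = 50, stabilize = 10), 0)
  # recount oracle: rebuild the assay world with the same seed and recount
  # births from the event log
  g <- buildAncestor()
  seed <- 5; copies <- 200; dims <- c(15, 15)
  f <- fitnessAssay(g, seed = seed)
  set.seed(seed)
  cells <- sample.int(prod(dims), copies) - 1L
  env <- defaultEnvironment(10000)
  r <- avidula:::cpp_run_world(dims[1], dims[2], cells, rep(g, copies),
                               rep(-1L, copies), rep(120, copies), 500L, 0,
                               env$resource, env$uptake, env$cmax, env$delta,
                               env$diffusion, 30L, 0L)
  expect_equal(f, mean(r$log$births[101:500]))
})

test_that("fitness assay is seed-deterministic with low cross-seed variation", {
  g <- buildAncestor()
  expect_identical(fitnessAssay(g, seed = 3), fitnessAssay(g, seed = 3))
  fits <- vapply(1:5, function(s) fitnessAssay(g, seed = s), numeric(1))
  expect_lt(sd(fits) / mean(fits), 0.10)   # assay stability
})

test_that("isolation assay: gestation ordering follows copy-loop throughput", {
  dead <- isolationAssay(strrep("A", 120))
  expect_equal(dead$merit, 120)     # basal merit only
  expect_equal(dead$gestation, Inf)
  expect_equal(dead$fitness, 0)
  g4 <- isolationAssay(fixtureGenome("loop-4x"))$gestation
  g2 <- isolationAssay(fixtureGenome("loop-2x-with-iflabel"))$gestation
  g2n <- isolationAssay(fixtureGenome("loop-2x-no-iflabel"))$gestation
  g1 <- isolationAssay(buildAncestor())$gestation
  expect_lt(g4, g2)
  expect_lt(g4, g2n)
  expect_lt(g2, g1)
  expect_lt(g2n, g1)
  expect_equal(g1, 471)  # hand-traced cycle count
})

test_that("viability is the fraction of faithful replicators", {
  anc <- buildAncestor()
  dead <- strrep("A", 120)
  expect_equal(viability(rep(anc, 3)), 1)
  expect_equal(viability(rep(dead, 2)), 0)
  expect_equal(viability(c(anc, anc, anc, dead)), 0.75)
})

test_that("phenotype profiling covers the 512-class space", {
  p <- phenotypeProfile(c(buildAncestor(), strrep("A", 120)))
  expect_equal(unname(p$performs[1, ]), c(TRUE, rep(FALSE, 8)))  # NOT only
  expect_equal(unname(p$counts[2, ]), rep(0L, 9))
  expect_equal(p$class[2], 1L)
  # the class map is a bijection onto 1..512
  combos <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 9)))
  cls <- phenotypeClass(combos)
  expect_equal(sort(cls), 1:512)
})

test_that("marginal utility honors its contracts on the fixture library", {
  anc <- buildAncestor()
  # process absent: 0 without running any assay
  expect_equal(marginalUtility(anc, "messaging"), 0)
  # knockout lethal: 1 (copying is essential)
  expect_equal(marginalUtility(anc, "copying")[1], 1, tolerance = 1e-12)
  # messaging-dependent genotype: strictly positive utility; its knockout
  # scores 0 (process absent after the knockout)
  msg <- fixtureGenome("messenger")
  u <- marginalUtility(msg, "messaging", seed = 2)
  expect_gt(u, 0.05)
  ko <- knockoutInstructions(msg, "messaging")
  expect_equal(marginalUtility(ko, "messaging", seed = 2), 0)
})

test_that("task complexity equals the exhaustive NAND-circuit minimum", {
  tc <- taskComplexity()
  # independent oracle: depth-first enumeration over gate sequences; each
  # step NANDs two existing wires, sharing allowed
  best <- new.env(parent = emptyenv())
  tt <- function(f) sum(f * c(1, 2, 4, 8))
  A <- c(0L, 1L, 0L, 1L); B <- c(0L, 0L, 1L, 1L)
  rec <- function(wires, gates, maxGates) {
    for (w in wires) {
      key <- as.character(tt(w))
      old <- best[[key]]
      if (is.null(old) || gates < old) best[[key]] <- gates
    }
    if (gates == maxGates) return()
    for (i in seq_along(wires)) for (j in i:length(wires)) {
      g <- 1L - (wires[[i]] & wires[[j]])
      rec(c(wires, list(g)), gates + 1L, maxGates)
    }
  }
  rec(list(A, B), 0L, 5L)
  logic <- list(NOT = 1L - A, NAND = 1L - (A & B), AND = A & B,
                ORN = A | (1L - B), OR = A | B, ANDN = A & (1L - B),
                NOR = 1L - (A | B), XOR = as.integer(xor(A, B)),
                EQU = 1L - as.integer(xor(A, B)))
  oracle <- vapply(logic, function(f) best[[as.character(tt(as.integer(f)))]],
                   numeric(1))
  expect_equal(unname(tc), unname(oracle))
  # NAND is the primitive; NOT is a self-NAND
  expect_equal(taskComplexity("NAND"), 1L)
  expect_equal(taskComplexity("NOT"), 1L)
  expect_equal(taskComplexity("EQU"), 5L)
  # monotone along the reward ordering groups
  vals <- taskTable()$value
  expect_true(all(diff(tc[order(vals)]) >= 0))
})

test_that("the messenger pair jointly performs NOR, which neither does alone", {
  a <- fixtureGenome("messenger-pair-A")
  b <- fixtureGenome("messenger-pair-B")
  jp <- jointPhenotype(a, b, updates = 150)
  expect_gt(jp["a", "NOR"], 0)
  pa <- phenotypeProfile(a)$performs[1, ]
  pb <- phenotypeProfile(b)$performs[1, ]
  expect_false(pa[["NOR"]])
  expect_false(pb[["NOR"]])
  expect_true(pa[["OR"]])       # A's solo partial computation
  expect_false(any(pb))         # B performs nothing alone
})
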