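# Ancestor construction, mutation, copy-loop surgery, serialization.

test_that("the ancestor meets its construction contract", {
  anc <- buildAncestor()
  expect_equal(nchar(anc), 120)
  # pinned in the repository as a versioned fixture
  pinned <- readGenomes(system.file("extdata", "ancestor.txt",
                                    package = "avidula"))
  expect_identical(anc, pinned)
  # phenotype: NOT only
  p <- phenotypeProfile(anc)
  expect_equal(unname(p$performs[1, ]),
               c(TRUE, rep(FALSE, 8)))
  # exactly one rotation instruction
  expect_equal(lengths(regmatches(anc, gregexpr("[EF]", anc))), 1)
  # copy-loop contains exactly one h-copy and an if-label
  reg <- locateCopyLoop(anc)
  loop <- substr(anc, reg$start, reg$end)
  expect_equal(sum(strsplit(loop, "")[[1]] == "v"), 1)
  expect_true(grepl("f", loop))
  # fully viable under high resource
  expect_equal(viability(anc), 1)
})

test_that("divide mutations are substitution-only with the configured event rate", {
  anc <- buildAncestor()
  set.seed(1)
  expect_identical(applyDivideMutations(anc, 0), anc)
  r1 <- applyDivideMutations(anc, 1, detail = TRUE)
  expect_equal(r1$events, 120)
  expect_equal(nchar(r1$genomes), 120)
  # binomial mean: 120 * 7.5e-3 = 0.9 events per genome
  set.seed(2)
  r <- applyDivideMutations(rep(anc, 10000), 7.5e-3, detail = TRUE)
  expect_true(all(nchar(r$genomes) == 120))
  m <- mean(r$events)
  se <- sqrt(0.9 / 10000)  # approx poisson se of the mean
  expect_lt(abs(m - 0.9), 4 * se)
})

test_that("locateCopyLoop finds the terminal replicative region", {
  anc <- buildAncestor()
  reg <- locateCopyLoop(anc)
  expect_equal(reg$role, "copy-loop")
  expect_equal(substr(anc, reg$start, reg$end), "zvfcaxgab")
  # no replicative structure at all
  expect_equal(locateCopyLoop(strrep("A", 120))$role, "other")
  # a 10-site loop is recovered exactly
  g2 <- fixtureGenome("loop-2x-with-iflabel")
  reg2 <- locateCopyLoop(g2)
  expect_equal(substr(g2, reg2$start, reg2$end), "zvvfcaxgab")
  expect_equal(reg2$end - reg2$start + 1, 10)
})

test_that("copy-loop transplants are deterministic, length-preserving surgery", {
  fx <- makeFixtures()
  loopy <- fx$genome[fx$loopHCopies > 0]
  # self-transplant is the identity
  for (g in loopy) expect_identical(transplantCopyLoop(g, g), g)
  # ancestor with the quad-copy donor loop carries 4 h-copy codes
  anc <- buildAncestor()
  quad <- transplantCopyLoop(anc, fixtureGenome("loop-4x"))
  expect_equal(nchar(quad), 120)
  reg <- locateCopyLoop(quad)
  expect_equal(sum(strsplit(substr(quad, reg$start, reg$end), "")[[1]] == "v"), 4)
  # replication speeds follow the transplanted loop
  gAnc <- isolationAssay(anc)$gestation
  gQuad <- isolationAssay(quad)$gestation
  expect_lt(gQuad, gAnc)
  # transplanting the slow ancestral loop into a fast 2-copy genome
  # increases its gestation
  fast <- fixtureGenome("loop-2x-with-iflabel")
  slowed <- transplantCopyLoop(fast, anc)
  expect_gt(isolationAssay(slowed)$gestation, isolationAssay(fast)$gestation)
})

test_that("knockout replaces process instructions with nop-X and is idempotent", {
  anc <- buildAncestor()
  # no messaging instructions present: identity
  expect_identical(knockoutInstructions(anc, "messaging"), anc)
  # copying knockout destroys replication
  ko <- knockoutInstructions(anc, "copying")
  expect_equal(nchar(ko), 120)
  expect_false(grepl("[vwxz]", ko))
  expect_equal(isolationAssay(ko)$fitness, 0)
  # idempotent
  msg <- fixtureGenome("messenger")
  k1 <- knockoutInstructions(msg, "messaging")
  expect_identical(knockoutInstructions(k1, "messaging"), k1)
  expect_false(grepl("[BCD]", k1))
})

test_that("surgery preserves length and alphabet on random genomes", {
  alpha <- strsplit(instructionAlphabet(), "")[[1]]
  set.seed(7)
  donors <- makeFixtures()
  donors <- donors$genome[donors$loopHCopies > 0]
  for (i in 1:25) {
    g <- paste(sample(alpha, 120, replace = TRUE), collapse = "")
    k <- knockoutInstructions(g, "messaging")
    expect_equal(nchar(k), 120)
    expect_silent(parseGenome(k))
    tp <- transplantCopyLoop(g, sample(donors, 1))
    expect_equal(nchar(tp), 120)
    expect_silent(parseGenome(tp))
  }
})

test_that("genome serialization round-trips and rejects malformed input", {
  alpha <- strsplit(instructionAlphabet(), "")[[1]]
  set.seed(8)
  gs <- replicate(10, paste(sample(alpha, 120, replace = TRUE), collapse = ""))
  expect_identical(parseGenome(gs), gs)
  expect_error(parseGenome(strrep("a", 119)), "length 119")
  expect_error(parseGenome(paste0(strrep("a", 50), "9", strrep("a", 69))),
               "site 51")
  # file round trip with comments
  f <- tempfile(fileext = ".txt")
  writeGenomes(gs, f, comment = "random test genomes")
  expect_identical(readGenomes(f), gs)
})
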