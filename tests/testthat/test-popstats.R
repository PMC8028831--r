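# Population analysis: KDE peaks, dip test, heterogeneity entropies,
# signaling classification, incidence tables.

test_that("fitness KDE finds peaks and samples exact 2-bandwidth windows", {
  # degenerate: all values equal
  k0 <- fitnessKde(rep(3.5, 10))
  expect_equal(nrow(k0$peaks), 1)
  expect_equal(k0$peaks$location, 3.5)
  expect_equal(k0$samples[[1]], 1:10)
  # constructed mixture: two peaks near 1 and 5
  set.seed(42)
  v <- c(rnorm(250, 1, 0.05), rnorm(250, 5, 0.05))
  k <- fitnessKde(v)
  expect_equal(nrow(k$peaks), 2)
  expect_lt(abs(k$peaks$location[1] - 1), 0.1)
  expect_lt(abs(k$peaks$location[2] - 5), 0.1)
  # window sampling returns exactly the values within 2 bandwidths
  for (p in seq_len(nrow(k$peaks))) {
    idx <- k$samples[[p]]
    inWindow <- abs(v - k$peaks$location[p]) <= 2 * k$bw
    expect_identical(idx, which(inWindow))
    expect_true(all(abs(v[idx] - k$peaks$location[p]) <= 2 * k$bw))
  }
})

test_that("dip statistic: exact two-point value, bounds and invariances", {
  # n = 2: the ecdf jump structure forces dip = 1/4
  expect_equal(dipStatistic(c(0, 1)), 0.25)
  expect_equal(dipStatistic(c(-3, 17)), 0.25)
  # degenerate samples
  expect_equal(dipStatistic(rep(2, 50)), 0)
  set.seed(10)
  for (n in c(10, 100, 1000)) {
    x <- runif(n)
    d <- dipStatistic(x)
    expect_gte(d, 1 / (2 * n))
    expect_lte(d, 0.25)
    # location/scale invariance
    expect_equal(dipStatistic(3 * x + 7), d)
  }
  # well-separated bimodal samples have much larger dip than unimodal ones
  set.seed(11)
  uni <- rnorm(400)
  bim <- c(rnorm(200, 0, 0.2), rnorm(200, 10, 0.2))
  expect_gt(dipStatistic(bim), 5 * dipStatistic(uni))
  # dip of a unimodal analytic sample shrinks as n grows
  expect_lt(dipStatistic(qnorm(((1:2000) - 0.5) / 2000)),
            dipStatistic(qnorm(((1:50) - 0.5) / 50)))
})

test_that("dip test separates unimodal from bimodal samples", {
  set.seed(12)
  uni <- runif(1000)
  t1 <- dipTest(uni, B = 200)
  expect_gt(t1$p.value, 0.05)
  bim <- c(rnorm(500, 0, 0.3), rnorm(500, 8, 0.3))
  t2 <- dipTest(bim, B = 200)
  expect_lt(t2$p.value, 0.05)
})

test_that("genotypic heterogeneity: analytic values and invariances", {
  anc <- buildAncestor()
  expect_equal(genotypicHeterogeneity(rep(anc, 20)), 0)
  # two genotypes at 50/50 differing at exactly 3 sites: 3 ln 2
  other <- anc
  substr(other, 1, 3) <- "mmm"
  pop <- c(rep(anc, 10), rep(other, 10))
  expect_equal(genotypicHeterogeneity(pop), 3 * log(2))
  # permutation invariance over organisms
  set.seed(13)
  expect_equal(genotypicHeterogeneity(sample(pop)), 3 * log(2))
  # a site uniformly occupied by all 32 codes contributes ln 32
  alpha <- strsplit(instructionAlphabet(), "")[[1]]
  pop32 <- vapply(alpha, function(ch) {
    g <- anc; substr(g, 60, 60) <- ch; g
  }, character(1))
  expect_equal(genotypicHeterogeneity(unname(pop32)), log(32))
  # bounds on arbitrary random snapshots
  set.seed(14)
  rnd <- replicate(30, paste(sample(alpha, 120, replace = TRUE), collapse = ""))
  h <- genotypicHeterogeneity(rnd)
  expect_gte(h, 0)
  expect_lte(h, 120 * log(32))
})

test_that("phenotypic heterogeneity spans 0 to ln 512", {
  expect_equal(phenotypicHeterogeneity(rep(7L, 100)), 0)
  expect_equal(phenotypicHeterogeneity(rep(c(1L, 2L), 50)), log(2))
  expect_equal(phenotypicHeterogeneity(1:512), log(512))
  # matrix input
  m <- matrix(FALSE, 4, 9); m[3:4, 1] <- TRUE
  expect_equal(phenotypicHeterogeneity(m), log(2))
})

test_that("signaling classification thresholds pooled utilities at the peak midpoint", {
  # all utilities zero: fallback threshold, all non-signaling
  expect_warning(cls0 <- classifySignaling(list(rep(0, 10), rep(0, 10))),
                 "fallback")
  expect_false(any(cls0$signaling))
  # constructed mixture: half the genotypes near 0, half near 0.2
  set.seed(15)
  mkPop <- function(mu) rnorm(30, mu, 0.015)
  pops <- c(lapply(1:6, function(i) mkPop(0)), lapply(1:6, function(i) mkPop(0.2)))
  cls <- classifySignaling(pops)
  thr <- attr(cls, "threshold")
  expect_lt(abs(thr - 0.1), 0.05)
  expect_identical(cls$signaling, rep(c(FALSE, TRUE), each = 6))
  # invariant to population ordering
  clsRev <- classifySignaling(rev(pops))
  expect_identical(clsRev$signaling, rev(cls$signaling))
})

test_that("incidence tables count signaling populations per condition cell", {
  runs <- data.frame(
    worldSize = rep(c(50, 200), each = 10),
    resource = 100,
    signaling = c(rep(c(TRUE, FALSE), c(3, 7)), rep(c(TRUE, FALSE), c(6, 4))),
    extinct = FALSE)
  tab <- incidenceTable(runs)
  expect_equal(tab$signaling, c(3, 6))
  expect_equal(tab$runs, c(10, 10))
  # extinct runs are excluded from the denominator, reported separately
  runs$extinct[1:2] <- TRUE   # two extinct signaling-positive runs
  tab2 <- incidenceTable(runs)
  expect_equal(tab2$runs, c(8, 10))
  expect_equal(tab2$signaling, c(1, 6))
  expect_equal(tab2$extinct, c(2, 0))
})
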