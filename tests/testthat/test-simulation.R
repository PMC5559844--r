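test_that("synthetic parents are informative by construction and reproducible", {
  par <- synthParents(500, 5e5, seed = 41)
  inf <- findInformativePositions(par$mother, par$father)
  expect_equal(nrow(inf), 500L)
  # same seed -> identical tables; different seed -> different
  par2 <- synthParents(500, 5e5, seed = 41)
  expect_identical(methData(par$mother), methData(par2$mother))
  par3 <- synthParents(500, 5e5, seed = 42)
  expect_false(identical(methData(par$mother), methData(par3$mother)))
  # counts encode the level exactly
  d <- methData(par$mother)
  expect_equal(d$mc / d$total, weightedMethylation(d$mc, d$total))
  # empty case
  par0 <- synthParents(0, 5e5)
  expect_equal(nrow(methData(par0$mother)), 0L)
})

test_that("high and low parental levels separate as designed", {
  par <- synthParents(4000, 4e6, seed = 43)
  m <- methData(par$mother); f <- methData(par$father)
  hi <- ifelse(m$is_methylated, m$mc, f$mc) / 100
  lo <- ifelse(m$is_methylated, f$mc, m$mc) / 100
  # Beta(8,2) vs Beta(2,8): means 0.8 and 0.2
  expect_equal(mean(hi), 0.8, tolerance = 0.02)
  expect_equal(mean(lo), 0.2, tolerance = 0.02)
  expect_true(all(hi >= 0 & hi <= 1) && all(lo >= 0 & lo <= 1))
})

test_that("offspring levels follow the clamped uniform error model", {
  par <- synthParents(800, 8e5, seed = 44)
  m <- methData(par$mother); f <- methData(par$father)

  # y = 0: simulated level equals the expected level exactly
  sim0 <- simulateOffspring(par, 0, y = 0, seed = 440)
  g <- sim0$truth$genotype[1]
  lvl <- methData(sim0$methylome)$mc / 100
  expected <- switch(g, MOTHER = m$mc / 100, FATHER = f$mc / 100,
                     HET = (m$mc + f$mc) / 200)
  expect_equal(lvl, round(expected * 100) / 100)

  # y = 0.3: every level within [max(0, x - y), min(1, x + y)]
  sim3 <- simulateOffspring(par, 5, y = 0.3, seed = 443)
  region <- findInterval(m$pos - 1, sim3$truth$start)
  geno <- sim3$truth$genotype[region]
  x <- ifelse(geno == "MOTHER", m$mc / 100,
              ifelse(geno == "FATHER", f$mc / 100, (m$mc + f$mc) / 200))
  lvl3 <- methData(sim3$methylome)$mc / 100
  expect_true(all(lvl3 >= pmax(0, x - 0.3) - 0.005))
  expect_true(all(lvl3 <= pmin(1, x + 0.3) + 0.005))
  expect_true(all(lvl3 >= 0 & lvl3 <= 1))

  expect_error(simulateOffspring(par, 0, y = 1.5), "\\[0, 1\\]")
})

test_that("breakpoints are equally spaced and regions tile the chromosome", {
  par <- synthParents(100, 1e6, seed = 45)
  sim <- simulateOffspring(par, 4, y = 0, seed = 450)
  tr <- sim$truth
  expect_equal(nrow(tr), 5L)
  expect_equal(tr$start, c(0, 1, 2, 3, 4) * 2e5)
  expect_equal(tr$end, c(1, 2, 3, 4, 5) * 2e5)
  # 0 to nBreakpoints actual changes
  changes <- sum(tr$genotype[-1] != tr$genotype[-5])
  expect_true(changes >= 0 && changes <= 4)
})

test_that("genotype draws follow the 1:2:1 Mendelian ratio", {
  par <- synthParents(10, 1e6, seed = 46)
  set.seed(46)
  draws <- unlist(lapply(1:400, function(i)
    simulateOffspring(par, 9, y = 0, seed = 4600 + i)$truth$genotype))
  tab <- table(factor(draws, levels = c("MOTHER", "HET", "FATHER")))
  chi <- stats::chisq.test(tab, p = c(0.25, 0.5, 0.25))
  expect_gt(chi$p.value, 0.001)
})

test_that("micro-F1 equals the fraction of correctly labeled bins", {
  expect_equal(accuracyF1(states3[c(1, 2, 3, 1)], states3[c(1, 2, 3, 1)]), 1)
  expect_equal(accuracyF1(states3[c(1, 2, 3, 1)], states3[c(1, 2, 3, 2)]),
               0.75)
  expect_error(accuracyF1(states3[1:3], states3[1:2]), "bin structure")
  # random predictions against 1:2:1 truth: expectation 0.25^2+0.5^2+0.25^2
  set.seed(47)
  sc <- replicate(300, {
    tr <- sample(states3, 60, replace = TRUE, prob = c(0.25, 0.5, 0.25))
    pr <- sample(states3, 60, replace = TRUE, prob = c(0.25, 0.5, 0.25))
    accuracyF1(pr, tr)
  })
  expect_equal(mean(sc), 0.375, tolerance = 0.015)
})

test_that("truth projection assigns each bin its majority genotype", {
  truth <- data.frame(start = c(0, 100, 220), end = c(100, 220, 300),
                      genotype = c("MOTHER", "HET", "FATHER"))
  bins <- data.frame(start = c(0, 150, 200), end = c(150, 200, 300))
  expect_equal(truthToBins(truth, bins), c("MOTHER", "MPV", "FATHER"))
})

test_that("the simulation grid is reproducible and degrades with error", {
  par <- synthParents(1500, 1.5e6, seed = 48)
  cfg <- simulationConfig(nSamples = 4, errors = c(0, 0.3), binSizes = 5e4,
                          iterations = 2, seed = 48)
  g1 <- runGrid(cfg, par, chromLength = 1.5e6)
  g2 <- runGrid(cfg, par, chromLength = 1.5e6)
  expect_identical(g1, g2)
  expect_true(all(g1$meanF1 >= 0 & g1$meanF1 <= 1))
  expect_gte(mean(g1$meanF1[g1$y == 0]), mean(g1$meanF1[g1$y == 0.3]) - 0.02)
})

test_that("simulation config validates its grid", {
  expect_error(simulationConfig(errors = 1.2), "\\[0, 1\\]")
  expect_error(simulationConfig(nSamples = 0), "nSamples")
  expect_silent(simulationConfig())
})
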