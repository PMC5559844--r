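test_that("informative positions require coverage and discordant calls", {
  mother <- mkMeth(c(100, 200, 300, 400),
                   c(5, 2, 4, 4), c(5, 2, 4, 4), meth = TRUE, id = "m")
  father <- mkMeth(c(100, 200, 300, 400),
                   c(0, 0, 3, 0), c(4, 9, 3, 9),
                   meth = c(FALSE, FALSE, TRUE, FALSE), id = "f")
  inf <- findInformativePositions(mother, father)
  # 100: cov 5/4, discordant -> informative
  # 200: mother cov 2 < 3 -> no; 300: both methylated -> no; 400: yes
  expect_equal(inf$pos, c(100L, 400L))

  noCall <- mkMeth(100, 2, 4, id = "x")
  expect_error(findInformativePositions(noCall, father), "calls")
})

test_that("mid-parent vectors average the parents elementwise", {
  expect_equal(midparentVector(c(1, 0), c(0, 1)), c(0.5, 0.5))
  expect_equal(midparentVector(c(0.8, 0.2), c(0.2, 0.6)), c(0.5, 0.4))
  v <- c(0.3, 0.7, 0.1)
  expect_equal(midparentVector(v, v), v)
  expect_error(midparentVector(c(1, 0), 1), "equal length")
})

test_that("epiRIL weights derive from F8 heterozygosity", {
  w <- epirilWeights()
  expect_equal(unname(w[2]), (1 / 2)^7)
  expect_equal(round(unname(w[2]), 4), 0.0078)
  expect_equal(unname(w[1]), (1 - (1 / 2)^7) / 2)
  expect_equal(round(unname(w[1]), 4), 0.4961)
  expect_equal(sum(w), 1)
  # 127:2:127 ratio
  expect_equal(unname(w / w[2]), c(63.5, 1, 63.5))
})

test_that("epiRIL emission adjustment folds MPV mass into the father state", {
  adj <- epirilAdjust(rbind(c(0.5, 0.3, 0.2), c(0.1, 0.8, 0.1)))
  expect_equal(unname(adj[1, ]), c(0.5, 0, 0.5))
  expect_equal(unname(adj[2, ]), c(0.1, 0, 0.9))
  expect_equal(unname(rowSums(adj)), c(1, 1))
})

test_that("a parental sample maps to its own state everywhere", {
  par <- synthParents(600, 6e5, seed = 31)
  # run the mother itself through the pipeline as an "offspring"
  motherCopy <- par$mother
  motherCopy@sampleId <- "m2"
  map <- epigenotypePipeline(par$mother, par$father,
                             list(m2 = motherCopy), binSize = 50000,
                             chromLengths = c(chr3 = 6e5))
  expect_true(all(finalStates(map)[, "m2"] == "MOTHER"))
  expect_true(all(finalStates(map)[, "mother"] == "MOTHER"))
  expect_true(all(finalStates(map)[, "father"] == "FATHER"))
  expect_true(all(finalStates(map)[, "mpv"] == "MPV"))
})

test_that("noiseless offspring are recovered exactly at unambiguous bins", {
  par <- synthParents(2000, 2e6, seed = 32)
  sims <- lapply(1:6, function(s)
    simulateOffspring(par, s - 1, y = 0, seed = 320 + s,
                      sampleId = paste0("o", s)))
  off <- setNames(lapply(sims, `[[`, "methylome"), paste0("o", 1:6))
  map <- epigenotypePipeline(par$mother, par$father, off, binSize = 50000,
                             chromLengths = c(chr3 = 2e6))
  bins <- binTable(map)
  for (s in 1:6) {
    tr <- truthToBins(sims[[s]]$truth, bins)
    ok <- unambiguousBins(sims[[s]]$truth, bins)
    expect_true(all(finalStates(map)[ok, paste0("o", s)] == tr[ok]))
  }
})

test_that("probability arrays are normalized and stages are argmax-consistent", {
  par <- synthParents(800, 8e5, seed = 33)
  sim <- simulateOffspring(par, 3, y = 0.2, seed = 330, sampleId = "o")
  map <- epigenotypePipeline(par$mother, par$father, list(o = sim$methylome),
                             binSize = 50000, chromLengths = c(chr3 = 8e5))
  for (s in seq_along(map@samples)) {
    expect_equal(unname(rowSums(lrProbs(map)[, , s])),
                 rep(1, nrow(binTable(map))), tolerance = 1e-6)
    expect_equal(unname(rowSums(fbPosteriors(map)[, , s])),
                 rep(1, nrow(binTable(map))), tolerance = 1e-6)
    expect_equal(lrStates(map)[, s],
                 states3[max.col(lrProbs(map)[, , s], ties.method = "first")])
    expect_equal(fbStates(map)[, s],
                 states3[max.col(fbPosteriors(map)[, , s],
                                 ties.method = "first")])
  }
  for (tr in map@transitions)
    for (m in tr) expect_equal(unname(rowSums(m)), rep(1, 3),
                               tolerance = 1e-12)
})

test_that("centromere masking drives masked bins by transitions alone", {
  par <- synthParents(1500, 1.5e6, seed = 34)
  sim <- simulateOffspring(par, 0, y = 0, seed = 340, sampleId = "o")
  cen <- data.frame(chrom = "chr3", start = 6e5, end = 9e5)
  map <- epigenotypePipeline(par$mother, par$father, list(o = sim$methylome),
                             binSize = 50000, chromLengths = c(chr3 = 1.5e6),
                             centromeres = cen)
  b <- binTable(map)
  expect_true(any(b$isCentromere))
  expect_true(all(b$isCentromere == (b$start < 9e5 & b$end > 6e5)))
  # the zero-breakpoint sample keeps one state across the masked region
  tr <- truthToBins(sim$truth, b)
  expect_true(all(finalStates(map)[, "o"] == tr))
})

test_that("breakpoints sit on shared bin boundaries between state changes", {
  par <- synthParents(2000, 2e6, seed = 35)
  sim <- simulateOffspring(par, 4, y = 0, seed = 350, sampleId = "o")
  map <- epigenotypePipeline(par$mother, par$father, list(o = sim$methylome),
                             binSize = 50000, chromLengths = c(chr3 = 2e6))
  bp <- breakpoints(map)
  b <- binTable(map)
  st <- finalStates(map)[, "o"]
  expected <- b$end[which(st[-1] != st[-length(st)])]
  expect_equal(bp$pos[bp$sample == "o"], expected)
  expect_true(all(bp$from != bp$to))
  # crossover counts agree with the breakpoint table
  cc <- countCrossovers(map)
  expect_equal(cc$n[cc$sample == "o"], length(expected))
})

test_that("epiril mode never predicts the MPV state for offspring", {
  par <- synthParents(1000, 1e6, seed = 36)
  # an F8-like sample: mosaic of homozygous blocks only
  set.seed(36)
  m <- methData(par$mother); f <- methData(par$father)
  half <- m$pos <= 5e5
  d <- m
  d$mc <- ifelse(half, m$mc, f$mc)
  sim <- MethylomeTable(d, "ril")
  map <- epigenotypePipeline(par$mother, par$father, list(ril = sim),
                             binSize = 50000, chromLengths = c(chr3 = 1e6),
                             mode = "epiril")
  expect_true(all(finalStates(map)[, "ril"] %in% c("MOTHER", "FATHER")))
  expect_equal(sum(finalStates(map)[, "ril"] == "MOTHER"),
               sum(binTable(map)$start < 5e5))
})

test_that("replicates enter training and the transition pool", {
  par <- synthParents(1000, 1e6, seed = 37)
  jitter <- function(x, id) {
    d <- methData(x)
    set.seed(97)
    flip <- stats::runif(nrow(d)) < 0.02
    d$mc <- ifelse(flip, d$total - d$mc, d$mc)
    MethylomeTable(d, id)
  }
  mRep <- jitter(par$mother, "mr1")
  fRep <- jitter(par$father, "fr1")
  sim <- simulateOffspring(par, 2, y = 0.2, seed = 370, sampleId = "o")
  map <- epigenotypePipeline(par$mother, par$father, list(o = sim$methylome),
                             motherReps = list(mRep), fatherReps = list(fRep),
                             binSize = 50000, chromLengths = c(chr3 = 1e6))
  roles <- sampleRoles(map)
  expect_true(all(c("mother_rep", "father_rep", "mpv_rep") %in% roles))
  expect_true(all(finalStates(map)[, names(roles)[roles == "mother_rep"]]
                  == "MOTHER"))
  tr <- truthToBins(sim$truth, binTable(map))
  ok <- unambiguousBins(sim$truth, binTable(map))
  expect_true(mean(finalStates(map)[ok, "o"] == tr[ok]) > 0.9)
})
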