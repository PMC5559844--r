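library(GenomicRanges)

gr <- function(start, end, chrom = "Chr1", ...) {
  GRanges(chrom, IRanges(start = start, end = end), ...)
}

test_that("region filters apply length, cytosine, and span thresholds", {
  regions <- gr(start = c(1, 1, 1, 1),
                end = c(39, 100, 100, 100))
  levels <- rbind(c(0.1, 0.5),    # span 0.4, but 39 bp -> removed
                  c(0.1, 0.5),    # 9 cytosines -> removed
                  c(0.35, 0.50),  # span 0.15 -> removed
                  c(0.2, 0.6))    # keeps everything
  nCyt <- c(12, 9, 12, 12)
  keep <- filterRegions(regions, levels, nCyt)
  expect_equal(keep, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("region summaries pool counts and count covered cytosines", {
  a <- mkMeth(c(10, 20, 30, 200), c(2, 3, 0, 5), c(4, 6, 2, 5), id = "a")
  b <- mkMeth(c(10, 20, 30, 200), c(1, 0, 1, 4), c(3, 5, 4, 4), id = "b")
  regions <- gr(start = c(1, 150), end = c(100, 250))
  rl <- regionLevels(regions, list(a = a, b = b))
  expect_equal(rl$mc[, "a"], c(5, 5))
  expect_equal(rl$total[, "a"], c(12, 5))
  expect_equal(unname(rl$level[1, "b"]), 2 / 12)
  # position 30 has coverage 2 in sample a -> not counted as covered
  expect_equal(rl$nCytosines, c(2, 1))
})

test_that("level-difference z-test reproduces the worked example", {
  # 90/100 vs 10/100: diff 0.8, z = (0.8 - 0.25) / sqrt(2 * 0.09/100)
  zt <- ztestLevelDifference(90, 100, 10, 100)
  expect_equal(zt$z, 0.55 / sqrt(0.0018), tolerance = 1e-9)
  expect_equal(zt$z, 12.96, tolerance = 1e-3)
  expect_lt(zt$p, 1e-12)

  # equal proportions: z < 0, p > 0.5
  zt2 <- ztestLevelDifference(40, 100, 40, 100)
  expect_lt(zt2$z, 0)
  expect_gt(zt2$p, 0.5)

  # doubling totals at fixed proportions increases |z|
  z1 <- ztestLevelDifference(60, 100, 20, 100)$z
  z2 <- ztestLevelDifference(120, 200, 40, 200)$z
  expect_gt(abs(z2), abs(z1))

  # zero totals are undefined
  expect_true(is.na(ztestLevelDifference(0, 0, 5, 10)$z))
})

test_that("epiallele calls define epiloci and hotspots", {
  # region 1: one strong change; region 2: none; region 3: three changes
  mc <- rbind(c(95, 5, 5, 5),
              c(50, 50, 50, 50),
              c(95, 5, 95, 5))
  tot <- matrix(100, 3, 4)
  res <- callEpialleles(mc, tot)
  expect_equal(res$nTests, 9L)
  expect_equal(res$loci$nEpialleles, c(1, 0, 3))
  expect_equal(res$loci$isEpilocus, c(TRUE, FALSE, TRUE))
  expect_equal(res$loci$isHotspot, c(FALSE, FALSE, TRUE))
  expect_true(all(res$calls$padj >= res$calls$p - 1e-15))
  expect_error(callEpialleles(mc[, 1, drop = FALSE],
                              tot[, 1, drop = FALSE]), "2 generations")
})

test_that("methylated-region retention screens pooled levels", {
  mcPan <- c(400, 10, 0)
  totPan <- c(1000, 1000, 1000)
  genLevels <- rbind(c(0.35, 0.45), c(0.005, 0.015), c(0, 0))
  keep <- retainMethylatedRegions(mcPan, totPan, genLevels,
                                  nGenerations = 8)
  expect_equal(as.vector(keep), c(TRUE, FALSE, FALSE))
})

test_that("parent DMR filtering eliminates sibling overlaps and weak DMRs", {
  # 107-candidate toy set: 100 pass, of which 7 overlap a sibling DMR
  starts <- seq(1000, by = 1000, length.out = 107)
  parent <- gr(start = starts, end = starts + 99, levelDiff = 0.5)
  sib <- gr(start = starts[c(3, 10, 20, 30, 40, 50, 60)] + 99,
            end = starts[c(3, 10, 20, 30, 40, 50, 60)] + 300)
  out <- parentDmrFilter(parent, sib)
  expect_equal(length(out), 100L)     # 107 candidates - 7 overlapping
  # a 1-bp overlap is enough to eliminate
  p1 <- gr(start = 1, end = 100, levelDiff = 0.5)
  s1 <- gr(start = 100, end = 200)
  expect_equal(length(parentDmrFilter(p1, s1)), 0L)
  # a 20% level difference does not survive the 25% filter
  p2 <- gr(start = 1, end = 100, levelDiff = 0.20)
  expect_equal(length(parentDmrFilter(p2, GRanges())), 0L)
  # sub-40 bp DMRs are dropped
  p3 <- gr(start = 1, end = 39, levelDiff = 0.5)
  expect_equal(length(parentDmrFilter(p3, GRanges())), 0L)
})

test_that("feature assignment follows the priority order and sums to 1", {
  feats <- c(gr(50, 120, type = "CDS"),
             gr(50, 200, type = "TE"),
             gr(130, 160, type = "ncRNA"),
             gr(1, 60, type = "promoter"))
  # region 1-200: promoter 1-49 (49 bp; 50-60 lost to CDS priority? no:
  # CDS outranks promoter), CDS 50-120 (71), ncRNA 130-160 (31),
  # TE 121-129 and 161-200 (49), intergenic 0
  r <- assignFeatures(gr(1, 200), feats)
  expect_equal(unname(rowSums(r)), 1)
  expect_equal(unname(r[1, "ncRNA"]), 31 / 200)
  expect_equal(unname(r[1, "CDS"]), 71 / 200)
  expect_equal(unname(r[1, "promoter"]), 49 / 200)
  expect_equal(unname(r[1, "TE"]), 49 / 200)
  expect_equal(unname(r[1, "intergenic"]), 0)

  # a base covered by CDS and TE goes to CDS
  r2 <- assignFeatures(gr(50, 120), feats)
  expect_equal(unname(r2[1, "CDS"]), 1)
  expect_equal(unname(r2[1, "TE"]), 0)

  # bases in no feature are intergenic; 60 bp promoter + 40 bp intergenic
  feats3 <- gr(1, 60, type = "promoter")
  r3 <- assignFeatures(gr(1, 100), feats3)
  expect_equal(unname(r3[1, "promoter"]), 0.6)
  expect_equal(unname(r3[1, "intergenic"]), 0.4)

  expect_error(assignFeatures(gr(1, 10), gr(1, 5, type = "exon")),
               "malformed")
})

test_that("feature maps derive promoters and introns from gene models", {
  ann <- c(gr(1001, 3000, type = "gene", strand = "+"),
           gr(1001, 1500, type = "exon"),
           gr(2001, 3000, type = "exon"),
           gr(1101, 1500, type = "CDS"),
           gr(1001, 1100, type = "five_prime_UTR"),
           gr(5000, 5100, type = "tRNA"),
           gr(4000, 4200, type = "transposable_element"))
  fm <- buildFeatureMap(ann)
  expect_true(all(c("promoter", "intron", "UTR", "CDS", "ncRNA", "TE") %in%
                  S4Vectors::mcols(fm)$type))
  prom <- fm[S4Vectors::mcols(fm)$type == "promoter"]
  expect_equal(start(prom), 1)      # trimmed at the chromosome start
  expect_equal(end(prom), 1000)
  intr <- fm[S4Vectors::mcols(fm)$type == "intron"]
  expect_equal(start(intr), 1501)
  expect_equal(end(intr), 2000)
})

test_that("the centromere sits at the spline minimum of gene density", {
  # V-shaped density over a 30-Mb chromosome with vertex at 14.8 Mb
  set.seed(62)
  mids <- (seq_len(300) - 0.5) * 1e5
  dens <- abs(mids - 14.8e6) / 1e5 + stats::rnorm(300, 0, 0.5)
  cen <- defineCentromere(dens)
  expect_equal(cen$center, 14.8e6, tolerance = 0.02)
  expect_equal(cen$interval, c(13.3e6, 16.3e6), tolerance = 0.02)
  expect_warning(flat <- defineCentromere(rep(5, 100)), "flat")
  expect_true(is.na(flat$center))
})

test_that("the packaged centromere table covers the five chromosomes", {
  cen <- athalianaCentromeres()
  expect_equal(sort(unique(cen$chrom)), paste0("Chr", 1:5))
  expect_true(all(cen$end > cen$start))
  expect_equal(sum(cen$chrom == "Chr4"), 2L)
})
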