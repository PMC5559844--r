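# Region-level machinery: summarizing methylomes over candidate regions,
# retention filters for methylated regions and transgenerational epialleles,
# z-tests for level differences, parent-parent DMR filtering against
# sibling-specific DMRs, genomic-feature categorization, and the
# gene-density centromere definition. Regions are GRanges (1-based, closed,
# as is standard for GRanges); widths therefore use GenomicRanges::width.

#' Summarize methylomes over regions
#'
#' For each region and sample, sums methylated and total reads over the
#' cytosines falling inside the region and counts cytosines covered by at
#' least `minCov` reads in every sample.
#'
#' @param regions `GRanges` of candidate regions.
#' @param tables named list of [MethylomeTable-class] objects.
#' @param minCov coverage threshold defining a "covered" cytosine.
#' @return list with matrices `mc`, `total`, `level` (regions x samples) and
#'   vector `nCytosines` (cytosines covered `>= minCov` in all samples).
#' @export
regionLevels <- function(regions, tables, minCov = 3) {
  stopifnot(is(regions, "GRanges"), length(tables) >= 1)
  ns <- length(tables)
  nr <- length(regions)
  ids <- names(tables)
  if (is.null(ids)) ids <- vapply(tables, sampleId, "")
  mc <- total <- matrix(0, nr, ns, dimnames = list(NULL, ids))
  coveredAll <- NULL
  hitsList <- vector("list", ns)
  for (s in seq_len(ns)) {
    d <- tables[[s]]@data
    gr <- GenomicRanges::GRanges(d$chrom,
                                 IRanges::IRanges(d$pos, width = 1))
    h <- GenomicRanges::findOverlaps(gr, regions)
    hitsList[[s]] <- h
    qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
    mc[, s] <- as.numeric(tapply(d$mc[qi], factor(si, levels = seq_len(nr)),
                                 sum, default = 0))
    total[, s] <- as.numeric(tapply(d$total[qi],
                                    factor(si, levels = seq_len(nr)),
                                    sum, default = 0))
  }
  # cytosines covered >= minCov in all samples, keyed by chrom:pos
  keyCov <- NULL
  for (s in seq_len(ns)) {
    d <- tables[[s]]@data
    k <- paste(d$chrom, d$pos)[d$total >= minCov]
    keyCov <- if (is.null(keyCov)) k else intersect(keyCov, k)
  }
  d1 <- tables[[1]]@data
  k1 <- paste(d1$chrom, d1$pos)
  covered <- k1 %in% keyCov
  gr1 <- GenomicRanges::GRanges(d1$chrom, IRanges::IRanges(d1$pos, width = 1))
  h1 <- GenomicRanges::findOverlaps(gr1[covered], regions)
  nCytosines <- as.numeric(table(factor(S4Vectors::subjectHits(h1),
                                        levels = seq_len(nr))))
  level <- ifelse(total > 0, mc / total, NA_real_)
  list(mc = mc, total = total, level = level, nCytosines = nCytosines)
}

#' Filter candidate epiallele regions
#'
#' Retains regions at least `minLen` bp long, with at least `minCytosines`
#' cytosines covered by at least the coverage threshold in all samples, and
#' with at least `minSpan` difference between the highest and lowest
#' per-sample methylation level.
#'
#' @param regions `GRanges` of candidates.
#' @param levels matrix (regions x samples/generations) of methylation
#'   levels.
#' @param nCytosines per-region count of sufficiently covered cytosines
#'   (see [regionLevels()]).
#' @param minLen minimum region length in bp.
#' @param minCytosines minimum covered cytosines.
#' @param minSpan minimum level span across samples.
#' @return Logical vector of retained regions (subset with
#'   `regions[filterRegions(...)]`).
#' @export
filterRegions <- function(regions, levels, nCytosines, minLen = 40,
                          minCytosines = 10, minSpan = 0.20) {
  stopifnot(is(regions, "GRanges"),
            nrow(levels) == length(regions),
            length(nCytosines) == length(regions))
  span <- apply(levels, 1, function(z) {
    z <- z[!is.na(z)]
    if (!length(z)) return(NA_real_)
    max(z) - min(z)
  })
  GenomicRanges::width(regions) >= minLen &
    nCytosines >= minCytosines &
    !is.na(span) & span >= minSpan
}

#' One-sided z-test for a methylation-level difference exceeding a margin
#'
#' Tests whether the absolute difference between two methylation levels
#' exceeds `delta`, using region-summed counts and the unpooled binomial
#' standard error: z = (|p1 - p2| - delta) / sqrt(p1(1-p1)/n1 +
#' p2(1-p2)/n2), with the p-value from the upper normal tail.
#'
#' @param mc1,total1,mc2,total2 region-summed methylated and total read
#'   counts for the two samples/generations (vectorized).
#' @param delta margin the difference must exceed (default 0.25).
#' @return list with vectors `z` and `p` (`NA` where a total is zero).
#' @export
ztestLevelDifference <- function(mc1, total1, mc2, total2, delta = 0.25) {
  p1 <- ifelse(total1 > 0, mc1 / total1, NA_real_)
  p2 <- ifelse(total2 > 0, mc2 / total2, NA_real_)
  se <- sqrt(p1 * (1 - p1) / total1 + p2 * (1 - p2) / total2)
  d <- abs(p1 - p2)
  z <- ifelse(se > 0, (d - delta) / se,
              ifelse(d > delta, Inf, -Inf))
  z[is.na(p1) | is.na(p2)] <- NA_real_
  list(z = z, p = stats::pnorm(z, lower.tail = FALSE))
}

#' Call transgenerational epialleles and epiloci
#'
#' For every filtered region, applies the one-sided z-test for a
#' greater-than-`delta` level difference between each pair of adjacent
#' generations, BH-adjusts across all tests in the line, and calls an
#' epiallele where the adjusted p-value is at most `alpha`. Regions with at
#' least one epiallele are epiloci; regions with multiple methylation-state
#' changes between generations are flagged as instability hotspots.
#'
#' @param mc,total matrices (regions x generations, columns in generation
#'   order) of region-summed counts.
#' @param delta level-difference margin.
#' @param alpha adjusted-p threshold.
#' @return list with `calls` (one row per region x adjacent-generation
#'   pair: `z`, `p`, `padj`, `isEpiallele`), `loci` (per region:
#'   `nEpialleles`, `isEpilocus`, `isHotspot`), and `nTests` (the BH family
#'   size).
#' @export
callEpialleles <- function(mc, total, delta = 0.25, alpha = 0.05) {
  mc <- as.matrix(mc); total <- as.matrix(total)
  ng <- ncol(mc)
  if (ng < 2) stop("need at least 2 generations")
  nr <- nrow(mc)
  calls <- do.call(rbind, lapply(seq_len(ng - 1), function(g) {
    zt <- ztestLevelDifference(mc[, g], total[, g], mc[, g + 1],
                               total[, g + 1], delta)
    data.frame(region = seq_len(nr), fromGen = g, toGen = g + 1,
               z = zt$z, p = zt$p)
  }))
  calls$padj <- stats::p.adjust(calls$p, method = "BH")
  calls$isEpiallele <- !is.na(calls$padj) & calls$padj <= alpha
  nEpi <- as.numeric(tapply(calls$isEpiallele,
                            factor(calls$region, levels = seq_len(nr)), sum))
  loci <- data.frame(region = seq_len(nr), nEpialleles = nEpi,
                     isEpilocus = nEpi >= 1, isHotspot = nEpi >= 2)
  list(calls = calls[order(calls$region, calls$fromGen), ],
       loci = loci, nTests = sum(!is.na(calls$p)))
}

#' Retention test for methylated regions
#'
#' One-sided z-test that a region's pooled (pan-methylome) methylation level
#' exceeds an expected level of 25% in at least one generation, i.e.
#' 0.25 / nGenerations on the pooled counts; p-values are BH-adjusted.
#' Regions where every generation's level is below `minLevel` are removed
#' regardless. The intent of the pooled-level threshold is a conservative
#' screen for regions methylated in at least one generation; see the
#' methods vignette for the interpretation adopted.
#'
#' @param mcPan,totalPan pooled region-summed counts across generations.
#' @param genLevels matrix (regions x generations) of per-generation
#'   levels.
#' @param nGenerations number of generations in the line.
#' @param minLevel floor below which a region is removed when no generation
#'   reaches it.
#' @param alpha adjusted-p threshold.
#' @return Logical vector of retained regions, with attribute `padj`.
#' @export
retainMethylatedRegions <- function(mcPan, totalPan, genLevels, nGenerations,
                                    minLevel = 0.10, alpha = 0.05) {
  p0 <- 0.25 / nGenerations
  phat <- ifelse(totalPan > 0, mcPan / totalPan, NA_real_)
  se <- sqrt(phat * (1 - phat) / totalPan)
  z <- ifelse(!is.na(se) & se > 0, (phat - p0) / se,
              ifelse(phat > p0, Inf, -Inf))
  p <- stats::pnorm(z, lower.tail = FALSE)
  padj <- stats::p.adjust(p, method = "BH")
  anyHigh <- apply(as.matrix(genLevels), 1, function(l)
    any(!is.na(l) & l >= minLevel))
  keep <- !is.na(padj) & padj <= alpha & anyHigh
  attr(keep, "padj") <- padj
  keep
}

#' Filter parent-parent DMRs against sibling-specific DMRs
#'
#' Retains differentially methylated regions between the parents that are at
#' least `minLen` bp long and show at least `minDiff` absolute difference in
#' methylation level, then eliminates any that overlap (by >= 1 bp) a
#' sibling-specific DMR, since such regions reflect variation within a
#' parental line rather than between the parents.
#'
#' @param parentDmrs `GRanges` of parent-parent DMRs with a numeric
#'   metadata column `levelDiff` (absolute parental level difference).
#' @param siblingDmrs `GRanges` of sibling-specific DMRs.
#' @param minLen minimum DMR length in bp.
#' @param minDiff minimum absolute level difference.
#' @return The retained `GRanges`.
#' @export
parentDmrFilter <- function(parentDmrs, siblingDmrs, minLen = 40,
                            minDiff = 0.25) {
  stopifnot(is(parentDmrs, "GRanges"), is(siblingDmrs, "GRanges"),
            "levelDiff" %in% names(S4Vectors::mcols(parentDmrs)))
  keep <- GenomicRanges::width(parentDmrs) >= minLen &
    S4Vectors::mcols(parentDmrs)$levelDiff >= minDiff
  out <- parentDmrs[keep]
  ov <- GenomicRanges::countOverlaps(out, siblingDmrs) > 0
  out[!ov]
}

.FEATURE_PRIORITY <- c("ncRNA", "UTR", "intron", "CDS", "promoter", "TE")

#' Assign genomic-feature proportions to regions
#'
#' Every base of a region is assigned exactly one feature type by priority:
#' non-coding RNA (highest), untranslated region, intron, coding sequence,
#' promoter, transposable element (lowest); bases in no feature are
#' intergenic. The result is the proportion of region bases per type.
#'
#' @param regions `GRanges`.
#' @param features `GRanges` with a metadata column `type` taking values in
#'   `c("ncRNA", "UTR", "intron", "CDS", "promoter", "TE")`.
#' @return Matrix (regions x feature types, plus `intergenic`), rows
#'   summing to 1.
#' @export
assignFeatures <- function(regions, features) {
  stopifnot(is(regions, "GRanges"), is(features, "GRanges"),
            "type" %in% names(S4Vectors::mcols(features)))
  types <- S4Vectors::mcols(features)$type
  if (!all(types %in% .FEATURE_PRIORITY))
    stop("malformed annotation: unknown feature type(s) ",
         paste(setdiff(types, .FEATURE_PRIORITY), collapse = ", "))
  out <- matrix(0, length(regions), length(.FEATURE_PRIORITY) + 1,
                dimnames = list(NULL, c(.FEATURE_PRIORITY, "intergenic")))
  byType <- lapply(.FEATURE_PRIORITY, function(t)
    GenomicRanges::reduce(BiocGenerics::unstrand(
      GenomicRanges::granges(features[types == t]))))
  for (r in seq_along(regions)) {
    rem <- BiocGenerics::unstrand(GenomicRanges::granges(regions[r]))
    w <- GenomicRanges::width(rem)
    for (ti in seq_along(.FEATURE_PRIORITY)) {
      hit <- GenomicRanges::intersect(rem, byType[[ti]])
      bp <- sum(GenomicRanges::width(hit))
      out[r, ti] <- bp
      if (bp > 0) rem <- GenomicRanges::setdiff(rem, hit)
    }
    out[r, "intergenic"] <- sum(GenomicRanges::width(rem))
    out[r, ] <- out[r, ] / w
  }
  out
}

#' Build a typed feature map from a GFF-style annotation
#'
#' Maps common annotation types onto the six feature classes used by
#' [assignFeatures()]: non-coding RNA types to `ncRNA`, five/three prime
#' UTRs to `UTR`, `CDS` to `CDS`, transposable elements to `TE`; introns
#' are gene bodies minus exons, and promoters are the 1 kb upstream of each
#' protein-coding gene's transcription start site.
#'
#' @param annotation `GRanges` with a `type` metadata column using GFF3
#'   feature types (`gene`, `exon`, `CDS`, `five_prime_UTR`,
#'   `three_prime_UTR`, `ncRNA`/`tRNA`/`rRNA`/`miRNA`/`snoRNA`/`snRNA`/
#'   `lnc_RNA`, `transposable_element`).
#' @param promoterWidth upstream promoter width in bp.
#' @return `GRanges` with a `type` column suitable for [assignFeatures()].
#' @export
buildFeatureMap <- function(annotation, promoterWidth = 1000) {
  stopifnot(is(annotation, "GRanges"),
            "type" %in% names(S4Vectors::mcols(annotation)))
  tp <- as.character(S4Vectors::mcols(annotation)$type)
  pick <- function(types)
    GenomicRanges::reduce(BiocGenerics::unstrand(
      GenomicRanges::granges(annotation[tp %in% types])))
  genesStranded <- GenomicRanges::granges(annotation[tp == "gene"])
  genes <- pick("gene")
  exons <- pick("exon")
  introns <- GenomicRanges::setdiff(genes, exons)
  prom <- BiocGenerics::unstrand(IRanges::restrict(GenomicRanges::promoters(
    genesStranded, upstream = promoterWidth, downstream = 0), start = 1L))
  pieces <- list(
    ncRNA = pick(c("ncRNA", "tRNA", "rRNA", "miRNA", "snoRNA", "snRNA",
                   "lnc_RNA", "ncRNA_gene")),
    UTR = pick(c("five_prime_UTR", "three_prime_UTR")),
    intron = introns,
    CDS = pick("CDS"),
    promoter = prom,
    TE = pick(c("transposable_element", "transposable_element_gene")))
  out <- do.call(c, unname(lapply(names(pieces), function(nm) {
    g <- pieces[[nm]]
    S4Vectors::mcols(g)$type <- if (length(g)) nm else character()
    g
  })))
  out
}

#' Locate a centromere from gene density
#'
#' Fits a smoothing spline to per-window gene density along the chromosome;
#' the spline's minimum is taken as the centromere center and the
#' centromere as `halfWidth` bp on either side. Chromosomes with flat
#' density yield a warning and an undefined interval.
#'
#' @param density numeric vector of gene-bp counts per window.
#' @param windowSize window width in bp (default 100 kb).
#' @param halfWidth half-width of the reported interval (default 1.5 Mb).
#' @return list with `center` and `interval` (`c(start, end)` clamped at 0),
#'   or `NA` values when undefined.
#' @export
defineCentromere <- function(density, windowSize = 1e5, halfWidth = 1.5e6) {
  if (length(unique(density)) < 2) {
    warning("flat density: centromere undefined")
    return(list(center = NA_real_, interval = c(NA_real_, NA_real_)))
  }
  mid <- (seq_along(density) - 0.5) * windowSize
  fit <- stats::smooth.spline(mid, density)
  grid <- seq(min(mid), max(mid), by = 1000)
  pred <- stats::predict(fit, grid)$y
  center <- grid[which.min(pred)]
  list(center = center,
       interval = c(max(0, center - halfWidth), center + halfWidth))
}

#' Conventional A. thaliana centromere intervals
#'
#' The spline-minimum definition (center +/- 1.5 Mb) for chromosomes 1, 2,
#' 3, and 5 of the TAIR10 assembly, with the chromosome-4 centromere split
#' around the heterochromatic knob. Usable directly as the `centromeres`
#' argument of [epigenotypePipeline()]; user-supplied intervals always
#' override.
#'
#' @return `data.frame` with `chrom`, `start`, `end` (0-based half-open,
#'   bp).
#' @export
athalianaCentromeres <- function() {
  data.frame(
    chrom = c("Chr1", "Chr2", "Chr3", "Chr4", "Chr4", "Chr5"),
    start = c(13.3e6, 2.4e6, 12e6, 1.6e6, 2.9e6, 10.4e6),
    end = c(16.3e6, 5.4e6, 15e6, 1.9e6, 5e6, 13.4e6))
}
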