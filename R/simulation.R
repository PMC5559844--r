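# Simulation validator: synthetic parental methylomes with differentially
# methylated positions, F2 offspring produced by recombination blocks plus
# bounded uniform error, and micro-F1 scoring of the recovered maps.

.simSeed <- function(seed, iteration, sample = 0L) {
  # deterministic per-(iteration, sample) stream; keep below 2^31
  as.integer((as.numeric(seed) * 48271 + iteration * 7919 + sample * 104729)
             %% 2147483587)
}

#' Generate two synthetic parental methylomes
#'
#' Scatters `nPositions` cytosines uniformly along one chromosome. At each
#' position one randomly chosen parent draws a high methylation level from
#' Beta(8, 2) and the other a low level from Beta(2, 8). Levels are stored as
#' counts with total 100 (mc = round(level * 100)) so the level implied by
#' the counts is exact, and the methylation call is assigned by construction
#' (high parent methylated, low parent not), making every position
#' informative between the parents.
#'
#' @param nPositions number of differentially methylated positions.
#' @param chromLength chromosome length in bp (default 20 Mb).
#' @param seed RNG seed.
#' @param chrom chromosome name.
#' @return list with elements `mother` and `father`
#'   ([MethylomeTable-class]).
#' @export
synthParents <- function(nPositions, chromLength = 20e6, seed = 1,
                         chrom = "chr3") {
  stopifnot(nPositions >= 0)
  if (nPositions == 0) {
    empty <- data.frame(chrom = character(), pos = integer(),
                        strand = character(), context = character(),
                        mc = integer(), total = integer(),
                        is_methylated = logical())
    out <- list(mother = MethylomeTable(empty, "mother"),
                father = MethylomeTable(empty, "father"))
    attr(out, "chromLength") <- chromLength
    return(out)
  }
  set.seed(.simSeed(seed, 0L))
  pos <- sort(sample.int(chromLength, nPositions))
  high <- stats::rbeta(nPositions, 8, 2)
  low <- stats::rbeta(nPositions, 2, 8)
  motherHigh <- stats::runif(nPositions) < 0.5
  build <- function(levels, meth, id) {
    mc <- as.integer(round(levels * 100))
    MethylomeTable(data.frame(chrom = chrom, pos = pos, strand = "+",
                              context = "CG", mc = mc, total = 100L,
                              is_methylated = meth), id)
  }
  out <- list(mother = build(ifelse(motherHigh, high, low), motherHigh,
                             "mother"),
              father = build(ifelse(motherHigh, low, high), !motherHigh,
                             "father"))
  attr(out, "chromLength") <- chromLength
  out
}

#' Simulate an F2 offspring methylome with known genotype blocks
#'
#' Places `nBreakpoints` equally spaced potential breakpoints along the
#' chromosome and draws a genotype (maternal, heterozygous, paternal, with
#' probabilities 0.25/0.5/0.25) independently for each resulting region;
#' adjacent regions may share a genotype, so the number of actual genotype
#' changes is between 0 and `nBreakpoints`. At each parental differentially
#' methylated position, the expected level `x` is the maternal, mid-parent,
#' or paternal level according to the region's genotype, and the simulated
#' level is drawn uniformly from `[max(0, x - y), min(1, x + y)]`.
#'
#' @param parents list with `mother` and `father` tables (see
#'   [synthParents()]; any parental pair over shared positions works).
#' @param nBreakpoints number of equally spaced potential breakpoints.
#' @param y per-position uniform error half-width in `[0, 1]`.
#' @param seed RNG seed.
#' @param sampleId offspring identifier.
#' @return list with `methylome` ([MethylomeTable-class], counts with total
#'   100) and `truth` (`data.frame` of `start`, `end` 0-based half-open and
#'   `genotype` in `MOTHER`/`HET`/`FATHER`).
#' @export
simulateOffspring <- function(parents, nBreakpoints, y, seed = 1,
                              sampleId = "sim") {
  if (y < 0 || y > 1) stop("error parameter y must lie in [0, 1]")
  m <- parents$mother@data; f <- parents$father@data
  stopifnot(identical(m$pos, f$pos), identical(m$chrom, f$chrom))
  chromLength <- attr(parents, "chromLength")
  if (is.null(chromLength)) chromLength <- max(m$pos)
  set.seed(seed)
  cuts <- if (nBreakpoints > 0)
    chromLength * seq_len(nBreakpoints) / (nBreakpoints + 1) else numeric()
  starts <- c(0, cuts); ends <- c(cuts, chromLength)
  geno <- sample(c("MOTHER", "HET", "FATHER"), length(starts),
                 replace = TRUE, prob = c(0.25, 0.5, 0.25))
  lvM <- m$mc / m$total; lvF <- f$mc / f$total
  region <- findInterval(m$pos - 1, starts)
  x <- ifelse(geno[region] == "MOTHER", lvM,
              ifelse(geno[region] == "FATHER", lvF, (lvM + lvF) / 2))
  lo <- pmax(0, x - y); hi <- pmin(1, x + y)
  lvl <- stats::runif(length(x), lo, hi)
  meth <- MethylomeTable(data.frame(chrom = m$chrom, pos = m$pos,
                                    strand = m$strand, context = m$context,
                                    mc = as.integer(round(lvl * 100)),
                                    total = 100L, is_methylated = NA),
                         sampleId)
  list(methylome = meth,
       truth = data.frame(start = starts, end = ends, genotype = geno))
}

#' Project simulated truth onto a bin structure
#'
#' Each bin is assigned the genotype covering the largest share of its
#' width; `HET` is mapped to the `MPV` state label used by the pipeline.
#'
#' @param truth a `truth` data.frame from [simulateOffspring()].
#' @param bins bin `data.frame` with `start`, `end` (e.g. from
#'   [binTable()]).
#' @return Character vector of per-bin states.
#' @export
truthToBins <- function(truth, bins) {
  lab <- c(MOTHER = "MOTHER", HET = "MPV", FATHER = "FATHER")
  vapply(seq_len(nrow(bins)), function(b) {
    ov <- pmin(truth$end, bins$end[b]) - pmax(truth$start, bins$start[b])
    g <- truth$genotype[which.max(ov)]
    lab[[g]]
  }, "")
}

#' Micro-averaged F1 score of predicted bin states
#'
#' Micro-averaging pools true positives, false positives, and false
#' negatives over the three classes; for single-label multiclass prediction
#' this equals the fraction of correctly labeled bins.
#'
#' @param predicted,truth equal-length per-bin state vectors.
#' @return Score in `[0, 1]`.
#' @export
accuracyF1 <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and truth must share the bin structure")
  tp <- sum(predicted == truth)
  fp <- sum(predicted != truth)   # every wrong label is one FP and one FN
  fn <- fp
  2 * tp / (2 * tp + fp + fn)
}

#' Run the simulation validation grid
#'
#' For each iteration, simulates `nSamples` offspring (sample `s` carrying
#' `s - 1` potential breakpoints) from the parents and, for every
#' (error, bin size) combination, runs the full epigenotyping pipeline and
#' scores each sample's final map against the simulated truth with
#' [accuracyF1()]. No centromere mask is applied.
#'
#' @param config a [SimulationConfig-class].
#' @param parents parent list from [synthParents()].
#' @param chromLength chromosome length in bp.
#' @return `data.frame` with one row per (sample, y, binSize): mean accuracy
#'   over iterations in `meanF1`.
#' @export
runGrid <- function(config, parents, chromLength = 20e6) {
  stopifnot(is(config, "SimulationConfig"))
  chrom <- parents$mother@data$chrom[1]
  chromLengths <- stats::setNames(chromLength, chrom)
  res <- list()
  for (it in seq_len(config@iterations)) {
    # one genotype assignment per (iteration, sample, y); all bin sizes share it
    for (y in config@errors) {
      sims <- lapply(seq_len(config@nSamples), function(s)
        simulateOffspring(parents, nBreakpoints = s - 1L, y = y,
                          seed = .simSeed(config@seed, it, s),
                          sampleId = paste0("sim", s)))
      offspring <- stats::setNames(lapply(sims, `[[`, "methylome"),
                                   paste0("sim", seq_len(config@nSamples)))
      for (bs in config@binSizes) {
        map <- epigenotypePipeline(parents$mother, parents$father, offspring,
                                   binSize = bs, chromLengths = chromLengths)
        bins <- binTable(map)
        fin <- finalStates(map)
        for (s in seq_len(config@nSamples)) {
          tr <- truthToBins(sims[[s]]$truth, bins)
          res[[length(res) + 1]] <- data.frame(
            iteration = it, sample = s, y = y, binSize = bs,
            f1 = accuracyF1(fin[, paste0("sim", s)], tr))
        }
      }
    }
  }
  res <- do.call(rbind, res)
  agg <- stats::aggregate(f1 ~ sample + y + binSize, data = res, FUN = mean)
  names(agg)[names(agg) == "f1"] <- "meanF1"
  agg[order(agg$y, agg$binSize, agg$sample), ]
}
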