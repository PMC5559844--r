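# Central S4 classes. State order is fixed package-wide: MOTHER < MPV < FATHER.
# All argmax tie-breaks use this order.

.STATES <- c("MOTHER", "MPV", "FATHER")

.VALID_CONTEXTS <- c("CG", "CHG", "CHH")

#' MethylomeTable: per-cytosine methylation counts for one sample
#'
#' Holds one sample's per-cytosine methylation data in allc-style form:
#' chromosome, 1-based position, strand, trinucleotide context class, count of
#' methylated reads (`mc`), total read count, and the binomial-test
#' methylation call (`is_methylated`, may be `NA` when no call has been made).
#'
#' @slot sampleId single character identifier.
#' @slot data `data.frame` with columns `chrom`, `pos`, `strand`, `context`,
#'   `mc`, `total`, `is_methylated`, sorted by chromosome then position.
#' @export
setClass("MethylomeTable",
  representation(sampleId = "character", data = "data.frame"))

.validMethylomeTable <- function(object) {
  d <- object@data
  msgs <- character()
  need <- c("chrom", "pos", "strand", "context", "mc", "total", "is_methylated")
  if (!all(need %in% names(d)))
    return(paste("missing columns:", paste(setdiff(need, names(d)), collapse = ", ")))
  if (length(object@sampleId) != 1L)
    msgs <- c(msgs, "sampleId must be a single string")
  if (nrow(d)) {
    if (any(d$mc > d$total)) msgs <- c(msgs, "mc exceeds total")
    if (any(d$mc < 0)) msgs <- c(msgs, "negative mc")
    if (any(d$total < 1)) msgs <- c(msgs, "total must be positive")
    if (!all(d$context %in% .VALID_CONTEXTS))
      msgs <- c(msgs, "context must be one of CG, CHG, CHH")
    if (!all(d$strand %in% c("+", "-")))
      msgs <- c(msgs, "strand must be + or -")
    if (anyNA(d$pos) || any(tapply(d$pos, d$chrom, function(p) any(diff(p) <= 0))))
      msgs <- c(msgs, "positions must be strictly increasing within a chromosome")
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("MethylomeTable", .validMethylomeTable)

#' Construct a MethylomeTable
#'
#' Rows are sorted by chromosome and position; validity (counts, contexts,
#' strictly increasing positions) is enforced.
#'
#' @param data data.frame with columns `chrom`, `pos`, `strand`, `context`,
#'   `mc`, `total` and optionally `is_methylated`.
#' @param sampleId sample identifier.
#' @return A [MethylomeTable-class] object.
#' @export
MethylomeTable <- function(data, sampleId = "sample") {
  if (is.null(data$is_methylated)) data$is_methylated <- NA
  data <- data[, c("chrom", "pos", "strand", "context", "mc", "total",
                   "is_methylated")]
  data$chrom <- as.character(data$chrom)
  data$pos <- as.integer(data$pos)
  data$mc <- as.integer(data$mc)
  data$total <- as.integer(data$total)
  data$is_methylated <- as.logical(data$is_methylated)
  data <- data[order(data$chrom, data$pos), , drop = FALSE]
  rownames(data) <- NULL
  methods::new("MethylomeTable", sampleId = as.character(sampleId), data = data)
}

#' BinSet: fixed-width chromosome bins with their informative positions
#'
#' Produced by [makeBins()]. Bins tile each chromosome with 0-based half-open
#' coordinates; neighbouring bins holding fewer than the minimum number of
#' informative positions have been merged.
#'
#' @slot bins `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open), `nPositions`, `isCentromere`.
#' @slot positions list (one element per bin row) of the 1-based informative
#'   positions falling in the bin.
#' @slot binSize the requested bin width in bp before merging.
#' @export
setClass("BinSet",
  representation(bins = "data.frame", positions = "list", binSize = "numeric"))

setValidity("BinSet", function(object) {
  b <- object@bins
  msgs <- character()
  if (!all(c("chrom", "start", "end", "nPositions", "isCentromere") %in% names(b)))
    return("bins must have chrom, start, end, nPositions, isCentromere")
  if (length(object@positions) != nrow(b))
    msgs <- c(msgs, "positions list length must equal number of bins")
  if (nrow(b)) {
    if (any(b$end <= b$start)) msgs <- c(msgs, "bin end must exceed start")
    if (!all(b$nPositions == lengths(object@positions)))
      msgs <- c(msgs, "nPositions inconsistent with positions list")
    tiled <- tapply(seq_len(nrow(b)), b$chrom, function(i)
      all(b$start[i][-1] == b$end[i][-length(i)]))
    if (!all(unlist(tiled))) msgs <- c(msgs, "bins must tile each chromosome")
  }
  if (length(msgs)) msgs else TRUE
})

#' EpigenotypeMap: per-bin parent-of-origin state across samples
#'
#' Stores the three stages of the epigenotyping procedure for every classified
#' sample: logistic-regression class probabilities and preliminary states,
#' forward-backward posteriors and states, and the final Viterbi states. Also
#' records the per-chromosome transition matrices estimated at each stage.
#'
#' @slot bins bin `data.frame` as in [BinSet-class].
#' @slot samples character vector of classified sample ids.
#' @slot roles character vector parallel to `samples` (`mother`, `father`,
#'   `mpv`, `offspring`, `mother_rep`, `father_rep`, `mpv_rep`).
#' @slot lrProbs,fbPosteriors numeric arrays `[bins, 3 states, samples]`.
#' @slot lrStates,fbStates,finalStates character matrices `[bins, samples]`.
#' @slot uninformative logical per bin: classifier training vectors identical.
#' @slot transitions per-chromosome list with elements `lr` and `fb`, the
#'   transition matrices used by the forward-backward and Viterbi stages.
#' @export
setClass("EpigenotypeMap",
  representation(bins = "data.frame", samples = "character",
                 roles = "character", lrProbs = "array",
                 fbPosteriors = "array", lrStates = "matrix",
                 fbStates = "matrix", finalStates = "matrix",
                 uninformative = "logical", transitions = "list"))

setValidity("EpigenotypeMap", function(object) {
  nb <- nrow(object@bins); ns <- length(object@samples)
  msgs <- character()
  if (!identical(dim(object@lrProbs), c(nb, 3L, ns)))
    msgs <- c(msgs, "lrProbs must be [bins, 3, samples]")
  if (!identical(dim(object@fbPosteriors), c(nb, 3L, ns)))
    msgs <- c(msgs, "fbPosteriors must be [bins, 3, samples]")
  if (!identical(dim(object@finalStates), c(nb, ns)))
    msgs <- c(msgs, "finalStates must be [bins, samples]")
  if (length(object@roles) != ns)
    msgs <- c(msgs, "roles must parallel samples")
  if (nb && ns) {
    if (anyNA(object@finalStates) || !all(object@finalStates %in% .STATES))
      msgs <- c(msgs, "finalStates must be defined for every bin")
    s1 <- apply(object@lrProbs, c(1, 3), sum)
    s2 <- apply(object@fbPosteriors, c(1, 3), sum)
    if (max(abs(s1 - 1)) > 1e-6 || max(abs(s2 - 1)) > 1e-6)
      msgs <- c(msgs, "probability vectors must sum to 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' SimulationConfig: grid settings for the simulation validator
#'
#' Defaults reproduce the validation design: 20 simulated offspring carrying
#' 0 to 19 equally spaced potential breakpoints, per-position uniform error
#' levels from 0 to 1 in steps of 0.1, bin sizes from 10 to 500 kb, and 25
#' iterations per condition.
#'
#' @slot nSamples number of simulated offspring per iteration; sample `s`
#'   carries `s - 1` potential breakpoints.
#' @slot errors vector of error half-widths `y` in `[0, 1]`.
#' @slot binSizes vector of bin widths in bp.
#' @slot iterations iterations per condition; reported accuracy is their mean.
#' @slot seed base RNG seed.
#' @export
setClass("SimulationConfig",
  representation(nSamples = "integer", errors = "numeric",
                 binSizes = "numeric", iterations = "integer",
                 seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  if (any(object@errors < 0 | object@errors > 1))
    msgs <- c(msgs, "errors must lie in [0, 1]")
  if (object@nSamples < 1L) msgs <- c(msgs, "nSamples must be >= 1")
  if (object@iterations < 1L) msgs <- c(msgs, "iterations must be >= 1")
  if (any(object@binSizes <= 0)) msgs <- c(msgs, "binSizes must be positive")
  if (length(msgs)) msgs else TRUE
})

#' @rdname SimulationConfig-class
#' @param nSamples,errors,binSizes,iterations,seed see slot documentation.
#' @return A `SimulationConfig` object.
#' @export
simulationConfig <- function(nSamples = 20, errors = seq(0, 1, by = 0.1),
                             binSizes = c(10, 20, 50, 100, 200, 500) * 1000,
                             iterations = 25, seed = 1) {
  methods::new("SimulationConfig", nSamples = as.integer(nSamples),
               errors = as.numeric(errors), binSizes = as.numeric(binSizes),
               iterations = as.integer(iterations), seed = as.integer(seed))
}
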