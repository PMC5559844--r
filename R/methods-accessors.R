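#' @rdname MethylomeTable-class
#' @export
setMethod("sampleId", "MethylomeTable", function(x) x@sampleId)

#' @rdname MethylomeTable-class
#' @export
setMethod("methData", "MethylomeTable", function(x) x@data)

#' @describeIn MethylomeTable-class number of cytosine records.
#' @export
setMethod("length", "MethylomeTable", function(x) nrow(x@data))

#' @describeIn MethylomeTable-class coerce to the underlying data.frame.
#' @param row.names,optional,... passed on for S3/S4 consistency (unused).
#' @export
setMethod("as.data.frame", "MethylomeTable",
  function(x, row.names = NULL, optional = FALSE, ...) x@data)

setMethod("show", "MethylomeTable", function(object) {
  d <- object@data
  cat("MethylomeTable '", object@sampleId, "': ", nrow(d), " cytosines",
      sep = "")
  if (nrow(d)) {
    cat(" on ", length(unique(d$chrom)), " chromosome(s)", sep = "")
    called <- sum(!is.na(d$is_methylated))
    cat("; ", called, " with methylation calls", sep = "")
  }
  cat("\n")
})

#' @rdname BinSet-class
#' @export
setMethod("binTable", "BinSet", function(x) x@bins)

#' @rdname BinSet-class
#' @export
setMethod("binPositions", "BinSet", function(x) x@positions)

#' @describeIn BinSet-class number of bins.
#' @export
setMethod("length", "BinSet", function(x) nrow(x@bins))

setMethod("show", "BinSet", function(object) {
  b <- object@bins
  cat("BinSet: ", nrow(b), " bins (requested width ", object@binSize,
      " bp) on ", length(unique(b$chrom)), " chromosome(s); ",
      sum(b$isCentromere), " centromeric\n", sep = "")
})

#' @rdname EpigenotypeMap-class
#' @export
setMethod("binTable", "EpigenotypeMap", function(x) x@bins)

#' @rdname EpigenotypeMap-class
#' @export
setMethod("finalStates", "EpigenotypeMap", function(x) x@finalStates)

#' @rdname EpigenotypeMap-class
#' @export
setMethod("lrStates", "EpigenotypeMap", function(x) x@lrStates)

#' @rdname EpigenotypeMap-class
#' @export
setMethod("fbStates", "EpigenotypeMap", function(x) x@fbStates)

#' @rdname EpigenotypeMap-class
#' @export
setMethod("lrProbs", "EpigenotypeMap", function(x) x@lrProbs)

#' @rdname EpigenotypeMap-class
#' @export
setMethod("fbPosteriors", "EpigenotypeMap", function(x) x@fbPosteriors)

#' @rdname EpigenotypeMap-class
#' @export
setMethod("sampleRoles", "EpigenotypeMap",
  function(x) stats::setNames(x@roles, x@samples))

setMethod("show", "EpigenotypeMap", function(object) {
  cat("EpigenotypeMap: ", nrow(object@bins), " bins x ",
      length(object@samples), " samples (",
      sum(object@roles == "offspring"), " offspring)\n", sep = "")
  if (nrow(object@bins)) {
    tab <- table(factor(object@finalStates[, object@roles == "offspring"],
                        levels = .STATES))
    cat("  offspring final states: ",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  }
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: ", object@nSamples, " samples x ",
      object@iterations, " iterations; y in {",
      paste(object@errors, collapse = ", "), "}; bins {",
      paste(object@binSizes / 1000, collapse = ", "), "} kb; seed ",
      object@seed, "\n", sep = "")
})

#' Export an epigenotype map as a BED-like table
#'
#' @param x an `EpigenotypeMap`.
#' @param samples samples to include (default: all).
#' @return A long-format `data.frame` with columns `chrom`, `start`, `end`,
#'   `sample`, `state` and the stage probabilities for each of the three
#'   states.
#' @export
mapToBed <- function(x, samples = x@samples) {
  stopifnot(is(x, "EpigenotypeMap"), all(samples %in% x@samples))
  out <- do.call(rbind, lapply(samples, function(s) {
    i <- match(s, x@samples)
    data.frame(chrom = x@bins$chrom, start = x@bins$start, end = x@bins$end,
               sample = s, state = x@finalStates[, i],
               lr_mother = x@lrProbs[, 1, i], lr_mpv = x@lrProbs[, 2, i],
               lr_father = x@lrProbs[, 3, i],
               fb_mother = x@fbPosteriors[, 1, i],
               fb_mpv = x@fbPosteriors[, 2, i],
               fb_father = x@fbPosteriors[, 3, i])
  }))
  rownames(out) <- NULL
  out
}
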