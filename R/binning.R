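#' Tile a chromosome into bins and merge sparse bins
#'
#' Breaks the chromosome into consecutive fixed-width bins (last bin
#' shorter), counts the informative positions falling in each, and merges
#' any bin holding fewer than `minPositions` positions into its neighbor:
#' sparse bins merge forward into the next bin, and a sparse terminal bin
#' merges backward. Merging repeats until every bin satisfies the minimum or
#' a single bin remains.
#'
#' @param chromLength chromosome length in bp.
#' @param binSize requested bin width in bp.
#' @param positions 1-based informative positions on the chromosome.
#' @param minPositions minimum informative positions per bin.
#' @param chrom chromosome name recorded in the result.
#' @param centromere optional numeric `c(start, end)` (0-based half-open);
#'   bins overlapping it are flagged centromeric.
#' @return A [BinSet-class] for the chromosome.
#' @export
makeBins <- function(chromLength, binSize, positions, minPositions = 3,
                     chrom = "chr", centromere = NULL) {
  stopifnot(binSize > 0, chromLength > 0)
  positions <- sort(as.numeric(positions))
  if (any(positions < 1 | positions > chromLength))
    stop("positions outside [1, chromLength]")
  starts <- seq(0, chromLength - 1e-9, by = binSize)
  ends <- pmin(starts + binSize, chromLength)
  # position p (1-based) falls in bin with start <= p-1 < end
  binOf <- findInterval(positions - 1, starts)
  counts <- tabulate(binOf, nbins = length(starts))
  while (length(counts) > 1 && any(counts < minPositions)) {
    i <- which(counts < minPositions)[1]
    j <- if (i < length(counts)) i + 1L else i - 1L  # forward; terminal backward
    lo <- min(i, j); hi <- max(i, j)
    starts <- starts[-hi]; ends <- ends[-lo]
    counts[lo] <- counts[lo] + counts[hi]
    counts <- counts[-hi]
  }
  binOf <- findInterval(positions - 1, starts)
  posList <- unname(split(positions, factor(binOf, levels = seq_along(starts))))
  isCen <- rep(FALSE, length(starts))
  if (!is.null(centromere) && length(starts))
    isCen <- starts < centromere[2] & ends > centromere[1]
  methods::new("BinSet",
               bins = data.frame(chrom = chrom, start = starts, end = ends,
                                 nPositions = lengths(posList),
                                 isCentromere = isCen),
               positions = posList, binSize = binSize)
}
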