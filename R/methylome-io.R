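# allc-style I/O and per-position methylation statistics.
#
# The allc format is a 7-column TSV: chromosome, 1-based position, strand,
# context class, methylated-read count, total-read count, binary methylation
# call. Coordinates are 1-based inclusive in files; interval types elsewhere
# in the package are 0-based half-open.

.ALLC_COLS <- c("chrom", "pos", "strand", "context", "mc", "total",
                "is_methylated")

#' Read an allc-style methylation table
#'
#' Reads a tab-separated per-cytosine methylation file (gzip-transparent).
#' A header row is detected and skipped if present. Rows with unparseable
#' counts are dropped with a warning; rows where `mc > total` raise an error.
#'
#' @param path path to the allc TSV (may be gzipped).
#' @param sampleId sample identifier (default: file base name).
#' @return A [MethylomeTable-class].
#' @export
readAllc <- function(path, sampleId = sub("\\.(tsv|txt)(\\.gz)?$", "",
                                          basename(path))) {
  emptyTable <- function() data.table::data.table()
  if (file.exists(path) && file.size(path) == 0L) {
    dt <- emptyTable()
  } else if (grepl("\\.gz$", path)) {
    lines <- readLines(gzfile(path))
    dt <- if (length(lines))
      data.table::fread(text = lines, header = FALSE, sep = "\t",
                        colClasses = "character", fill = TRUE)
    else emptyTable()
  } else {
    dt <- data.table::fread(path, header = FALSE, sep = "\t",
                            colClasses = "character", fill = TRUE)
  }
  if (nrow(dt) == 0L) {
    return(MethylomeTable(data.frame(chrom = character(), pos = integer(),
                                     strand = character(), context = character(),
                                     mc = integer(), total = integer(),
                                     is_methylated = logical()), sampleId))
  }
  if (ncol(dt) < 7L) stop("allc file must have 7 tab-separated columns")
  dt <- dt[, 1:7]
  data.table::setnames(dt, .ALLC_COLS)
  # header row: counts fail to parse as integers
  if (is.na(suppressWarnings(as.integer(dt$mc[1]))) ||
      is.na(suppressWarnings(as.integer(dt$total[1]))))
    dt <- dt[-1]
  pos <- suppressWarnings(as.integer(dt$pos))
  mc <- suppressWarnings(as.integer(dt$mc))
  total <- suppressWarnings(as.integer(dt$total))
  bad <- is.na(pos) | is.na(mc) | is.na(total) |
    !(dt$strand %in% c("+", "-")) | !(dt$context %in% .VALID_CONTEXTS)
  if (any(bad)) {
    warning(sum(bad), " malformed row(s) dropped from ", path)
    dt <- dt[!bad]; pos <- pos[!bad]; mc <- mc[!bad]; total <- total[!bad]
  }
  if (any(mc > total)) stop("validation error: mc > total in ", path)
  meth <- suppressWarnings(as.integer(dt$is_methylated))
  MethylomeTable(data.frame(chrom = dt$chrom, pos = pos, strand = dt$strand,
                            context = dt$context, mc = mc, total = total,
                            is_methylated = ifelse(is.na(meth), NA, meth == 1L)),
                 sampleId)
}

#' Write a MethylomeTable as an allc TSV
#'
#' @param x a [MethylomeTable-class].
#' @param path output path (".gz" suffix writes gzipped).
#' @return `path`, invisibly.
#' @export
writeAllc <- function(x, path) {
  stopifnot(is(x, "MethylomeTable"))
  d <- x@data
  d$is_methylated <- as.integer(d$is_methylated)
  data.table::fwrite(d, path, sep = "\t", col.names = FALSE, na = "0")
  invisible(path)
}

#' Weighted methylation level
#'
#' The read-count-weighted methylation level mC / (mC + uC), i.e. methylated
#' reads over total reads. Vectorized; monotone nondecreasing in `mc` at
#' fixed `total`.
#'
#' @param mc methylated-read count(s).
#' @param total total read count(s); must be positive.
#' @return Numeric level(s) in `[0, 1]`.
#' @export
weightedMethylation <- function(mc, total) {
  if (any(total == 0))
    stop("undefined methylation level: total read count is zero")
  if (any(mc > total) || any(mc < 0)) stop("require 0 <= mc <= total")
  mc / total
}

#' Call per-position methylation status
#'
#' One-sided binomial test of each position's methylated-read count against
#' the bisulfite non-conversion rate, P(X >= mc | n = total, p =
#' nonconversion), followed by Benjamini-Hochberg FDR correction across all
#' tested positions (all contexts pooled, one sample = one family). Positions
#' covered by fewer than `minCoverage` reads are excluded from testing and
#' marked unmethylated.
#'
#' @param x a [MethylomeTable-class].
#' @param nonconversion non-conversion rate in `[0, 1]` (typically estimated
#'   from chloroplast-aligned reads).
#' @param alpha FDR threshold for calling a position methylated.
#' @param minCoverage minimum total reads for a position to be tested.
#' @return The table with `is_methylated` filled in.
#' @export
callMethylationStatus <- function(x, nonconversion, alpha = 0.05,
                                  minCoverage = 3) {
  stopifnot(is(x, "MethylomeTable"))
  if (length(nonconversion) != 1 || nonconversion < 0 || nonconversion > 1)
    stop("nonconversion must be a single rate in [0, 1]")
  d <- x@data
  if (!nrow(d)) return(x)
  tested <- d$total >= minCoverage
  is_meth <- rep(FALSE, nrow(d))
  if (any(tested)) {
    p <- stats::pbinom(d$mc[tested] - 1L, d$total[tested], nonconversion,
                       lower.tail = FALSE)
    padj <- stats::p.adjust(p, method = "BH")
    is_meth[tested] <- padj <= alpha
  }
  d$is_methylated <- is_meth
  methods::initialize(x, data = d)
}

#' One-sided binomial tail probability
#'
#' P(X >= mc) for X ~ Binomial(total, p). Exposed for testing the
#' methylation-status call against direct probability-mass summation.
#'
#' @param mc observed successes.
#' @param total number of trials.
#' @param p success probability.
#' @return Upper-tail probability.
#' @keywords internal
binomTailP <- function(mc, total, p) {
  stats::pbinom(mc - 1L, total, p, lower.tail = FALSE)
}

#' Combine samples into a pan-methylome
#'
#' Sums methylated and total read counts at each position across the supplied
#' samples of a line. Positions are matched on (chromosome, position); a
#' position reported with conflicting strand or context across samples is a
#' validation error. Methylation calls are reset to `NA` (call them on the
#' combined counts if needed).
#'
#' @param tables list of [MethylomeTable-class] objects sharing a reference
#'   coordinate system.
#' @param sampleId identifier for the combined table.
#' @return A [MethylomeTable-class] of per-position summed counts.
#' @export
combinePanMethylome <- function(tables, sampleId = "pan") {
  stopifnot(length(tables) >= 1, all(vapply(tables, is, TRUE, "MethylomeTable")))
  dt <- data.table::rbindlist(lapply(tables, function(t) t@data))
  key <- dt[, list(n = data.table::uniqueN(paste(strand, context))),
            by = c("chrom", "pos")]
  if (any(key$n > 1))
    stop("validation error: conflicting strand/context at shared position(s)")
  agg <- dt[, list(strand = strand[1], context = context[1],
                   mc = sum(mc), total = sum(total)),
            by = c("chrom", "pos")]
  MethylomeTable(data.frame(chrom = agg$chrom, pos = agg$pos,
                            strand = agg$strand, context = agg$context,
                            mc = agg$mc, total = agg$total,
                            is_methylated = NA), sampleId)
}

#' Unmethylated twin of a methylome
#'
#' Sets methylated read counts to zero while maintaining the total number of
#' reads at each position; used as the fully-unmethylated comparison partner
#' of a pan-methylome when screening for methylated regions.
#'
#' @param x a [MethylomeTable-class].
#' @return The twin table with `mc = 0` everywhere.
#' @export
unmethylatedTwin <- function(x) {
  stopifnot(is(x, "MethylomeTable"))
  d <- x@data
  d$mc <- 0L
  d$is_methylated <- FALSE
  methods::initialize(x, data = d,
                      sampleId = paste0(x@sampleId, "_unmethylated"))
}
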