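# Post-map population checks: crossover counts against a fitted Poisson via
# an exact multinomial goodness-of-fit test, and per-bin allele frequencies
# against the Mendelian 1:1 expectation via chi-square.

#' @describeIn countCrossovers count adjacent-bin state changes per sample
#'   and chromosome of an epigenotype map (offspring samples by default).
#' @param x an [EpigenotypeMap-class] or a per-bin state matrix.
#' @param samples samples to count.
#' @param ... unused.
#' @export
setMethod("countCrossovers", "EpigenotypeMap",
  function(x, samples = x@samples[x@roles == "offspring"], ...) {
    out <- expand.grid(sample = samples, chrom = unique(x@bins$chrom),
                       stringsAsFactors = FALSE)
    out$n <- mapply(function(s, chrom) {
      st <- x@finalStates[x@bins$chrom == chrom, match(s, x@samples)]
      sum(st[-1] != st[-length(st)])
    }, out$sample, out$chrom)
    out
  })

#' @describeIn countCrossovers count state changes in a plain state vector.
#' @export
setMethod("countCrossovers", "character",
  function(x, ...) sum(x[-1] != x[-length(x)]))

#' Exact multinomial goodness-of-fit test
#'
#' Two-sided exact test of observed category counts against expected
#' probabilities. The p-value is the total probability of outcomes no more
#' probable than the observed one. All compositions of `n` into the
#' categories are enumerated when their number is at most `maxEnum`;
#' otherwise the p-value is approximated by Monte Carlo with a fixed seed
#' and the achievable resolution reported via the `nSim` attribute.
#'
#' @param observed integer vector of category counts.
#' @param prob expected category probabilities (normalized internally).
#' @param maxEnum largest outcome-space size enumerated exactly.
#' @param nSim Monte Carlo draws used beyond that.
#' @param seed Monte Carlo seed.
#' @return p-value in (0, 1], with attributes `method` and (for Monte
#'   Carlo) `nSim`.
#' @export
exactMultinomialTest <- function(observed, prob, maxEnum = 1e6,
                                 nSim = 1e5, seed = 1) {
  stopifnot(length(observed) == length(prob), all(observed >= 0),
            all(prob >= 0), any(prob > 0))
  prob <- prob / sum(prob)
  n <- sum(observed)
  k <- length(observed)
  if (n == 0) return(structure(1, method = "degenerate"))
  logp <- log(prob)
  logp[prob == 0] <- -Inf
  lprob <- function(X) {  # rows of X are compositions
    lgamma(n + 1) - rowSums(lgamma(X + 1)) +
      rowSums(sweep(X, 2, logp, `*`), na.rm = TRUE)
  }
  lobs <- lprob(matrix(observed, 1))
  nOutcomes <- choose(n + k - 1, k - 1)
  if (nOutcomes <= maxEnum) {
    comps <- .compositions(n, k)
    lp <- lprob(comps)
    p <- sum(exp(lp[lp <= lobs + 1e-7]))
    return(structure(min(p, 1), method = "enumeration"))
  }
  set.seed(seed)
  draws <- t(stats::rmultinom(nSim, n, prob))
  p <- (1 + sum(lprob(draws) <= lobs + 1e-7)) / (1 + nSim)
  structure(p, method = "monte-carlo", nSim = nSim)
}

# all compositions of n into k nonnegative parts (stars and bars)
.compositions <- function(n, k) {
  if (k == 1) return(matrix(n, 1, 1))
  bars <- utils::combn(n + k - 1, k - 1)
  first <- bars[1, ] - 1
  last <- n + k - 1 - bars[k - 1, ]
  if (k == 2) return(cbind(first, last, deparse.level = 0))
  mid <- bars[-1, , drop = FALSE] - bars[-(k - 1), , drop = FALSE] - 1
  unname(cbind(first, t(mid), last))
}

#' Crossover-count test against a fitted Poisson
#'
#' For each chromosome, fits a Poisson distribution to the per-sample
#' crossover counts by their mean, computes expected probabilities for 0-6
#' crossovers with the residual mass lumped into a terminal ">6" category,
#' and runs the exact multinomial goodness-of-fit test of the observed
#' count distribution against those probabilities. P-values are BH-adjusted
#' across chromosomes.
#'
#' @param counts `data.frame` with columns `sample`, `chrom`, `n` (see
#'   [countCrossovers()]).
#' @param maxCount largest crossover count given its own category.
#' @param ... passed to [exactMultinomialTest()].
#' @return list with `summary` (per-chromosome mean, standard error,
#'   p-value, BH-adjusted p-value) and `expected` (per-chromosome expected
#'   category probabilities and observed category counts).
#' @export
crossoverTest <- function(counts, maxCount = 6, ...) {
  stopifnot(all(c("sample", "chrom", "n") %in% names(counts)))
  chroms <- unique(counts$chrom)
  if (length(unique(counts$sample)) < 2)
    stop("crossover test requires at least 2 samples")
  expected <- list()
  summ <- do.call(rbind, lapply(chroms, function(chrom) {
    x <- counts$n[counts$chrom == chrom]
    lambda <- mean(x)
    probs <- c(stats::dpois(0:maxCount, lambda),
               stats::ppois(maxCount, lambda, lower.tail = FALSE))
    obs <- tabulate(factor(pmin(x, maxCount + 1), levels = 0:(maxCount + 1)),
                    nbins = maxCount + 2)
    p <- exactMultinomialTest(obs, probs, ...)
    expected[[chrom]] <<- data.frame(
      category = c(as.character(0:maxCount), paste0(">", maxCount)),
      prob = probs, observed = obs)
    data.frame(chrom = chrom, nSamples = length(x), mean = lambda,
               se = stats::sd(x) / sqrt(length(x)), p = as.numeric(p))
  }))
  summ$padj <- stats::p.adjust(summ$p, method = "BH")
  list(summary = summ, expected = expected)
}

#' Per-bin allele-frequency test against the Mendelian 1:1 expectation
#'
#' Each F2 contributes two alleles per bin (heterozygous bins contribute one
#' maternal and one paternal). Per bin, a chi-square goodness-of-fit test
#' compares the maternal:paternal allele counts to 1:1; p-values are
#' BH-adjusted across bins.
#'
#' @param x an [EpigenotypeMap-class] (offspring samples used) or a
#'   character state matrix `[bins, samples]`.
#' @param bins optional bin `data.frame` to carry through to the result.
#' @return `data.frame` with per-bin allele counts, chi-square statistic,
#'   `p`, and `padj`.
#' @export
alleleFrequencyTest <- function(x, bins = NULL) {
  if (is(x, "EpigenotypeMap")) {
    bins <- x@bins
    x <- x@finalStates[, x@roles == "offspring", drop = FALSE]
  }
  stopifnot(is.matrix(x))
  if (ncol(x) == 0) stop("no samples to test")
  nM <- 2 * rowSums(x == "MOTHER") + rowSums(x == "MPV")
  nF <- 2 * rowSums(x == "FATHER") + rowSums(x == "MPV")
  tot <- nM + nF
  chisq <- (nM - tot / 2)^2 / (tot / 2) + (nF - tot / 2)^2 / (tot / 2)
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  out <- data.frame(nMother = nM, nFather = nF, chisq = chisq, p = p,
                    padj = stats::p.adjust(p, method = "BH"))
  if (!is.null(bins)) out <- cbind(bins[, c("chrom", "start", "end")], out)
  rownames(out) <- NULL
  out
}
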