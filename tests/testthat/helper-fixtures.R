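# Shared fixtures and independent oracles for the test suite.

states3 <- c("MOTHER", "MPV", "FATHER")

# quick MethylomeTable from vectors
mkMeth <- function(pos, mc, total, chrom = "Chr1", strand = "+",
                   context = "CG", meth = NA, id = "s") {
  MethylomeTable(data.frame(chrom = chrom, pos = pos, strand = strand,
                            context = context, mc = mc, total = total,
                            is_methylated = meth), id)
}

# --- independent oracles -----------------------------------------------

# binomial upper tail by direct pmf summation
oracleBinomTail <- function(mc, total, p) {
  if (mc > total) return(0)
  sum(vapply(mc:total, function(k) stats::dbinom(k, total, p), 0))
}

# forward-backward posteriors by exhaustive enumeration over all 3^N paths
oracleEnumPosteriors <- function(emissions, trans, init = rep(1 / 3, 3),
                                 mask = NULL) {
  e <- as.matrix(emissions)
  if (!is.null(mask)) e[mask, ] <- 1
  n <- nrow(e)
  paths <- as.matrix(expand.grid(rep(list(1:3), n)))
  pr <- apply(paths, 1, function(pp) {
    v <- init[pp[1]] * e[1, pp[1]]
    if (n > 1) for (t in 2:n) v <- v * trans[pp[t - 1], pp[t]] * e[t, pp[t]]
    v
  })
  post <- matrix(sapply(1:3, function(k)
    vapply(1:n, function(t) sum(pr[paths[, t] == k]), 0)), n, 3)
  post / rowSums(post)
}

# maximum path probability by exhaustive enumeration
oracleMaxPathLog <- function(emissions, trans, init = rep(1 / 3, 3),
                             mask = NULL) {
  e <- as.matrix(emissions)
  if (!is.null(mask)) e[mask, ] <- 1
  n <- nrow(e)
  paths <- as.matrix(expand.grid(rep(list(1:3), n)))
  lp <- apply(paths, 1, function(pp) {
    v <- log(init[pp[1]]) + log(e[1, pp[1]])
    if (n > 1) for (t in 2:n)
      v <- v + log(trans[pp[t - 1], pp[t]]) + log(e[t, pp[t]])
    v
  })
  max(lp)
}

# exact multinomial p-value by enumeration over all k^n sample-to-category
# assignments (independent of the composition-based implementation)
oracleMultinomP <- function(observed, prob) {
  n <- sum(observed)
  k <- length(observed)
  asg <- as.matrix(expand.grid(rep(list(1:k), n)))
  outcomeP <- function(cnt) stats::dmultinom(cnt, prob = prob)
  pObs <- outcomeP(observed)
  tot <- 0
  for (i in seq_len(nrow(asg))) {
    cnt <- tabulate(asg[i, ], nbins = k)
    pAsg <- prod(prob[asg[i, ]])
    if (outcomeP(cnt) <= pObs * (1 + 1e-9)) tot <- tot + pAsg
  }
  tot
}

# random row-stochastic 3x3 matrix
randTrans <- function() {
  m <- matrix(stats::runif(9, 0.05, 1), 3, 3)
  m / rowSums(m)
}

# random emission matrix [n x 3]
randEmiss <- function(n) {
  m <- matrix(stats::runif(3 * n, 0.01, 1), n, 3)
  m / rowSums(m)
}

# bins wholly inside one truth block (unambiguous single label)
unambiguousBins <- function(truth, bins) {
  chg <- truth$start[-1][truth$genotype[-1] != truth$genotype[-nrow(truth)]]
  vapply(seq_len(nrow(bins)), function(b)
    !any(chg > bins$start[b] & chg < bins$end[b]), TRUE)
}

# simulate an F2 cohort of per-bin state maps with Mendelian 1:2:1 blocks
# and Poisson(lambda) crossovers (used by the population checks)
simulateMendelianCohort <- function(nSamples = 20, nBins = 100, lambda = 2) {
  sapply(seq_len(nSamples), function(s) {
    nco <- stats::rpois(1, lambda)
    cuts <- sort(stats::runif(nco)) * nBins
    blockOf <- findInterval(seq_len(nBins) - 0.5, cuts) + 1
    geno <- sample(states3, nco + 1, replace = TRUE,
                   prob = c(0.25, 0.5, 0.25))
    geno[blockOf]
  })
}
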