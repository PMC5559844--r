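# Categorization of parent-parent DMR inheritance in F2 offspring:
# Games-Howell-style pairwise statistics between F2 epigenotype groups,
# a label-permutation bootstrap null for significance, and rule-based
# assignment to expected / parental-dominant / no-association / ambiguous.

.PAIRS <- list(MF = c("MOTHER", "FATHER"), HF = c("MPV", "FATHER"),
               HM = c("MPV", "MOTHER"))

#' Games-Howell pairwise statistic
#'
#' The Welch-type statistic |mean(a) - mean(b)| / sqrt(var(a)/n_a +
#' var(b)/n_b) used for pairwise comparison of unequal-variance groups. The
#' studentized-range scaling constant of the classic Games-Howell procedure
#' is omitted because significance is judged against a bootstrap null of the
#' same statistic, under which any constant factor cancels.
#'
#' @param a,b numeric methylation levels of two F2 epigenotype groups.
#' @return The t-value, or `NA` when either group has fewer than 2 members
#'   or the pooled standard error is zero.
#' @export
gamesHowellT <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) return(NA_real_)
  se2 <- stats::var(a) / length(a) + stats::var(b) / length(b)
  d <- abs(mean(a) - mean(b))
  if (se2 == 0) {
    if (d == 0) return(0)
    return(NA_real_)
  }
  d / sqrt(se2)
}

.pairT <- function(levels, labels) {
  vapply(.PAIRS, function(pr)
    gamesHowellT(levels[labels == pr[1]], levels[labels == pr[2]]),
    numeric(1))
}

#' Bootstrap null thresholds for epigenotype-group comparisons
#'
#' Builds a null distribution of pairwise t-values by randomly re-assigning
#' the observed epigenotype label multiset to the F2 methylation levels
#' (`nBoot` permutations by default, preserving the observed label
#' distribution; set `replace = TRUE` to resample labels with replacement
#' instead). A comparison is significant when its observed t-value is
#' greater than or equal to the 99th percentile of its null t-values.
#'
#' @param levels per-F2 methylation levels at the region.
#' @param labels per-F2 epigenotype labels (`MOTHER`/`MPV`/`FATHER`).
#' @param nBoot number of bootstrap draws.
#' @param seed RNG seed; fixed seed gives bit-reproducible thresholds.
#' @param quantile percentile of the null defining the threshold.
#' @param replace sample labels with replacement instead of permuting.
#' @return Named vector of thresholds for the pairs `MF`, `HF`, `HM` (NA
#'   when no draw yields a t-value for the pair).
#' @export
bootstrapNull <- function(levels, labels, nBoot = 2000, seed = 1,
                          quantile = 0.99, replace = FALSE) {
  stopifnot(length(levels) == length(labels))
  set.seed(seed)
  tmat <- matrix(NA_real_, nBoot, length(.PAIRS),
                 dimnames = list(NULL, names(.PAIRS)))
  n <- length(labels)
  for (i in seq_len(nBoot)) {
    lab <- sample(labels, n, replace = replace)
    tmat[i, ] <- .pairT(levels, lab)
  }
  apply(tmat, 2, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(NA_real_)
    stats::quantile(col, quantile, names = FALSE)
  })
}

#' Categorize one region's inheritance pattern
#'
#' Applies the categorization rules in order: (1) all three pairwise
#' comparisons significant -> `expected` (each epigenotype group has its own
#' mean level, i.e. additive inheritance); (2) the mean level of all F2s
#' within `tol` of one parent's level and every F2 closer to that parent ->
#' `parental_dominant`; (3) neither heterozygous comparison significant ->
#' `no_association`; (4) exactly one heterozygous comparison significant ->
#' `ambiguous`. Regions whose significance flags are incomplete in a way the
#' rules cannot resolve (both heterozygous comparisons significant without
#' the maternal-paternal one) are also `ambiguous`.
#'
#' @param tvals named t-values for pairs `MF`, `HF`, `HM`.
#' @param thresholds matching bootstrap thresholds (see [bootstrapNull()]).
#' @param f2Levels per-F2 levels at the region.
#' @param parentLevels `c(mother, father)` levels at the region.
#' @param tol absolute level tolerance for parental dominance.
#' @return One of `"expected"`, `"parental_dominant"`, `"no_association"`,
#'   `"ambiguous"`, or `"unassessable"` when any t-value is missing.
#' @export
categorizeRegion <- function(tvals, thresholds, f2Levels, parentLevels,
                             tol = 0.10) {
  if (anyNA(tvals) || anyNA(thresholds)) return("unassessable")
  sig <- tvals >= thresholds
  if (all(sig)) return("expected")
  mLevel <- parentLevels[1]; fLevel <- parentLevels[2]
  meanF2 <- mean(f2Levels)
  closerM <- abs(f2Levels - mLevel) <= abs(f2Levels - fLevel)
  if ((abs(meanF2 - mLevel) <= tol && all(closerM)) ||
      (abs(meanF2 - fLevel) <= tol && all(!closerM)))
    return("parental_dominant")
  if (!sig[["HF"]] && !sig[["HM"]]) return("no_association")
  "ambiguous"
}

#' Categorize inheritance patterns across regions
#'
#' Runs the full categorization for each region: pairwise Games-Howell
#' t-values between the F2 epigenotype groups, bootstrap null thresholds at
#' the 99th percentile, and the rule-based category. Regions where any
#' pairwise t-value cannot be obtained (a group smaller than 2 or zero
#' variance everywhere) are reported `unassessable` and carry `NA`
#' statistics.
#'
#' @param f2Levels matrix (regions x F2 samples) of methylation levels.
#' @param epigenotypes character matrix (regions x F2 samples) of
#'   epigenotype states at each region (from the epigenotype map).
#' @param parentLevels matrix (regions x 2: mother, father levels).
#' @param nBoot,seed,tol see [bootstrapNull()] and [categorizeRegion()].
#' @return `data.frame` with per-region t-values, thresholds, significance
#'   flags, and `category`.
#' @export
categorizeInheritance <- function(f2Levels, epigenotypes, parentLevels,
                                  nBoot = 2000, seed = 1, tol = 0.10) {
  f2Levels <- as.matrix(f2Levels)
  epigenotypes <- as.matrix(epigenotypes)
  parentLevels <- as.matrix(parentLevels)
  nr <- nrow(f2Levels)
  stopifnot(nrow(epigenotypes) == nr, nrow(parentLevels) == nr)
  out <- do.call(rbind, lapply(seq_len(nr), function(r) {
    lv <- f2Levels[r, ]; lab <- epigenotypes[r, ]
    ok <- !is.na(lv)
    lv <- lv[ok]; lab <- lab[ok]
    tv <- .pairT(lv, lab)
    if (anyNA(tv)) {
      th <- rep(NA_real_, 3); names(th) <- names(.PAIRS)
      cat_ <- "unassessable"
    } else {
      th <- bootstrapNull(lv, lab, nBoot = nBoot,
                          seed = .simSeed(seed, r))
      cat_ <- categorizeRegion(tv, th, lv, parentLevels[r, ], tol = tol)
    }
    data.frame(region = r, t_MF = tv[["MF"]], t_HF = tv[["HF"]],
               t_HM = tv[["HM"]], thr_MF = th[["MF"]], thr_HF = th[["HF"]],
               thr_HM = th[["HM"]], category = cat_)
  }))
  rownames(out) <- NULL
  out
}
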