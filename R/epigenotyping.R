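# The core epigenotyping procedure: informative positions -> per-chromosome
# bins -> per-bin one-vs-rest logistic classifier -> forward-backward
# smoothing -> Viterbi decoding. Each chromosome is analyzed independently.

#' Find parentally differentially methylated (informative) positions
#'
#' A position is informative when it is covered by at least `minCoverage`
#' reads in both parents and exactly one parent is methylated according to
#' the binomial methylation-status call.
#'
#' @param mother,father [MethylomeTable-class] objects with `is_methylated`
#'   set (see [callMethylationStatus()]).
#' @param minCoverage minimum read coverage in each parent.
#' @return `data.frame` with columns `chrom`, `pos`.
#' @export
findInformativePositions <- function(mother, father, minCoverage = 3) {
  stopifnot(is(mother, "MethylomeTable"), is(father, "MethylomeTable"))
  m <- mother@data; f <- father@data
  if (anyNA(m$is_methylated) || anyNA(f$is_methylated))
    stop("both parents need methylation calls (callMethylationStatus)")
  km <- paste(m$chrom, m$pos); kf <- paste(f$chrom, f$pos)
  i <- match(km, kf)
  ok <- !is.na(i) & m$total >= minCoverage & f$total[i] >= minCoverage &
    xor(m$is_methylated, f$is_methylated[i])
  data.frame(chrom = m$chrom[ok], pos = m$pos[ok])
}

#' Mid-parent methylation vector
#'
#' The element-wise average methylation level of the two parents at each
#' position; used as the training vector for the heterozygous (MPV) class.
#'
#' @param motherLevels,fatherLevels equal-length level vectors over the same
#'   positions.
#' @return Numeric vector of mid-parent levels.
#' @export
midparentVector <- function(motherLevels, fatherLevels) {
  if (length(motherLevels) != length(fatherLevels))
    stop("parent level vectors must have equal length")
  (motherLevels + fatherLevels) / 2
}

#' Class weights for F8 epiRIL epigenotyping
#'
#' Expected residual heterozygosity after seven rounds of selfing is
#' (1/2)^7 = 0.0078125, so the heterozygous class is weighted 0.0078125 and
#' each homozygous class (1 - 0.0078125)/2 = 0.49609375, a 127:2:127 ratio,
#' in place of the F2 1:2:1 weighting.
#'
#' @param generations number of selfed generations (default 8, i.e. F8).
#' @return Length-3 weight vector in state order (MOTHER, MPV, FATHER).
#' @export
epirilWeights <- function(generations = 8) {
  het <- 0.5^(generations - 1)
  c(MOTHER = (1 - het) / 2, MPV = het, FATHER = (1 - het) / 2)
}

#' Emission adjustment for epiRIL decoding
#'
#' In crosses to a methylation-mutant parent the classifier splits the
#' mutant parent's probability mass between the father and MPV states while
#' the MPV state itself is never a plausible call for F8 individuals. Before
#' forward-backward smoothing, the MPV emission mass at each bin is added to
#' the father (mutant) state and the MPV emission set to zero.
#'
#' @param probs matrix `[bins, 3]` of classifier probabilities in state
#'   order.
#' @return Adjusted emission matrix.
#' @export
epirilAdjust <- function(probs) {
  probs <- as.matrix(probs)
  stopifnot(ncol(probs) == 3)
  probs[, 3] <- probs[, 3] + probs[, 2]
  probs[, 2] <- 0
  colnames(probs) <- .STATES
  probs
}

# Build the level matrix [informative positions x samples], keeping only
# positions covered >= minCoverage in every sample.
.levelMatrix <- function(informative, tables, minCoverage) {
  keyInf <- paste(informative$chrom, informative$pos)
  keep <- rep(TRUE, nrow(informative))
  L <- matrix(NA_real_, nrow(informative), length(tables),
              dimnames = list(NULL, names(tables)))
  for (s in seq_along(tables)) {
    d <- tables[[s]]@data
    i <- match(keyInf, paste(d$chrom, d$pos))
    ok <- !is.na(i) & d$total[i] >= minCoverage
    keep <- keep & ok
    L[ok, s] <- d$mc[i[ok]] / d$total[i[ok]]
  }
  list(levels = L[keep, , drop = FALSE], informative = informative[keep, ])
}

#' Run the full epigenotyping procedure
#'
#' Identifies informative positions between the parents, restricts to
#' positions sufficiently covered in every sample, bins each chromosome,
#' classifies every bin of every sample with a per-bin one-vs-rest logistic
#' regression trained on the mother, father, and mid-parent vectors (plus
#' replicate-derived vectors when supplied), then smooths each sample's
#' state sequence with a forward-backward pass and decodes the final map by
#' Viterbi. Transition matrices are estimated per chromosome from the
#' decoded states of all classified samples except the mother and father
#' (pseudo-count 1). Centromeric bins, when provided, are masked so only
#' transition probabilities inform their state.
#'
#' @param mother,father parental [MethylomeTable-class] objects with
#'   methylation calls.
#' @param offspring named list of offspring [MethylomeTable-class] objects.
#' @param motherReps,fatherReps optional lists of parental replicate tables
#'   (e.g. selfed-progeny generations G'1/G'2); replicate pairs also
#'   contribute mid-parent training vectors.
#' @param binSize bin width in bp (default 50 kb).
#' @param chromLengths named numeric vector of chromosome lengths.
#' @param centromeres optional `data.frame` with `chrom`, `start`, `end`
#'   (0-based half-open) giving intervals to mask.
#' @param mode `"f2"` (1:2:1 class weights) or `"epiril"` (F8 weights plus
#'   the MPV-to-father emission adjustment, see [epirilAdjust()]).
#' @param classWeights override the mode's class weights.
#' @param transitionSamples which classified samples feed the transition
#'   estimates: everything but the parents (default) or offspring only.
#' @param classifierC inverse regularization strength of the per-bin
#'   classifier (see [trainClassifyBin()]).
#' @param classifierScheme `"multinomial"` (default) or `"ovr"`; see
#'   [trainClassifyBin()].
#' @param minCoverage minimum reads per position per sample.
#' @return An [EpigenotypeMap-class] covering all classified samples.
#' @export
epigenotypePipeline <- function(mother, father, offspring,
                                motherReps = list(), fatherReps = list(),
                                binSize = 50000, chromLengths,
                                centromeres = NULL,
                                mode = c("f2", "epiril"),
                                classWeights = NULL,
                                transitionSamples = c("all_but_parents",
                                                      "offspring_only"),
                                classifierC = 100,
                                classifierScheme = c("multinomial", "ovr"),
                                minCoverage = 3) {
  classifierScheme <- match.arg(classifierScheme)
  mode <- match.arg(mode)
  transitionSamples <- match.arg(transitionSamples)
  if (is.null(classWeights))
    classWeights <- if (mode == "epiril") unname(epirilWeights())
                    else c(0.25, 0.5, 0.25)
  if (is.null(names(offspring)) || any(names(offspring) == ""))
    names(offspring) <- vapply(offspring, sampleId, "")
  stopifnot(!is.null(names(chromLengths)))

  informative <- findInformativePositions(mother, father, minCoverage)
  if (!nrow(informative)) stop("no informative positions between parents")

  nRep <- min(length(motherReps), length(fatherReps))
  seqNames <- function(prefix, x)
    if (length(x)) paste0(prefix, seq_along(x)) else character(0)
  tables <- c(list(mother = mother, father = father),
              stats::setNames(motherReps, seqNames("mother_rep", motherReps)),
              stats::setNames(fatherReps, seqNames("father_rep", fatherReps)),
              offspring)
  lm <- .levelMatrix(informative, tables, minCoverage)
  L <- lm$levels
  informative <- lm$informative
  if (!nrow(L)) stop("no informative position is covered in all samples")

  # classified pseudo-samples: MPV from the parents and from replicate pairs
  mpvCols <- cbind(mpv = midparentVector(L[, "mother"], L[, "father"]))
  if (nRep > 0) {
    for (r in seq_len(nRep))
      mpvCols <- cbind(mpvCols, midparentVector(L[, paste0("mother_rep", r)],
                                                L[, paste0("father_rep", r)]))
    colnames(mpvCols) <- c("mpv", paste0("mpv_rep", seq_len(nRep)))
  }
  L <- cbind(L, mpvCols)
  roles <- c("mother", "father",
             rep("mother_rep", length(motherReps)),
             rep("father_rep", length(fatherReps)),
             rep("offspring", length(offspring)),
             "mpv", rep("mpv_rep", nRep))
  names(roles) <- colnames(L)
  trainCols <- names(roles)[roles %in% c("mother", "father", "mother_rep",
                                         "father_rep", "mpv", "mpv_rep")]
  trainLabels <- c(mother = "MOTHER", father = "FATHER",
                   mother_rep = "MOTHER", father_rep = "FATHER",
                   mpv = "MPV", mpv_rep = "MPV")[roles[trainCols]]
  nS <- ncol(L)
  inTrans <- !(roles %in% c("mother", "father"))
  if (transitionSamples == "offspring_only") inTrans <- roles == "offspring"

  chroms <- intersect(names(chromLengths), unique(informative$chrom))
  missing <- setdiff(unique(informative$chrom), names(chromLengths))
  if (length(missing))
    stop("chromLengths missing for: ", paste(missing, collapse = ", "))

  binsAll <- list(); lrP <- list(); fbP <- list()
  lrS <- list(); fbS <- list(); finS <- list(); uninf <- list()
  transAll <- list()
  for (chrom in chroms) {
    onChrom <- informative$chrom == chrom
    pos <- informative$pos[onChrom]
    Lc <- L[onChrom, , drop = FALSE]
    if (length(pos) < 3)
      warning("chromosome ", chrom, " has fewer than 3 informative positions; ",
              "its map is uninformative")
    bs <- makeBins(chromLengths[[chrom]], binSize, pos, chrom = chrom)
    nb <- length(bs)
    mask <- rep(FALSE, nb)
    if (!is.null(centromeres)) {
      ci <- centromeres[centromeres$chrom == chrom, , drop = FALSE]
      for (r in seq_len(nrow(ci)))
        mask <- mask | (bs@bins$start < ci$end[r] & bs@bins$end > ci$start[r])
      bs@bins$isCentromere <- mask
    }
    probs <- array(NA_real_, c(nb, 3, nS),
                   dimnames = list(NULL, .STATES, colnames(L)))
    uninfB <- logical(nb)
    posIndex <- match(unlist(bs@positions), pos)
    offsets <- c(0, cumsum(lengths(bs@positions)))
    for (b in seq_len(nb)) {
      idx <- if (offsets[b] == offsets[b + 1]) integer()
             else posIndex[(offsets[b] + 1):offsets[b + 1]]
      Xtr <- t(Lc[idx, trainCols, drop = FALSE])
      Xsm <- t(Lc[idx, , drop = FALSE])
      cls <- trainClassifyBin(Xtr, unname(trainLabels), Xsm,
                              classWeights = classWeights, C = classifierC,
                              scheme = classifierScheme)
      probs[b, , ] <- t(cls$probs)
      uninfB[b] <- cls$uninformative
    }
    lrStates <- apply(probs, 3, function(p)
      .STATES[max.col(p, ties.method = "first")])
    lrStates <- matrix(lrStates, nb, nS, dimnames = list(NULL, colnames(L)))

    emiss <- probs
    if (mode == "epiril")
      for (s in seq_len(nS)) emiss[, , s] <- epirilAdjust(emiss[, , s])

    T1 <- estimateTransitions(
      lapply(which(inTrans), function(s) lrStates[, s]))
    fbPost <- array(NA_real_, dim(probs), dimnames = dimnames(probs))
    fbStates <- matrix(NA_character_, nb, nS,
                       dimnames = list(NULL, colnames(L)))
    for (s in seq_len(nS)) {
      fb <- forwardBackward(emiss[, , s, drop = FALSE][, , 1], T1, mask)
      fbPost[, , s] <- fb$posterior
      fbStates[, s] <- fb$states
    }
    T2 <- estimateTransitions(
      lapply(which(inTrans), function(s) fbStates[, s]))
    finStates <- matrix(NA_character_, nb, nS,
                        dimnames = list(NULL, colnames(L)))
    for (s in seq_len(nS))
      finStates[, s] <- viterbiPath(fbPost[, , s, drop = FALSE][, , 1],
                                    T2, mask)$states

    binsAll[[chrom]] <- bs@bins
    lrP[[chrom]] <- probs; fbP[[chrom]] <- fbPost
    lrS[[chrom]] <- lrStates; fbS[[chrom]] <- fbStates
    finS[[chrom]] <- finStates; uninf[[chrom]] <- uninfB
    transAll[[chrom]] <- list(lr = T1, fb = T2)
  }
  bins <- do.call(rbind, binsAll)
  rownames(bins) <- NULL
  bindArr <- function(lst) {
    out <- array(NA_real_, c(nrow(bins), 3, nS),
                 dimnames = list(NULL, .STATES, colnames(L)))
    at <- 0
    for (a in lst) { out[at + seq_len(dim(a)[1]), , ] <- a; at <- at + dim(a)[1] }
    out
  }
  methods::new("EpigenotypeMap", bins = bins, samples = colnames(L),
               roles = unname(roles), lrProbs = bindArr(lrP),
               fbPosteriors = bindArr(fbP),
               lrStates = do.call(rbind, lrS), fbStates = do.call(rbind, fbS),
               finalStates = do.call(rbind, finS),
               uninformative = unlist(uninf, use.names = FALSE),
               transitions = transAll)
}

#' Recombination breakpoints of an epigenotype map
#'
#' A breakpoint is the shared boundary between adjacent bins of one
#' chromosome whose final states differ; its coordinate is the end of the
#' left bin.
#'
#' @param x an [EpigenotypeMap-class].
#' @param samples samples to report (default: offspring).
#' @param ... unused.
#' @return `data.frame` with `sample`, `chrom`, `pos`, `from`, `to`.
#' @export
setMethod("breakpoints", "EpigenotypeMap",
  function(x, samples = x@samples[x@roles == "offspring"], ...) {
    out <- list()
    for (s in samples) {
      i <- match(s, x@samples)
      for (chrom in unique(x@bins$chrom)) {
        rows <- which(x@bins$chrom == chrom)
        st <- x@finalStates[rows, i]
        chg <- which(st[-1] != st[-length(st)])
        if (length(chg))
          out[[length(out) + 1]] <- data.frame(
            sample = s, chrom = chrom, pos = x@bins$end[rows[chg]],
            from = st[chg], to = st[chg + 1])
      }
    }
    if (!length(out))
      return(data.frame(sample = character(), chrom = character(),
                        pos = numeric(), from = character(),
                        to = character()))
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
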