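# Three-state HMM machinery: transition estimation from decoded state
# sequences, scaled forward-backward smoothing, and Viterbi decoding.
# Centromeric bins can be masked, in which case their emission terms are
# replaced by 1.0 for every state so that only transitions inform the result.

#' Estimate a 3x3 transition matrix from state sequences
#'
#' Counts adjacent-bin transitions l -> k over all supplied sequences, adds a
#' pseudo-count of 1 to every cell, and row-normalizes. When estimating
#' transitions for the epigenotyping HMM, sequences should come from all
#' classified samples except the mother and father.
#'
#' @param stateSeqs list of character vectors over
#'   `c("MOTHER", "MPV", "FATHER")` (one vector per sample-chromosome).
#' @param pseudo pseudo-count added to each of the 9 cells.
#' @return Row-stochastic 3x3 matrix with state dimnames.
#' @export
estimateTransitions <- function(stateSeqs, pseudo = 1) {
  if (is.character(stateSeqs)) stateSeqs <- list(stateSeqs)
  counts <- matrix(0, 3, 3, dimnames = list(.STATES, .STATES))
  for (s in stateSeqs) {
    if (length(s) < 2) next
    stopifnot(all(s %in% .STATES))
    from <- factor(s[-length(s)], levels = .STATES)
    to <- factor(s[-1], levels = .STATES)
    counts <- counts + table(from, to)
  }
  counts <- counts + pseudo
  counts / rowSums(counts)
}

.maskedEmissions <- function(emissions, mask) {
  emissions <- as.matrix(emissions)
  stopifnot(ncol(emissions) == 3)
  if (!is.null(mask)) {
    stopifnot(length(mask) == nrow(emissions))
    emissions[mask, ] <- 1
  }
  emissions
}

#' Forward-backward posterior smoothing
#'
#' Standard scaled forward-backward over a three-state chain. Masked bins
#' (e.g. centromeric) contribute emission probability 1.0 for every state so
#' that only the transition structure informs their posterior. Per-bin
#' scaling keeps the recursion underflow-free for arbitrarily long
#' chromosomes.
#'
#' @param emissions matrix `[bins, 3]` of per-bin state emission weights
#'   (e.g. classifier probabilities).
#' @param trans row-stochastic 3x3 transition matrix.
#' @param mask optional logical per bin; `TRUE` masks the bin's emissions.
#' @param init initial state distribution (default uniform).
#' @return list with `posterior` (matrix `[bins, 3]`, rows summing to 1) and
#'   `states` (per-bin argmax, ties broken in state order).
#' @export
forwardBackward <- function(emissions, trans, mask = NULL,
                            init = rep(1 / 3, 3)) {
  e <- .maskedEmissions(emissions, mask)
  n <- nrow(e)
  stopifnot(n >= 1, all(abs(rowSums(trans) - 1) < 1e-9))
  alpha <- matrix(0, n, 3)
  beta <- matrix(0, n, 3)
  scale <- numeric(n)
  a <- init * e[1, ]
  scale[1] <- sum(a)
  alpha[1, ] <- a / scale[1]
  if (n > 1) {
    for (t in 2:n) {
      a <- drop(alpha[t - 1, ] %*% trans) * e[t, ]
      scale[t] <- sum(a)
      alpha[t, ] <- a / scale[t]
    }
  }
  beta[n, ] <- 1
  if (n > 1) {
    for (t in (n - 1):1)
      beta[t, ] <- drop(trans %*% (e[t + 1, ] * beta[t + 1, ])) / scale[t + 1]
  }
  post <- alpha * beta
  post <- post / rowSums(post)
  colnames(post) <- .STATES
  list(posterior = post,
       states = .STATES[max.col(post, ties.method = "first")])
}

#' Viterbi decoding
#'
#' Maximum-likelihood state path in log space. Masked bins contribute
#' emission 1.0 (log 0) for every state. Score ties during the recursion and
#' at the terminal bin are broken deterministically by the fixed state order
#' MOTHER < MPV < FATHER.
#'
#' @inheritParams forwardBackward
#' @return list with `states` (the decoded path) and `logScore` (the path's
#'   log probability).
#' @export
viterbiPath <- function(emissions, trans, mask = NULL, init = rep(1 / 3, 3)) {
  e <- .maskedEmissions(emissions, mask)
  n <- nrow(e)
  logE <- log(e)
  logT <- log(trans)
  delta <- matrix(-Inf, n, 3)
  back <- matrix(1L, n, 3)
  delta[1, ] <- log(init) + logE[1, ]
  if (n > 1) {
    for (t in 2:n) {
      for (k in 1:3) {
        cand <- delta[t - 1, ] + logT[, k]
        back[t, k] <- which.max(cand)     # first max: state-order tie-break
        delta[t, k] <- cand[back[t, k]] + logE[t, k]
      }
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1) for (t in (n - 1):1) path[t] <- back[t + 1, path[t + 1]]
  list(states = .STATES[path], logScore = max(delta[n, ]))
}
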