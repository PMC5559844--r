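# Per-bin one-vs-rest L2-regularized logistic regression.
#
# The training set per bin is tiny (the two parents, their mid-parent vector,
# and optional replicates), while the feature dimension is the number of
# informative positions in the bin. The optimum of the L2-penalized primal
# lies in the span of the training rows, so each binary subproblem is solved
# over the (n+1)-dimensional span coefficients with BFGS:
#   min_{v,b}  0.5 v'Kv + C * sum_i s_i log(1 + exp(-t_i (K v + b)_i))
# where K = X X', t_i in {-1,+1} and s_i is the per-class sample weight.
# Decision values for new vectors x are f = v' X x + b.

.log1pexp <- function(z) {
  # log(1 + exp(z)), stable for large |z|
  out <- numeric(length(z))
  big <- z > 33.3
  out[big] <- z[big]
  out[!big] <- log1p(exp(z[!big]))
  out
}

.fitBinaryLR <- function(K, target, sw, C = 1, maxit = 200L) {
  n <- nrow(K)
  obj <- function(par) {
    v <- par[1:n]; b <- par[n + 1]
    f <- drop(K %*% v) + b
    0.5 * sum(v * drop(K %*% v)) + C * sum(sw * .log1pexp(-target * f))
  }
  grd <- function(par) {
    v <- par[1:n]; b <- par[n + 1]
    f <- drop(K %*% v) + b
    u <- sw * target * stats::plogis(-target * f)
    c(drop(K %*% v) - C * drop(K %*% u), -C * sum(u))
  }
  fit <- stats::optim(rep(0, n + 1), obj, grd, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12))
  list(v = fit$par[1:n], b = fit$par[n + 1])
}

# Weighted multinomial (softmax) logistic ridge in the same dual-span
# parametrization: per class k, w_k = X' v_k. Objective
#   0.5 sum_k v_k' K v_k + C sum_i s_i CE(y_i, softmax(K V + b)_i).
.fitMultinomialLR <- function(K, Y, sw, C = 1, maxit = 300L) {
  n <- nrow(K)
  unpack <- function(par) list(V = matrix(par[1:(3 * n)], n, 3),
                               b = par[3 * n + 1:3])
  obj <- function(par) {
    pb <- unpack(par)
    Fm <- K %*% pb$V + rep(pb$b, each = n)
    Fm <- Fm - apply(Fm, 1, max)
    logZ <- log(rowSums(exp(Fm)))
    0.5 * sum(pb$V * (K %*% pb$V)) -
      C * sum(sw * (rowSums(Y * Fm) - logZ))
  }
  grd <- function(par) {
    pb <- unpack(par)
    Fm <- K %*% pb$V + rep(pb$b, each = n)
    Fm <- Fm - apply(Fm, 1, max)
    P <- exp(Fm) / rowSums(exp(Fm))
    R <- sw * (P - Y)
    c(as.vector(K %*% pb$V + C * K %*% R), C * colSums(R))
  }
  fit <- stats::optim(rep(0, 3 * n + 3), obj, grd, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12))
  unpack(fit$par)
}

#' Train a per-bin classifier and classify sample vectors
#'
#' Fits an L2-regularized multinomial logistic regression on the labeled
#' parental/mid-parent feature vectors of one bin and returns the class
#' probability 3-vector for each sample vector. Class weights are applied as
#' per-class sample weights.
#'
#' Two schemes are available. The default, `"multinomial"`, fits a single
#' softmax model; probabilities at the training prototypes are then sharp,
#' which is essential because they feed the HMM as emissions. The
#' `"ovr"` scheme fits three one-vs-rest binary models and normalizes their
#' sigmoid outputs; it is provided for comparison but is structurally
#' limited here: the mid-parent prototype is the exact midpoint of the
#' parental prototypes, so any linear score satisfies f(mpv) = (f(m) +
#' f(f)) / 2 and the balanced MPV-vs-rest subproblem optimizes to the flat
#' solution with probability 0.5 everywhere, capping homozygous bins at 2:1
#' odds and biasing the smoothing stages toward the heterozygous state.
#'
#' The default inverse regularization strength is deliberately large
#' (`C = 100`): the training set is a handful of noiseless prototype
#' vectors, so the intended behavior is a soft nearest-prototype rule.
#'
#' If all training vectors are identical (the parents do not differ anywhere
#' in the bin), uniform probabilities are emitted and the bin is flagged
#' uninformative.
#'
#' @param trainX numeric matrix of training vectors (rows = training samples,
#'   columns = informative positions in the bin).
#' @param trainLabels character vector of labels in
#'   `c("MOTHER", "MPV", "FATHER")`, parallel to `trainX` rows.
#' @param sampleX numeric matrix of vectors to classify (same columns).
#' @param classWeights length-3 weight vector in state order; the default
#'   1:2:1 weighting reflects expected F2 genotype frequencies.
#' @param C inverse regularization strength of the penalized log-loss.
#' @param scheme `"multinomial"` (softmax, default) or `"ovr"`.
#' @return list with `probs` (matrix `nrow(sampleX)` x 3, rows summing to 1),
#'   `states` (argmax labels, ties broken in state order), and
#'   `uninformative` flag.
#' @export
trainClassifyBin <- function(trainX, trainLabels, sampleX,
                             classWeights = c(0.25, 0.5, 0.25), C = 100,
                             scheme = c("multinomial", "ovr")) {
  scheme <- match.arg(scheme)
  trainX <- as.matrix(trainX); sampleX <- as.matrix(sampleX)
  stopifnot(nrow(trainX) == length(trainLabels),
            ncol(trainX) == ncol(sampleX),
            all(trainLabels %in% .STATES), length(classWeights) == 3)
  m <- nrow(sampleX)
  uninformative <- nrow(trainX) < 2 ||
    max(abs(sweep(trainX, 2, trainX[1, ]))) < 1e-12
  if (uninformative) {
    probs <- matrix(1 / 3, m, 3, dimnames = list(NULL, .STATES))
    return(list(probs = probs, states = rep(.STATES[1], m),
                uninformative = TRUE))
  }
  K <- tcrossprod(trainX)
  cross <- trainX %*% t(sampleX)       # n_train x m
  sw <- classWeights[match(trainLabels, .STATES)]
  if (scheme == "multinomial") {
    Y <- outer(trainLabels, .STATES, `==`) * 1
    fit <- .fitMultinomialLR(K, Y, sw, C = C)
    dec <- crossprod(cross, fit$V) + rep(fit$b, each = m)
    dec <- dec - apply(dec, 1, max)
    probs <- exp(dec) / rowSums(exp(dec))
  } else {
    dec <- matrix(NA_real_, m, 3)
    for (k in seq_along(.STATES)) {
      target <- ifelse(trainLabels == .STATES[k], 1, -1)
      fit <- .fitBinaryLR(K, target, sw, C = C)
      dec[, k] <- drop(crossprod(cross, fit$v)) + fit$b
    }
    p <- stats::plogis(dec)
    rs <- rowSums(p)
    zero <- rs < 1e-300
    p[zero, ] <- 1 / 3
    rs[zero] <- 1
    probs <- p / rs
  }
  dimnames(probs) <- list(NULL, .STATES)
  states <- .STATES[max.col(probs, ties.method = "first")]
  list(probs = probs, states = states, uninformative = FALSE)
}
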