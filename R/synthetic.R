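#' @include covariates-io.R
NULL

#' Random sparse positive-definite precision matrix
#'
#' Ground-truth generator for estimator validation: picks exactly
#' \code{round(density * n(n-1)/2)} off-diagonal support pairs uniformly
#' at random, assigns them signed weights with magnitude in
#' \code{weightRange}, and inflates the diagonal to strict diagonal
#' dominance (each row's diagonal exceeds the sum of absolute
#' off-diagonal entries), which guarantees positive definiteness.
#'
#' @param n dimension.
#' @param density fraction of possible edges present, in (0, 1].
#' @param seed integer seed (fully determines the matrix).
#' @param weightRange magnitude range of edge weights.
#' @return n x n symmetric positive-definite matrix with attribute
#'   \code{"edges"}: the 2-column matrix of (i, j) support pairs, i < j.
#' @export
randomSparsePrecision <- function(n, density, seed,
                                  weightRange = c(0.4, 0.8)) {
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  set.seed(as.integer(seed))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  m <- round(density * nrow(pairs))
  P <- matrix(0, n, n)
  edges <- pairs[integer(0), , drop = FALSE]
  if (m > 0) {
    sel <- sort(sample.int(nrow(pairs), m))
    edges <- pairs[sel, , drop = FALSE]
    w <- stats::runif(m, weightRange[1], weightRange[2]) *
      sample(c(-1, 1), m, replace = TRUE)
    P[edges] <- w
    P <- P + t(P)
  }
  diag(P) <- rowSums(abs(P)) + stats::runif(n, 0.3, 0.6)
  attr(P, "edges") <- unname(edges[order(edges[, 1], edges[, 2]), ,
                                   drop = FALSE])
  P
}

#' Synthetic covariate data from a known model
#'
#' Draws t independent frames from the model (real MD frames are
#' autocorrelated; independence is the clean regime for estimator
#' validation) and records the generating ground truth.
#'
#' @param model a [GaussianGraphicalModel-class].
#' @param t number of frames (>= 2).
#' @param seed integer seed.
#' @return a list with \code{data} (a [CovariateMatrix-class]) and
#'   \code{truth} (a list: the generating \code{model}, the \code{seed}).
#' @export
ggmDataset <- function(model, t, seed) {
  if (t < 2) stop("t must be >= 2")
  x <- sampleModel(model, t, seed = seed)
  list(data = covariateMatrix(x, labels = model@labels),
       truth = list(model = model, seed = as.integer(seed)))
}

#' Piecewise-stationary switching trajectory
#'
#' Emulates a trajectory that hops between conformational sub-states: a
#' hidden state sequence is drawn from a Markov chain (initial state from
#' \code{prior}, default uniform), and each window's frames are drawn
#' independently from that state's model.
#'
#' @param models list of k [GaussianGraphicalModel-class] objects of equal
#'   dimension (one per state).
#' @param transition k x k row-stochastic transition matrix.
#' @param windows number of windows (>= 1).
#' @param framesPerWindow frames per window (>= 2).
#' @param seed integer seed.
#' @param prior initial-state distribution (default uniform).
#' @return list with \code{data} (a [CovariateMatrix-class]) and
#'   \code{truth} (list: \code{states} — the hidden per-window state ids,
#'   \code{transition}, \code{models}, \code{framesPerWindow},
#'   \code{seed}).
#' @export
switchingTrajectory <- function(models, transition, windows, framesPerWindow,
                                seed, prior = NULL) {
  k <- length(models)
  transition <- as.matrix(transition)
  if (!all(dim(transition) == k)) stop("transition must be k x k")
  if (any(transition < 0) || max(abs(rowSums(transition) - 1)) > 1e-8)
    stop("transition rows must be stochastic")
  if (is.null(prior)) prior <- rep(1 / k, k)
  set.seed(as.integer(seed))
  states <- integer(windows)
  states[1] <- sample.int(k, 1L, prob = prior)
  if (windows > 1L) for (i in 2:windows)
    states[i] <- sample.int(k, 1L, prob = transition[states[i - 1L], ])
  frames <- lapply(states, function(s)
    sampleModel(models[[s]], framesPerWindow))
  x <- do.call(rbind, frames)
  list(data = covariateMatrix(x, labels = models[[1]]@labels),
       truth = list(states = states, transition = transition,
                    models = models,
                    framesPerWindow = as.integer(framesPerWindow),
                    seed = as.integer(seed)))
}

.edge_set <- function(P, threshold = 1e-8) {
  idx <- which(upper.tri(P) & abs(P) > threshold)
  idx
}

#' Recovery report against synthetic ground truth
#'
#' For a fitted [GaussianGraphicalModel-class]: edge precision, recall and
#' F1 of the fitted support against the generating support. For a fitted
#' [MarkovChainModel-class]: states are matched to the generating states
#' by the permutation minimizing the transition-matrix max-abs error, and
#' that error is reported together with the matching.
#'
#' @param truth the \code{truth} element returned by [ggmDataset()] or
#'   [switchingTrajectory()] (or a model / transition matrix directly).
#' @param fitted a fitted [GaussianGraphicalModel-class] or
#'   [MarkovChainModel-class].
#' @param threshold edge threshold on |precision|.
#' @return a list of class \code{recoveryReport}: for models,
#'   \code{precision}, \code{recall}, \code{f1}, \code{nTrue},
#'   \code{nFitted}; for chains, \code{permutation},
#'   \code{transitionError} (max-abs after matching).
#' @export
recoveryReport <- function(truth, fitted, threshold = 1e-8) {
  if (is(fitted, "GaussianGraphicalModel")) {
    trueModel <- if (is(truth, "GaussianGraphicalModel")) truth
                 else truth$model
    Pt <- trueModel@precision
    if (!all(dim(Pt) == dim(fitted@precision)))
      stop("truth and fitted model dimensions differ")
    ts <- .edge_set(Pt, threshold)
    fs <- .edge_set(fitted@precision, threshold)
    tp <- length(intersect(ts, fs))
    prec <- if (length(fs)) tp / length(fs) else if (!length(ts)) 1 else 0
    rec <- if (length(ts)) tp / length(ts) else 1
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    structure(list(precision = prec, recall = rec, f1 = f1,
                   nTrue = length(ts), nFitted = length(fs)),
              class = "recoveryReport")
  } else if (is(fitted, "MarkovChainModel")) {
    Tt <- if (is.matrix(truth)) truth else truth$transition
    k <- nrow(Tt)
    if (length(fitted@prior) != k)
      stop("truth and fitted chain sizes differ")
    perms <- .permutations(k)
    best <- NULL; bestErr <- Inf
    Tf <- fitted@transition
    for (p in perms) {
      err <- max(abs(Tf[p, p] - Tt))
      if (err < bestErr) { bestErr <- err; best <- p }
    }
    structure(list(permutation = best, transitionError = bestErr),
              class = "recoveryReport")
  } else stop("fitted must be a GaussianGraphicalModel or MarkovChainModel")
}

## All permutations of 1..k (k small: clusters number a handful)
.permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (p in .permutations(k - 1L)) {
      rest <- setdiff(seq_len(k), i)
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

#' @export
print.recoveryReport <- function(x, ...) {
  if (!is.null(x$f1))
    cat(sprintf("edge recovery: precision %.3f, recall %.3f, F1 %.3f (%d true, %d fitted)\n",
                x$precision, x$recall, x$f1, x$nTrue, x$nFitted))
  else
    cat(sprintf("chain recovery: transition max-abs error %.4f (permutation %s)\n",
                x$transitionError, paste(x$permutation, collapse = " ")))
  invisible(x)
}
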