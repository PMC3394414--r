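#' @include time-varying.R
NULL

#' Pairwise symmetric KL divergences between window models
#'
#' The T x T distance matrix used to cluster window models into
#' conformational sub-states: entry (i, j) is
#' \code{symmetricKL(model i, model j)}. Computed in closed form from the
#' cached per-model precisions, covariances and means (the log-determinant
#' terms cancel in the symmetrized divergence).
#'
#' @param tvm a [TimeVaryingModel-class] with T >= 2 windows.
#' @return symmetric T x T matrix with zero diagonal.
#' @export
pairwiseSymKL <- function(tvm) {
  models <- tvm@models
  T <- length(models)
  if (T < 2L) stop("at least 2 models required")
  n <- length(models[[1]]@mean)
  ## vec trick: tr(P_j Sigma_i) = <vec Sigma_i, vec P_j> for symmetric blocks
  Sig <- t(vapply(models, function(m) as.vector(m@covariance), numeric(n * n)))
  Pre <- t(vapply(models, function(m) as.vector(m@precision), numeric(n * n)))
  Mu <- t(vapply(models, function(m) m@mean, numeric(n)))
  cross <- Sig %*% t(Pre)                # cross[i, j] = tr(P_j Sigma_i)
  quad <- matrix(0, T, T)                # quad[i, j] = d_ij' P_i d_ij
  for (i in seq_len(T)) {
    d <- sweep(Mu, 2, Mu[i, ])
    quad[i, ] <- rowSums((d %*% models[[i]]@precision) * d)
  }
  D <- 0.5 * (cross + t(cross) + quad + t(quad) - 2 * n)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  pmax(D, 0)
}

#' Complete-linkage clustering of window models
#'
#' Agglomerative clustering under the maximum-linkage criterion (merge the
#' pair of clusters with the smallest maximum inter-element distance), cut
#' at k clusters. Cluster ids are assigned by order of first temporal
#' appearance, so cluster 1 always contains the first window.
#'
#' @param d symmetric distance matrix, e.g. from [pairwiseSymKL()].
#' @param k number of clusters, 1 <= k <= T.
#' @return integer vector of cluster ids 1..k, one per window, with
#'   attribute \code{"k"}.
#' @export
completeLinkage <- function(d, k) {
  d <- as.matrix(d)
  T <- nrow(d)
  k <- as.integer(k)
  if (k < 1L || k > T) stop("k must lie in 1..", T)
  labels0 <- if (k == T) seq_len(T) else if (k == 1L) rep(1L, T) else
    stats::cutree(stats::hclust(stats::as.dist(d), method = "complete"), k = k)
  ## relabel by first temporal appearance
  first <- match(unique(labels0), labels0)
  relab <- integer(max(labels0))
  relab[labels0[sort(first)]] <- seq_along(first)
  out <- relab[labels0]
  attr(out, "k") <- k
  out
}

#' Suggested number of sub-states
#'
#' Heuristic \code{ceiling(log(T))}: the number of sub-states visited by a
#' sequence of T window models is taken proportional to the logarithm of
#' T, because sub-states are separated by energy barriers and the
#' probability of surmounting a barrier is exponentially small in its
#' height. At T = 500 this gives 7. A documented, overridable reading —
#' pass an explicit k to [completeLinkage()] to override.
#'
#' @param T number of window models (>= 2).
#' @return integer.
#' @export
suggestK <- function(T) {
  if (T < 2) stop("T must be >= 2")
  as.integer(ceiling(log(T)))
}

#' Estimate a Markov chain over clustered window models
#'
#' Treats the clusters as states: the transition probability from state i
#' to state j is the count of consecutive window pairs (i followed by j)
#' divided by the outgoing count of i, and the prior is the relative
#' cluster size. A state with no outgoing transitions (it appears only at
#' the trajectory end) becomes a self-loop, with a warning; counts are not
#' smoothed. The representative model of each state is, by default, the
#' cluster medoid under symmetric KL (smallest summed distance to the
#' other members); \code{representative = "pooled"} instead refits one
#' model on the pooled frames of the member windows (requires \code{data}).
#'
#' @param assignment integer cluster ids in temporal (window) order, as
#'   returned by [completeLinkage()].
#' @param tvm the [TimeVaryingModel-class] the assignment refers to.
#' @param distance optional precomputed [pairwiseSymKL()] matrix (avoids
#'   recomputation when choosing medoids).
#' @param representative \code{"medoid"} (default) or \code{"pooled"}.
#' @param data covariate matrix; required for \code{"pooled"}.
#' @param lambda penalty for pooled refits (default: the tvm's lambda).
#' @return a [MarkovChainModel-class].
#' @export
estimateChain <- function(assignment, tvm, distance = NULL,
                          representative = c("medoid", "pooled"),
                          data = NULL, lambda = NULL) {
  representative <- match.arg(representative)
  assignment <- as.integer(assignment)
  T <- length(assignment)
  if (T != tvm@windowSpec@count)
    stop("assignment length must equal the number of windows")
  k <- max(assignment)
  if (!all(seq_len(k) %in% assignment))
    stop("every cluster id 1..k must be used")

  counts <- matrix(0, k, k)
  if (T > 1L) for (i in seq_len(T - 1L))
    counts[assignment[i], assignment[i + 1L]] <-
      counts[assignment[i], assignment[i + 1L]] + 1
  trans <- counts
  for (i in seq_len(k)) {
    rs <- sum(counts[i, ])
    if (rs == 0) {
      warning("state ", i, " has no outgoing transitions; using a self-loop")
      trans[i, i] <- 1
    } else trans[i, ] <- counts[i, ] / rs
  }
  prior <- tabulate(assignment, k) / T

  reps <- vector("list", k)
  if (representative == "medoid") {
    if (is.null(distance)) distance <- pairwiseSymKL(tvm)
    for (s in seq_len(k)) {
      members <- which(assignment == s)
      if (length(members) == 1L) reps[[s]] <- tvm@models[[members]]
      else {
        tot <- rowSums(distance[members, members, drop = FALSE])
        reps[[s]] <- tvm@models[[members[which.min(tot)]]]
      }
    }
  } else {
    if (is.null(data)) stop("representative = 'pooled' requires data")
    x <- .as_cov_values(data)
    if (is.null(lambda)) lambda <- tvm@lambda
    ws <- tvm@windowSpec
    labels <- tvm@models[[1]]@labels
    for (s in seq_len(k)) {
      rows <- which(ws@assignment %in% which(assignment == s))
      reps[[s]] <- learnGGM(covariateMatrix(x[rows, , drop = FALSE],
                                            labels = labels),
                            lambda = lambda)
    }
  }
  new("MarkovChainModel", prior = prior, transition = trans,
      stateModels = reps, framesPerState = tvm@windowSpec@width)
}

#' Generate a synthetic trajectory from a chain of models
#'
#' Samples a state sequence from the Markov chain (initial state from the
#' prior, then the transition matrix) and, for each visited state, draws
#' \code{framesPerState} conformations from that state's representative
#' model. Deterministic given the seed.
#'
#' @param chain a [MarkovChainModel-class].
#' @param nWindows number of windows (state visits) to generate (>= 1).
#' @param seed integer seed; if NULL the current RNG stream is used.
#' @return a list with \code{data} (a [CovariateMatrix-class] of
#'   \code{nWindows * framesPerState} frames) and \code{states} (the
#'   hidden state id of each window).
#' @export
sampleChainTrajectory <- function(chain, nWindows, seed = NULL) {
  nWindows <- as.integer(nWindows)
  if (nWindows < 1L) stop("nWindows must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  k <- length(chain@prior)
  states <- integer(nWindows)
  states[1] <- sample.int(k, 1L, prob = chain@prior)
  if (nWindows > 1L) for (i in 2:nWindows)
    states[i] <- sample.int(k, 1L, prob = chain@transition[states[i - 1L], ])
  w <- chain@framesPerState
  frames <- lapply(states, function(s)
    sampleModel(chain@stateModels[[s]], w))
  x <- do.call(rbind, frames)
  list(data = covariateMatrix(x, labels = chain@stateModels[[1]]@labels),
       states = states)
}

#' Stationary distribution of a Markov chain
#'
#' Left eigenvector of the transition matrix for eigenvalue 1, normalized
#' to sum 1.
#'
#' @param chain a [MarkovChainModel-class] (or a row-stochastic matrix).
#' @return length-k probability vector.
#' @export
stationaryDistribution <- function(chain) {
  P <- if (is(chain, "MarkovChainModel")) chain@transition else as.matrix(chain)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}
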