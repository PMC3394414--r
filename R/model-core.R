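#' @include AllGenerics.R
NULL

## log|P| via Cholesky; P must be PD
.logdet <- function(P) 2 * sum(log(diag(chol(P))))

.check_dim <- function(model, x) {
  n <- length(model@mean)
  if (is.matrix(x)) {
    if (ncol(x) != n) stop("dimension mismatch: x has ", ncol(x),
                           " columns, model has n = ", n)
  } else if (length(x) != n) {
    stop("dimension mismatch: x has length ", length(x), ", model has n = ", n)
  }
  if (!all(is.finite(x))) stop("x must be finite")
  invisible(n)
}

#' Log density under a Gaussian graphical model
#'
#' Evaluates \eqn{\log P(x) = -\frac12\log((2\pi)^n|\Sigma|)
#' - \frac12 (x-\mu)^T \Sigma^{-1} (x-\mu)} in nats.
#'
#' @param model a [GaussianGraphicalModel-class].
#' @param x a length-n vector, or a matrix with one row per observation.
#' @return a scalar, or a vector with one value per row of \code{x}.
#' @examples
#' m <- ggm(precision = diag(1))
#' logDensity(m, 0)          # -0.5 * log(2*pi)
#' @export
logDensity <- function(model, x) {
  .check_dim(model, x)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  d <- sweep(x, 2, model@mean)
  quad <- rowSums((d %*% model@precision) * d)
  as.vector(freeEnergy(model) - quad / 2)
}

#' Free energy of the model
#'
#' Returns \eqn{-\ln Z} with \eqn{Z = \sqrt{(2\pi)^n |\Sigma|}}; equals the
#' log density at the mean.
#'
#' @param model a [GaussianGraphicalModel-class].
#' @return scalar, nats.
#' @export
freeEnergy <- function(model) {
  n <- length(model@mean)
  -0.5 * (n * log(2 * pi) - .logdet(model@precision))
}

#' Differential entropy
#'
#' \eqn{\frac12 \log((2\pi e)^n |\Sigma|)} in nats. For a time-varying
#' model this is the segmentation diagnostic plotted along the trajectory.
#'
#' @param model a [GaussianGraphicalModel-class].
#' @return scalar, nats.
#' @export
differentialEntropy <- function(model) {
  n <- length(model@mean)
  0.5 * (n * log(2 * pi * exp(1)) - .logdet(model@precision))
}

#' Kullback-Leibler divergence between two models
#'
#' \deqn{KL(M_0\|M_1) = \tfrac12\big(\mathrm{tr}(\Sigma_1^{-1}\Sigma_0) +
#'   (\mu_1-\mu_0)^T\Sigma_1^{-1}(\mu_1-\mu_0) -
#'   \ln(|\Sigma_0|/|\Sigma_1|) - n\big)}
#'
#' Non-negative; zero iff the two distributions coincide. Not symmetric:
#' use [symmetricKL()] as a model-to-model distance.
#'
#' @param m0,m1 [GaussianGraphicalModel-class] objects of equal dimension.
#' @return scalar >= 0 (up to round-off), nats.
#' @export
klDivergence <- function(m0, m1) {
  n <- length(m0@mean)
  if (length(m1@mean) != n) stop("dimension mismatch between models")
  P1 <- m1@precision
  delta <- m1@mean - m0@mean
  0.5 * (sum(P1 * m0@covariance) + sum(delta * (P1 %*% delta)) +
         .logdet(m0@precision) - .logdet(P1) - n)
}

#' Symmetric KL divergence
#'
#' \eqn{KL(M_0\|M_1) + KL(M_1\|M_0)}; symmetric in its arguments, used as
#' the distance when clustering window models into sub-states.
#'
#' @inheritParams klDivergence
#' @return scalar >= 0.
#' @export
symmetricKL <- function(m0, m1) klDivergence(m0, m1) + klDivergence(m1, m0)

#' Condition a model on a subset of variables
#'
#' Clamps the variables \code{variables} (the set V) to \code{values} and
#' returns the marginal model over the remaining variables W, a Gaussian
#' with
#' \deqn{\mu_{W|v} = \mu_W + \Sigma_{WV}\Sigma_{VV}^{-1}(v - \mu_V),\qquad
#'       \Sigma_{W} = \Sigma_{WW} - \Sigma_{WV}\Sigma_{VV}^{-1}\Sigma_{VW}.}
#' Equivalently (and as implemented), the conditional precision is the
#' sub-block \eqn{\Sigma^{-1}_{WW}} of the precision matrix, so the sparse
#' edge structure over W is preserved exactly. This is the inference step
#' of perturbation analysis: clamp one part of the molecule, read off the
#' predicted response of the rest.
#'
#' @param model a [GaussianGraphicalModel-class].
#' @param variables indices or labels of the conditioned set V; at least
#'   one variable, and at least one variable must remain free.
#' @param values numeric clamp values v, one per conditioned variable.
#' @return a [GaussianGraphicalModel-class] over the free variables W.
#' @examples
#' S <- matrix(c(1, .5, .5, 1), 2)
#' m <- ggm(covariance = S, mean = c(0, 0), labels = c("a", "b"))
#' conditionModel(m, "b", 2)   # mean of a becomes 0.5 * 2
#' @export
conditionModel <- function(model, variables, values) {
  n <- length(model@mean)
  if (is.character(variables)) {
    idx <- match(variables, model@labels)
    if (anyNA(idx)) stop("unknown variable label(s): ",
                         paste(variables[is.na(idx)], collapse = ", "))
  } else {
    idx <- as.integer(variables)
    if (any(idx < 1L | idx > n)) stop("variable indices out of range 1..", n)
  }
  if (anyDuplicated(idx)) stop("conditioned variables must be distinct")
  if (length(idx) < 1L) stop("at least one variable must be conditioned")
  if (length(idx) >= n) stop("at least one variable must remain free")
  if (length(values) != length(idx))
    stop("values must match the number of conditioned variables")
  if (!all(is.finite(values))) stop("clamp values must be finite")
  W <- setdiff(seq_len(n), idx)
  P <- model@precision
  PWW <- P[W, W, drop = FALSE]
  PWV <- P[W, idx, drop = FALSE]
  shift <- solve(PWW, PWV %*% (as.numeric(values) - model@mean[idx]))
  ggm(precision = PWW, mean = model@mean[W] - as.vector(shift),
      labels = model@labels[W], lambda = model@lambda)
}

#' Sample conformations from a model
#'
#' Draws \code{count} independent samples from \eqn{N(\mu, \Sigma)} using
#' the lower-triangular Cholesky factor of the covariance. The seed fully
#' determines the output.
#'
#' @param model a [GaussianGraphicalModel-class].
#' @param count number of samples (>= 1).
#' @param seed integer seed; if NULL the current RNG stream is used.
#' @return a \code{count} x n matrix, columns named by covariate labels.
#' @export
sampleModel <- function(model, count, seed = NULL) {
  count <- as.integer(count)
  if (count < 1L) stop("count must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(model@mean)
  L <- t(chol(model@covariance))
  z <- matrix(stats::rnorm(count * n), count, n)
  x <- sweep(z %*% t(L), 2, model@mean, "+")
  colnames(x) <- model@labels
  x
}

#' Log likelihood of a covariate data set under a model
#'
#' Sums [logDensity()] over all frames; \code{normalization} divides the
#' total by the number of frames (\code{"per_frame"}) or by frames times
#' dimension (\code{"per_frame_per_dim"}). The normalization is exposed
#' because published per-data-set likelihood summaries differ in
#' convention.
#'
#' @param model a [GaussianGraphicalModel-class].
#' @param data a [CovariateMatrix-class] (or plain matrix) with n columns.
#' @param normalization one of \code{"total"}, \code{"per_frame"},
#'   \code{"per_frame_per_dim"}.
#' @return scalar, nats.
#' @export
dataLogLikelihood <- function(model, data,
                              normalization = c("total", "per_frame",
                                                "per_frame_per_dim")) {
  normalization <- match.arg(normalization)
  x <- if (is(data, "CovariateMatrix")) data@values else as.matrix(data)
  .check_dim(model, x)
  ll <- sum(logDensity(model, x))
  switch(normalization,
         total = ll,
         per_frame = ll / nrow(x),
         per_frame_per_dim = ll / (nrow(x) * ncol(x)))
}

#' Edge list of the Markov random field
#'
#' The non-zero off-diagonal entries of the precision matrix are the edges
#' of the model graph: direct couplings between covariates. Entries with
#' absolute value at or below \code{threshold} are treated as structural
#' zeros (floating point cannot represent "exactly zero" reliably).
#'
#' @param model a [GaussianGraphicalModel-class].
#' @param threshold edge threshold on |precision| (default 1e-8).
#' @return a data.frame with columns \code{i}, \code{j} (indices, i < j),
#'   \code{i_label}, \code{j_label}, and \code{weight} (the precision
#'   entry), ordered by (i, j).
#' @export
edgeList <- function(model, threshold = 1e-8) {
  P <- model@precision
  n <- nrow(P)
  ut <- which(upper.tri(P) & abs(P) > threshold, arr.ind = TRUE)
  ord <- order(ut[, 1], ut[, 2])
  ut <- ut[ord, , drop = FALSE]
  data.frame(i = ut[, 1], j = ut[, 2],
             i_label = model@labels[ut[, 1]],
             j_label = model@labels[ut[, 2]],
             weight = P[ut],
             stringsAsFactors = FALSE)
}
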