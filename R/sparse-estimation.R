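#' @include model-core.R
NULL

.as_cov_values <- function(data) {
  if (is(data, "CovariateMatrix")) data@values else {
    m <- as.matrix(data); storage.mode(m) <- "double"; m
  }
}

#' Sample mean of a covariate matrix
#'
#' @param data a [CovariateMatrix-class] (or plain matrix).
#' @return length-n vector of column means.
#' @export
sampleMean <- function(data) {
  colMeans(.as_cov_values(data))
}

#' Sample covariance of a covariate matrix
#'
#' Centered second-moment matrix scaled by \code{1/t}:
#' \eqn{S = \frac{1}{t}\sum_i (d_i-\mu)(d_i-\mu)^T}. The 1/t scaling makes
#' the trace term of the penalized likelihood the per-frame average, so a
#' given L1 penalty has comparable strength across trajectory lengths.
#'
#' @param data a [CovariateMatrix-class] (or plain matrix) with t >= 2 rows.
#' @return n x n symmetric positive semi-definite matrix.
#' @export
sampleCovariance <- function(data) {
  x <- .as_cov_values(data)
  if (nrow(x) < 2L) stop("at least 2 frames required for a sample covariance")
  xc <- sweep(x, 2, colMeans(x))
  crossprod(xc) / nrow(x)
}

## Soft threshold
.soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

## Inner box-constrained quadratic subproblem of the block coordinate
## descent, solved through its dual:
##   min_x  x' Q x - 2 s' x + 2 lambda ||x||_1,
## by cyclic coordinate minimization; the primal column is y = Q x.
## Q = W11 (current iterate with row/col j removed), s = S[-j, j].
.l1qp_cd <- function(Q, s, lambda, x, tol = 1e-10, maxIter = 10000L) {
  p <- length(s)
  qx <- as.vector(Q %*% x)
  dQ <- diag(Q)
  for (iter in seq_len(maxIter)) {
    delta <- 0
    for (i in seq_len(p)) {
      r <- s[i] - qx[i] + dQ[i] * x[i]
      xi <- if (r > lambda) (r - lambda) / dQ[i]
            else if (r < -lambda) (r + lambda) / dQ[i]
            else 0
      d <- xi - x[i]
      if (d != 0) {
        qx <- qx + Q[, i] * d
        x[i] <- xi
        if (abs(d) > delta) delta <- abs(d)
      }
    }
    if (delta <= tol) break
  }
  list(x = x, y = qx)
}

#' Block coordinate descent for the dual covariance problem
#'
#' Solves the dual of the L1-penalized maximum-likelihood precision
#' estimation problem,
#' \deqn{W^* = \arg\max \{\log|W| : \|W - S\|_\infty \le \lambda\},}
#' by iteratively optimizing one row/column of \eqn{W} at a time. Each
#' column update solves the box-constrained quadratic subproblem
#' \eqn{\min_y \{y^T W_{11}^{-1} y : \|y - S_j\|_\infty \le \lambda\}}
#' through its dual, an L1-penalized quadratic program, by cyclic
#' coordinate minimization. \eqn{W} is initialized at \eqn{S + \lambda I}
#' and every iterate is strictly positive definite; the sweep loop stops
#' when the duality-gap criterion
#' \eqn{\mathrm{tr}(W^{-1}S) - n + \lambda\|W^{-1}\|_1 \le \epsilon}
#' is met.
#'
#' The precision matrix is assembled from the dual coefficient vectors of
#' the final sweep (\eqn{P_{jj} = 1/(W_{jj} - W_j^T x_j)},
#' \eqn{P_{\cdot j} = -x_j P_{jj}}), so zeros in the coefficient vectors
#' become exact structural zeros — the learned graph's missing edges.
#'
#' @param S symmetric positive semi-definite sample covariance.
#' @param lambda L1 penalty \eqn{\lambda \ge 0}; \code{lambda = 0} requires
#'   S strictly positive definite (the feasible set is the single point S).
#' @param epsilon convergence tolerance on the duality gap (default
#'   \code{1e-6 * n}).
#' @param maxSweeps sweep budget (default 200); exhausting it flags the
#'   result \code{converged = FALSE}, never silently.
#' @param keepPath if TRUE, store the iterate W after every sweep (for
#'   diagnostics).
#' @return a list with elements \code{W} (the regularized covariance),
#'   \code{precision}, \code{sweeps}, \code{converged}, \code{gap} (final
#'   duality gap), \code{logdetPath} (dual objective \eqn{\log|W|} after
#'   each sweep), and optionally \code{path}.
#' @references Banerjee, El Ghaoui & d'Aspremont (2008), JMLR 9:485-516.
#' @export
bcdSolve <- function(S, lambda, epsilon = NULL, maxSweeps = 200L,
                     keepPath = FALSE) {
  S <- as.matrix(S)
  n <- nrow(S)
  if (ncol(S) != n || max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
    stop("S must be a symmetric matrix")
  S <- (S + t(S)) / 2
  if (lambda < 0) stop("lambda must be >= 0")
  if (is.null(epsilon)) epsilon <- 1e-6 * n
  if (epsilon <= 0) stop("epsilon must be > 0")
  maxSweeps <- as.integer(maxSweeps)

  if (lambda == 0) {
    ch <- tryCatch(chol(S), error = function(e)
      stop("lambda = 0 requires a strictly positive-definite S"))
    P <- chol2inv(ch)
    return(list(W = S, precision = P, sweeps = 0L, converged = TRUE,
                gap = 0, logdetPath = 2 * sum(log(diag(ch)))))
  }

  W <- S + lambda * diag(n)
  if (n == 1L) {
    return(list(W = W, precision = 1 / W, sweeps = 0L, converged = TRUE,
                gap = 0, logdetPath = log(W[1, 1])))
  }

  X <- matrix(0, n - 1L, n)       # warm-started dual coefficients per column
  logdetPath <- numeric(0)
  path <- if (keepPath) list() else NULL
  converged <- FALSE
  gap <- Inf
  sweeps <- 0L
  for (sweep in seq_len(maxSweeps)) {
    for (j in seq_len(n)) {
      sol <- .l1qp_cd(W[-j, -j, drop = FALSE], S[-j, j], lambda, X[, j])
      X[, j] <- sol$x
      W[-j, j] <- sol$y
      W[j, -j] <- sol$y
    }
    sweeps <- sweep
    ch <- chol(W)
    P <- chol2inv(ch)
    logdetPath <- c(logdetPath, 2 * sum(log(diag(ch))))
    if (keepPath) path[[sweep]] <- W
    gap <- sum(P * S) - n + lambda * sum(abs(P))
    if (gap <= epsilon) { converged <- TRUE; break }
  }
  if (!converged)
    warning("block coordinate descent: sweep budget (", maxSweeps,
            ") exhausted; final duality gap ", signif(gap, 4))

  ## assemble precision from the dual coefficients: exact structural zeros
  ## (one more refresh sweep so each column block-inverse is consistent)
  P <- matrix(0, n, n)
  for (j in seq_len(n)) {
    sol <- .l1qp_cd(W[-j, -j, drop = FALSE], S[-j, j], lambda, X[, j])
    X[, j] <- sol$x
    W[-j, j] <- sol$y
    W[j, -j] <- sol$y
  }
  for (j in seq_len(n)) {
    x <- X[, j]
    pjj <- 1 / (W[j, j] - sum(W[-j, j] * x))
    P[j, j] <- pjj
    P[-j, j] <- -x * pjj
  }
  ## the support is symmetric by the KKT conditions; average the values
  P <- (P + t(P)) / 2

  out <- list(W = W, precision = P, sweeps = sweeps, converged = converged,
              gap = gap, logdetPath = logdetPath)
  if (keepPath) out$path <- path
  out
}

#' Learn an L1-regularized Gaussian graphical model
#'
#' The time-averaged model estimator: computes the sample mean and sample
#' covariance of the covariate time series, solves the dual
#' maximum-determinant problem with [bcdSolve()] to obtain the regularized
#' covariance \eqn{W} and the sparse precision \eqn{W^{-1}}, and assembles
#' the model with natural parameter \eqn{h = \Sigma^{-1}\mu}. The penalty
#' trades data fit against the number of edges: larger \code{lambda},
#' sparser graph.
#'
#' @param data a [CovariateMatrix-class] (or plain matrix), t frames x n
#'   covariates.
#' @param lambda L1 penalty; defaults to the analytic choice
#'   [defaultLambda()] evaluated at the data's dimensions and column
#'   standard deviations.
#' @param epsilon,maxSweeps convergence controls passed to [bcdSolve()].
#' @return a [GaussianGraphicalModel-class] carrying the fitted lambda.
#' @examples
#' set.seed(1)
#' d <- covariateMatrix(matrix(rnorm(600), 200, 3))
#' m <- learnGGM(d, lambda = 0.1)
#' edgeList(m)
#' @export
learnGGM <- function(data, lambda = NULL, epsilon = NULL, maxSweeps = 200L) {
  x <- .as_cov_values(data)
  labels <- colnames(x)
  if (is.null(labels)) labels <- paste0("V", seq_len(ncol(x)))
  if (nrow(x) < 2L) stop("at least 2 frames required")
  if (is.null(lambda))
    lambda <- defaultLambda(nrow(x), ncol(x), sigma = apply(x, 2, stats::sd))
  mu <- colMeans(x)
  S <- sampleCovariance(x)
  fit <- bcdSolve(S, lambda, epsilon = epsilon, maxSweeps = maxSweeps)
  ggm(precision = fit$precision, mean = mu, covariance = fit$W,
      labels = labels, lambda = lambda)
}

#' Penalized log-likelihood objective
#'
#' The primal objective the estimator maximizes:
#' \eqn{\log|\Sigma^{-1}| - \mathrm{tr}(S\Sigma^{-1}) -
#' \lambda\|\Sigma^{-1}\|_1}, with the L1 norm summing the absolute values
#' of all matrix entries (diagonal included).
#'
#' @param precision positive-definite precision matrix.
#' @param S sample covariance.
#' @param lambda L1 penalty.
#' @return scalar.
#' @export
penalizedObjective <- function(precision, S, lambda) {
  precision <- as.matrix(precision)
  if (!.is_pd(precision)) stop("precision must be positive definite")
  .logdet(precision) - sum(S * precision) - lambda * sum(abs(precision))
}

#' Thresholded sample-precision baseline
#'
#' The sub-optimal comparator: inverts the (unregularized) sample
#' covariance and keeps the \code{edgeCount} largest-magnitude off-diagonal
#' entries as edges. Ties in magnitude are broken lexicographically by
#' (i, j). Useful to show what L1-regularized estimation buys over naive
#' thresholding.
#'
#' @param data a [CovariateMatrix-class] (or matrix).
#' @param edgeCount number of edges to keep.
#' @return an edge-list data.frame as in [edgeList()].
#' @export
thresholdBaseline <- function(data, edgeCount) {
  x <- .as_cov_values(data)
  labels <- colnames(x)
  if (is.null(labels)) labels <- paste0("V", seq_len(ncol(x)))
  S <- sampleCovariance(x)
  ch <- tryCatch(chol(S), error = function(e)
    stop("sample covariance is singular; use the regularized estimator ",
         "learnGGM() instead"))
  P <- chol2inv(ch)
  n <- nrow(P)
  ut <- which(upper.tri(P), arr.ind = TRUE)
  w <- P[ut]
  ord <- order(-abs(w), ut[, 1], ut[, 2])
  keep <- ord[seq_len(min(edgeCount, length(ord)))]
  keep <- keep[abs(w[keep]) > 0]
  keep <- keep[order(ut[keep, 1], ut[keep, 2])]
  data.frame(i = ut[keep, 1], j = ut[keep, 2],
             i_label = labels[ut[keep, 1]], j_label = labels[ut[keep, 2]],
             weight = w[keep], stringsAsFactors = FALSE)
}

#' Analytic default L1 penalty
#'
#' The test-based penalty choice of Banerjee et al. (2008): with t frames,
#' n covariates and error level \eqn{\alpha},
#' \deqn{\lambda(\alpha) = (\max_{i \ne j}\hat\sigma_i\hat\sigma_j)\,
#'   \frac{t_{t-2}(\alpha / (2n^2))}{\sqrt{t - 2 + t_{t-2}^2(\alpha/(2n^2))}},}
#' where \eqn{t_{t-2}(\beta)} is the upper-\eqn{\beta} quantile of the
#' Student t distribution with t-2 degrees of freedom. At this level the
#' probability of falsely joining any two of the n(n-1)/2 pairs of
#' distinct connectivity components is bounded by \eqn{\alpha}. Monotone
#' non-increasing in t (more frames, less shrinkage) and increasing as
#' \eqn{\alpha \to 0} (stricter error control, more shrinkage).
#'
#' @param t number of frames (> 2).
#' @param n number of covariates.
#' @param alpha error level in (0, 1), default 0.05.
#' @param sigma per-covariate standard deviations (default 1, i.e. the
#'   penalty for standardized data); length 1 or n.
#' @return scalar penalty.
#' @references Banerjee, El Ghaoui & d'Aspremont (2008), JMLR 9:485-516.
#' @export
defaultLambda <- function(t, n, alpha = 0.05, sigma = 1) {
  if (t <= 2) stop("t must exceed 2")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  q <- stats::qt(1 - alpha / (2 * n^2), df = t - 2)
  if (length(sigma) == 1L) smax <- sigma^2
  else {
    op <- outer(sigma, sigma)
    diag(op) <- 0
    smax <- max(op)
  }
  smax * q / sqrt(t - 2 + q^2)
}
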