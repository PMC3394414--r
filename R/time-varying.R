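#' @include sparse-estimation.R
NULL

#' Partition a trajectory into windows
#'
#' Splits the t frames into \code{T = floor(t / width)} contiguous,
#' non-overlapping windows of \code{width} frames each; trailing frames
#' beyond \code{T * width} are excluded (and reported via a message).
#'
#' @param data a [CovariateMatrix-class] (or matrix).
#' @param width window width in frames (2 <= width <= t).
#' @return a [WindowSpec-class].
#' @examples
#' d <- covariateMatrix(matrix(rnorm(22), 11, 2))
#' partitionWindows(d, 2)   # 5 windows, one frame dropped
#' @export
partitionWindows <- function(data, width) {
  x <- .as_cov_values(data)
  t <- nrow(x)
  width <- as.integer(width)
  if (width < 2L) stop("window width must be >= 2 frames")
  if (width > t) stop("window width (", width, ") exceeds trajectory length (", t, ")")
  count <- t %/% width
  dropped <- t - count * width
  if (dropped > 0)
    message(dropped, " trailing frame(s) beyond ", count,
            " full windows were dropped")
  assignment <- rep(NA_integer_, t)
  assignment[seq_len(count * width)] <- rep(seq_len(count), each = width)
  new("WindowSpec", width = width, count = count, assignment = assignment)
}

#' Sawtooth smoothing kernel
#'
#' Trailing one-sided kernel over the current window and the
#' \code{depth - 1} preceding windows, each older window receiving half
#' the weight of the one after it, normalized to sum 1. Depth 3 gives
#' weights 4/7, 2/7, 1/7 (0.57, 0.29, 0.14 at two decimals) on offsets
#' 0, -1, -2; depth 2 gives 2/3, 1/3 (the current window twice the weight
#' of the previous); depth 1 is the identity kernel (no smoothing).
#'
#' @param depth number of windows mixed (>= 1).
#' @return a [KernelSpec-class].
#' @export
sawtoothKernel <- function(depth) {
  depth <- as.integer(depth)
  if (depth < 1L) stop("depth must be >= 1")
  w <- 2^(seq(depth - 1L, 0L))
  kernelSpec(offsets = -(seq_len(depth) - 1L), weights = w / sum(w))
}

## Per-window means and covariances (each window centered on its own mean)
.window_stats <- function(x, ws) {
  T <- ws@count
  mus <- matrix(0, T, ncol(x))
  covs <- vector("list", T)
  for (k in seq_len(T)) {
    rows <- which(ws@assignment == k)
    xk <- x[rows, , drop = FALSE]
    mus[k, ] <- colMeans(xk)
    xc <- sweep(xk, 2, mus[k, ])
    covs[[k]] <- crossprod(xc) / nrow(xk)
  }
  list(mu = mus, cov = covs)
}

.effective_weights <- function(kernelSpec, tau, T) {
  k <- tau + kernelSpec@offsets
  ok <- k >= 1L & k <= T
  w <- kernelSpec@weights[ok]
  if (!any(w > 0)) stop("all kernel weights fall outside the trajectory ",
                        "for window ", tau)
  list(windows = k[ok], weights = w / sum(w))
}

#' Kernel-weighted covariance of a window
#'
#' \deqn{S(\tau) = \frac{\sum_k w_k S_k}{\sum_k w_k}} over the windows
#' \code{k = tau + offset} reachable by the kernel, where \eqn{S_k} is the
#' centered second-moment matrix of window k (same 1/|window| scaling as
#' [sampleCovariance()]). Windows falling outside the trajectory
#' contribute nothing and their weights are excluded from the normalizer.
#'
#' @param data a [CovariateMatrix-class] (or matrix).
#' @param windowSpec a [WindowSpec-class] from [partitionWindows()].
#' @param kernelSpec a [KernelSpec-class], e.g. [sawtoothKernel()].
#' @param tau window index, 1..T.
#' @return n x n symmetric positive semi-definite matrix.
#' @export
weightedCovariance <- function(data, windowSpec, kernelSpec, tau) {
  x <- .as_cov_values(data)
  T <- windowSpec@count
  tau <- as.integer(tau)
  if (tau < 1L || tau > T) stop("tau must lie in 1..", T)
  st <- .window_stats(x, windowSpec)
  ew <- .effective_weights(kernelSpec, tau, T)
  S <- 0
  for (i in seq_along(ew$windows))
    S <- S + ew$weights[i] * st$cov[[ew$windows[i]]]
  S
}

#' Fit a time-varying Gaussian graphical model
#'
#' One L1-regularized model per trajectory window, each fitted by
#' [bcdSolve()] on the kernel-weighted covariance \eqn{S(\tau)} with a
#' shared penalty, so topology and parameters evolve smoothly along the
#' trajectory. The per-window mean uses the same kernel weights as
#' \eqn{S(\tau)}.
#'
#' @param data a [CovariateMatrix-class] (or matrix).
#' @param width window width in frames.
#' @param kernel a [KernelSpec-class]; default [sawtoothKernel(1)], i.e.
#'   no smoothing.
#' @param lambda shared L1 penalty; default [defaultLambda()] at the
#'   per-window sample size \code{width} (each model sees roughly one
#'   window's worth of frames).
#' @param epsilon,maxSweeps convergence controls passed to [bcdSolve()].
#' @return a [TimeVaryingModel-class].
#' @export
learnTimeVarying <- function(data, width, kernel = sawtoothKernel(1),
                             lambda = NULL, epsilon = NULL, maxSweeps = 200L) {
  x <- .as_cov_values(data)
  labels <- colnames(x)
  if (is.null(labels)) labels <- paste0("V", seq_len(ncol(x)))
  ws <- partitionWindows(x, width)
  if (is.null(lambda))
    lambda <- defaultLambda(ws@width, ncol(x), sigma = apply(x, 2, stats::sd))
  st <- .window_stats(x, ws)
  T <- ws@count
  models <- vector("list", T)
  for (tau in seq_len(T)) {
    ew <- .effective_weights(kernel, tau, T)
    S <- 0
    mu <- 0
    for (i in seq_along(ew$windows)) {
      S <- S + ew$weights[i] * st$cov[[ew$windows[i]]]
      mu <- mu + ew$weights[i] * st$mu[ew$windows[i], ]
    }
    fit <- bcdSolve(S, lambda, epsilon = epsilon, maxSweeps = maxSweeps)
    models[[tau]] <- ggm(precision = fit$precision, mean = mu,
                         covariance = fit$W, labels = labels, lambda = lambda)
  }
  new("TimeVaryingModel", models = models, windowSpec = ws,
      kernelSpec = kernel, lambda = lambda)
}

#' Differential entropy along the trajectory
#'
#' One [differentialEntropy()] value per window model, in window order.
#' Peaks and valleys segment the trajectory into putative conformational
#' sub-states.
#'
#' @param tvm a [TimeVaryingModel-class].
#' @return length-T numeric vector (nats).
#' @export
entropySeries <- function(tvm) {
  vapply(tvm@models, differentialEntropy, numeric(1))
}

#' Predictive log-likelihood of the next window
#'
#' Entry i is the mean log density of the frames of window i+1 under the
#' model of window i. Sharp drops mark transitions between sub-states.
#'
#' @param tvm a [TimeVaryingModel-class] with T >= 2 windows.
#' @param data the covariate matrix the model was fitted on.
#' @return length-(T-1) numeric vector.
#' @export
nextWindowLogLik <- function(tvm, data) {
  x <- .as_cov_values(data)
  ws <- tvm@windowSpec
  if (ws@count < 2L) stop("at least 2 windows required")
  vapply(seq_len(ws@count - 1L), function(i) {
    rows <- which(ws@assignment == i + 1L)
    mean(logDensity(tvm@models[[i]], x[rows, , drop = FALSE]))
  }, numeric(1))
}

#' Frame-by-model log-likelihood matrix
#'
#' Entry (frame, model) is the log density of that frame under that window
#' model; its block structure visualizes the sub-states visited by the
#' simulation.
#'
#' @param tvm a [TimeVaryingModel-class].
#' @param data the covariate matrix (all t frames are evaluated, including
#'   any frames dropped from the window partition).
#' @return t x T numeric matrix.
#' @export
logLikMatrix <- function(tvm, data) {
  x <- .as_cov_values(data)
  vapply(tvm@models, function(m) logDensity(m, x), numeric(nrow(x)))
}

#' Symmetric KL divergence between sequential models
#'
#' Entry i is \code{symmetricKL(model i, model i+1)}; spikes segment the
#' trajectory at sub-state boundaries.
#'
#' @param tvm a [TimeVaryingModel-class] with T >= 2 windows.
#' @return length-(T-1) numeric vector.
#' @export
sequentialKL <- function(tvm) {
  T <- tvm@windowSpec@count
  if (T < 2L) stop("at least 2 windows required")
  vapply(seq_len(T - 1L), function(i)
    symmetricKL(tvm@models[[i]], tvm@models[[i + 1L]]), numeric(1))
}

#' Segmentation diagnostics table
#'
#' Collects the per-window diagnostics into one data.frame: window index,
#' differential entropy, next-window mean log-likelihood (NA for the last
#' window) and sequential symmetric KL divergence (NA for the last
#' window).
#'
#' @param tvm a [TimeVaryingModel-class].
#' @param data the covariate matrix the model was fitted on.
#' @return data.frame with columns \code{window}, \code{entropy},
#'   \code{next_ll}, \code{seq_kl}.
#' @export
diagnosticsTable <- function(tvm, data) {
  T <- tvm@windowSpec@count
  data.frame(window = seq_len(T),
             entropy = entropySeries(tvm),
             next_ll = if (T > 1) c(nextWindowLogLik(tvm, data), NA) else NA,
             seq_kl = if (T > 1) c(sequentialKL(tvm), NA) else NA)
}
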