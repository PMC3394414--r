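#' @import methods
NULL

.symmetric <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol * max(1, max(abs(m)))
}

.is_pd <- function(m) {
  ch <- tryCatch(chol(m), error = function(e) NULL)
  !is.null(ch)
}

#' Covariate time series extracted from an MD trajectory
#'
#' A \code{CovariateMatrix} holds the universal input of all estimators in
#' this package: \code{t} frames (rows) by \code{n} covariates (columns),
#' e.g. per-residue C-alpha positional fluctuations in Angstrom. Column
#' names carry the covariate labels (typically residue identifiers); the
#' \code{frameIndex} slot keeps the original, strictly increasing frame
#' numbering of the trajectory.
#'
#' @slot values numeric matrix, frames by covariates, all entries finite.
#' @slot frameIndex numeric vector of length \code{nrow(values)}, strictly
#'   increasing frame identifiers.
#'
#' @seealso [covariateMatrix()], [learnGGM()], [learnTimeVarying()]
#' @export
setClass("CovariateMatrix",
  representation(values = "matrix", frameIndex = "numeric"))

setValidity("CovariateMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "values must be a numeric matrix")
  if (nrow(v) < 2L) msg <- c(msg, "a covariate matrix needs at least 2 frames")
  if (ncol(v) < 1L) msg <- c(msg, "a covariate matrix needs at least 1 covariate")
  if (length(v) && !all(is.finite(v))) msg <- c(msg, "all covariate values must be finite")
  if (length(object@frameIndex) != nrow(v))
    msg <- c(msg, "frameIndex length must equal the number of frames")
  if (length(object@frameIndex) > 1L && any(diff(object@frameIndex) <= 0))
    msg <- c(msg, "frameIndex must be strictly increasing")
  if (is.null(colnames(v))) msg <- c(msg, "covariates must be labelled (column names)")
  if (length(msg)) msg else TRUE
})

#' Construct a CovariateMatrix
#'
#' @param values numeric matrix (frames x covariates).
#' @param labels character vector of covariate names; defaults to existing
#'   column names or \code{V1..Vn}.
#' @param frameIndex strictly increasing frame identifiers; defaults to
#'   \code{1:t}.
#' @return A [CovariateMatrix-class] object.
#' @examples
#' d <- covariateMatrix(matrix(rnorm(20), 10, 2), labels = c("R1", "R2"))
#' nFrames(d)
#' @export
covariateMatrix <- function(values, labels = NULL, frameIndex = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(labels)) {
    labels <- colnames(values)
    if (is.null(labels)) labels <- paste0("V", seq_len(ncol(values)))
  }
  colnames(values) <- labels
  if (is.null(frameIndex)) frameIndex <- seq_len(nrow(values))
  new("CovariateMatrix", values = values, frameIndex = as.numeric(frameIndex))
}

#' Gaussian graphical model over molecular covariates
#'
#' A multivariate normal whose sparse precision matrix encodes the Markov
#' random field over covariates: a non-zero off-diagonal precision entry is
#' a direct coupling (an edge), a zero entry a conditional independence.
#' The model is parameterised by the precision matrix and the mean; the
#' covariance (inverse precision) and the natural parameter
#' \eqn{h = \Sigma^{-1}\mu} are cached for the analytic operations
#' (density, entropy, KL divergence, conditioning, sampling).
#'
#' @slot mean numeric length-n mean vector (covariate units, e.g. Angstrom).
#' @slot precision n x n symmetric positive-definite precision matrix.
#' @slot covariance n x n covariance matrix, inverse of \code{precision}.
#' @slot naturalParam numeric length-n vector, \code{precision \%*\% mean}.
#' @slot labels character covariate names.
#' @slot lambda numeric of length 0 or 1; the L1 penalty the model was
#'   fitted with, if any.
#'
#' @seealso [ggm()], [learnGGM()], [logDensity()], [conditionModel()]
#' @export
setClass("GaussianGraphicalModel",
  representation(mean = "numeric", precision = "matrix",
                 covariance = "matrix", naturalParam = "numeric",
                 labels = "character", lambda = "numeric"))

setValidity("GaussianGraphicalModel", function(object) {
  P <- object@precision; S <- object@covariance
  n <- length(object@mean)
  msg <- character()
  if (n < 1L) msg <- c(msg, "model dimension must be >= 1")
  if (!all(dim(P) == n) || !all(dim(S) == n))
    msg <- c(msg, "precision and covariance must be n x n")
  if (length(object@labels) != n) msg <- c(msg, "labels length must equal n")
  if (length(object@lambda) > 1L) msg <- c(msg, "lambda must have length 0 or 1")
  if (length(msg)) return(msg)
  if (!.symmetric(P, 1e-7)) msg <- c(msg, "precision must be symmetric")
  if (!.is_pd(P)) msg <- c(msg, "precision must be positive definite")
  if (max(abs(S %*% P - diag(n))) > 1e-3)
    msg <- c(msg, "covariance must invert precision (within tolerance)")
  if (max(abs(object@naturalParam - as.vector(P %*% object@mean))) >
      1e-6 * max(1, max(abs(object@naturalParam))))
    msg <- c(msg, "naturalParam must equal precision %*% mean")
  if (length(msg)) msg else TRUE
})

#' Construct a Gaussian graphical model
#'
#' Builds a [GaussianGraphicalModel-class] from a precision matrix (or,
#' alternatively, a covariance matrix) and a mean vector. The missing one
#' of precision/covariance is computed by Cholesky inversion; the natural
#' parameter is derived.
#'
#' @param precision symmetric positive-definite precision matrix.
#' @param mean mean vector (default zero).
#' @param covariance optionally, the covariance matrix; supply exactly one
#'   of \code{precision}/\code{covariance}, or both if consistent.
#' @param labels covariate names (default taken from dimnames or
#'   \code{V1..Vn}).
#' @param lambda optional L1 penalty to record on the model.
#' @return A [GaussianGraphicalModel-class].
#' @examples
#' m <- ggm(precision = diag(2), mean = c(0, 1))
#' differentialEntropy(m)
#' @export
ggm <- function(precision = NULL, mean = NULL, covariance = NULL,
                labels = NULL, lambda = numeric()) {
  if (is.null(precision) && is.null(covariance))
    stop("supply precision or covariance")
  .chol_pd <- function(m, what) {
    if (!.symmetric(m, 1e-7)) stop(what, " must be symmetric")
    tryCatch(chol(m), error = function(e)
      stop(what, " must be positive definite", call. = FALSE))
  }
  if (is.null(precision)) {
    covariance <- .as_sym_matrix(covariance)
    precision <- chol2inv(.chol_pd(covariance, "covariance"))
  } else {
    if (!.symmetric(as.matrix(precision), 1e-7))
      stop("precision must be symmetric")
    precision <- .as_sym_matrix(precision)
    if (is.null(covariance))
      covariance <- chol2inv(.chol_pd(precision, "precision"))
    else covariance <- .as_sym_matrix(covariance)
  }
  n <- nrow(precision)
  if (is.null(mean)) mean <- numeric(n)
  if (is.null(labels)) {
    labels <- colnames(precision)
    if (is.null(labels)) labels <- paste0("V", seq_len(n))
  }
  dimnames(precision) <- dimnames(covariance) <- list(labels, labels)
  new("GaussianGraphicalModel", mean = as.numeric(mean),
      precision = precision, covariance = covariance,
      naturalParam = as.vector(precision %*% as.numeric(mean)),
      labels = as.character(labels), lambda = as.numeric(lambda))
}

.as_sym_matrix <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  (m + t(m)) / 2
}

#' Window layout of a trajectory
#'
#' Non-overlapping, contiguous, ordered windows of equal width covering the
#' first \code{count * width} frames of a trajectory; a trailing partial
#' window is dropped.
#'
#' @slot width integer window width in frames (>= 2).
#' @slot count integer number of windows T.
#' @slot assignment integer vector over frames mapping each frame to its
#'   window (NA for dropped trailing frames).
#' @seealso [partitionWindows()]
#' @export
setClass("WindowSpec",
  representation(width = "integer", count = "integer", assignment = "integer"))

setValidity("WindowSpec", function(object) {
  msg <- character()
  if (object@width < 2L) msg <- c(msg, "window width must be >= 2 frames")
  if (object@count < 1L) msg <- c(msg, "at least one window required")
  used <- object@assignment[!is.na(object@assignment)]
  if (length(used) != object@width * object@count)
    msg <- c(msg, "assignment must cover count*width frames")
  if (length(used) && (any(diff(used) < 0) || !all(tabulate(used, object@count) == object@width)))
    msg <- c(msg, "windows must be contiguous, ordered, equal width")
  if (length(msg)) msg else TRUE
})

#' Smoothing kernel over neighbouring windows
#'
#' Non-negative weights attached to window offsets \code{-kappa..kappa};
#' the weighted covariance of window \code{tau} mixes the per-window
#' covariances of windows \code{tau + offset}. Offsets falling outside the
#' trajectory are dropped and the remaining weights renormalized.
#'
#' @slot offsets integer window offsets (relative to the current window).
#' @slot weights numeric non-negative weights, one per offset.
#' @seealso [sawtoothKernel()], [weightedCovariance()]
#' @export
setClass("KernelSpec",
  representation(offsets = "integer", weights = "numeric"))

setValidity("KernelSpec", function(object) {
  msg <- character()
  if (length(object@offsets) != length(object@weights))
    msg <- c(msg, "offsets and weights must have equal length")
  if (anyDuplicated(object@offsets)) msg <- c(msg, "offsets must be unique")
  if (!all(is.finite(object@weights)) || any(object@weights < 0))
    msg <- c(msg, "weights must be finite and non-negative")
  if (!any(object@weights > 0)) msg <- c(msg, "at least one positive weight required")
  if (length(msg)) msg else TRUE
})

#' @describeIn KernelSpec-class construct a kernel from offsets and weights.
#' @param offsets integer window offsets.
#' @param weights non-negative weights, one per offset.
#' @export
kernelSpec <- function(offsets, weights) {
  new("KernelSpec", offsets = as.integer(offsets), weights = as.numeric(weights))
}

#' Time-varying Gaussian graphical model
#'
#' An ordered sequence of [GaussianGraphicalModel-class] objects, one per
#' trajectory window, fitted with a shared L1 penalty and a smoothing
#' kernel so parameters evolve smoothly along the trajectory.
#'
#' @slot models list of T GaussianGraphicalModel objects in window order.
#' @slot windowSpec the [WindowSpec-class] used.
#' @slot kernelSpec the [KernelSpec-class] used.
#' @slot lambda the shared L1 penalty.
#' @seealso [learnTimeVarying()], [entropySeries()], [sequentialKL()]
#' @export
setClass("TimeVaryingModel",
  representation(models = "list", windowSpec = "WindowSpec",
                 kernelSpec = "KernelSpec", lambda = "numeric"))

setValidity("TimeVaryingModel", function(object) {
  msg <- character()
  if (length(object@models) != object@windowSpec@count)
    msg <- c(msg, "one model per window required")
  if (!all(vapply(object@models, is, logical(1), "GaussianGraphicalModel")))
    msg <- c(msg, "models must be GaussianGraphicalModel objects")
  if (length(msg)) msg else TRUE
})

#' Markov chain over conformational sub-states
#'
#' Clusters of window models act as states; the chain carries a prior over
#' states, a row-stochastic transition matrix estimated by counting
#' consecutive window-cluster transitions, and one representative Gaussian
#' graphical model per state from which conformations are generated.
#'
#' @slot prior length-k probability vector (cluster relative sizes).
#' @slot transition k x k row-stochastic transition matrix.
#' @slot stateModels list of k representative GaussianGraphicalModel objects.
#' @slot framesPerState integer; frames emitted per visited state (the
#'   window width of the underlying time-varying model).
#' @seealso [estimateChain()], [sampleChainTrajectory()]
#' @export
setClass("MarkovChainModel",
  representation(prior = "numeric", transition = "matrix",
                 stateModels = "list", framesPerState = "integer"))

setValidity("MarkovChainModel", function(object) {
  k <- length(object@prior)
  msg <- character()
  if (!all(dim(object@transition) == k))
    msg <- c(msg, "transition must be k x k")
  if (length(object@stateModels) != k)
    msg <- c(msg, "one representative model per state required")
  if (any(object@prior < 0) || abs(sum(object@prior) - 1) > 1e-8)
    msg <- c(msg, "prior must be a probability vector")
  if (any(object@transition < 0) ||
      max(abs(rowSums(object@transition) - 1)) > 1e-8)
    msg <- c(msg, "transition rows must be stochastic")
  if (object@framesPerState < 1L) msg <- c(msg, "framesPerState must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Atomic coordinate trajectory
#'
#' Minimal container for the coordinates of selected atoms across frames,
#' in the flat xyz layout used by bio3d: one row per frame, columns
#' \code{(x1, y1, z1, x2, ...)} in Angstrom.
#'
#' @slot xyz numeric matrix, frames x (3 * atoms).
#' @slot atomLabels character, one label per atom (e.g. residue numbers).
#' @seealso [readTrajectory()], [extractFluctuations()]
#' @export
setClass("CoordinateTrajectory",
  representation(xyz = "matrix", atomLabels = "character"))

setValidity("CoordinateTrajectory", function(object) {
  msg <- character()
  if (ncol(object@xyz) %% 3L != 0L) msg <- c(msg, "xyz must have 3 columns per atom")
  if (length(object@atomLabels) != ncol(object@xyz) / 3L)
    msg <- c(msg, "one label per atom required")
  if (length(object@xyz) && !all(is.finite(object@xyz)))
    msg <- c(msg, "coordinates must be finite")
  if (length(msg)) msg else TRUE
})

#' @describeIn CoordinateTrajectory-class construct from an xyz matrix.
#' @param xyz frames x (3*atoms) coordinate matrix.
#' @param atomLabels one label per atom.
#' @export
coordinateTrajectory <- function(xyz, atomLabels = NULL) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (is.null(atomLabels)) atomLabels <- as.character(seq_len(ncol(xyz) / 3L))
  new("CoordinateTrajectory", xyz = xyz, atomLabels = as.character(atomLabels))
}
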