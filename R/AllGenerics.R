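#' @include AllClasses.R
NULL

#' Number of frames / covariates
#'
#' @param x a [CovariateMatrix-class] or [CoordinateTrajectory-class].
#' @return integer.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nFrames
#' @export
setGeneric("nCovariates", function(x) standardGeneric("nCovariates"))

#' Covariate labels
#' @param x an object carrying covariate names.
#' @return character vector.
#' @export
setGeneric("covariateLabels", function(x) standardGeneric("covariateLabels"))

#' Raw covariate values
#' @param x a [CovariateMatrix-class].
#' @return numeric matrix, frames x covariates.
#' @export
setGeneric("covValues", function(x) standardGeneric("covValues"))

#' Frame identifiers
#' @param x a [CovariateMatrix-class].
#' @return numeric vector.
#' @export
setGeneric("frameIndex", function(x) standardGeneric("frameIndex"))

#' Model parameter accessors
#'
#' Accessors for the slots of a [GaussianGraphicalModel-class]: the mean
#' vector, the (sparse) precision matrix, its inverse the covariance
#' matrix, the natural parameter \eqn{h = \Sigma^{-1}\mu}, and the L1
#' penalty the model was fitted with (numeric(0) if none).
#'
#' @param object a [GaussianGraphicalModel-class].
#' @return the requested parameter.
#' @name ggm-accessors
NULL

#' @rdname ggm-accessors
#' @export
setGeneric("modelMean", function(object) standardGeneric("modelMean"))

#' @rdname ggm-accessors
#' @export
setGeneric("precisionMatrix", function(object) standardGeneric("precisionMatrix"))

#' @rdname ggm-accessors
#' @export
setGeneric("covarianceMatrix", function(object) standardGeneric("covarianceMatrix"))

#' @rdname ggm-accessors
#' @export
setGeneric("naturalParam", function(object) standardGeneric("naturalParam"))

#' @rdname ggm-accessors
#' @export
setGeneric("modelLambda", function(object) standardGeneric("modelLambda"))

#' @rdname ggm-accessors
#' @export
setGeneric("modelDim", function(object) standardGeneric("modelDim"))

#' Models of a time-varying fit
#' @param object a [TimeVaryingModel-class].
#' @return list of [GaussianGraphicalModel-class] objects in window order.
#' @export
setGeneric("windowModels", function(object) standardGeneric("windowModels"))

#' Markov chain accessors
#' @param object a [MarkovChainModel-class].
#' @name chain-accessors
NULL

#' @rdname chain-accessors
#' @export
setGeneric("chainPrior", function(object) standardGeneric("chainPrior"))

#' @rdname chain-accessors
#' @export
setGeneric("transitionMatrix", function(object) standardGeneric("transitionMatrix"))

#' @rdname chain-accessors
#' @export
setGeneric("stateModels", function(object) standardGeneric("stateModels"))

## ---- methods -------------------------------------------------------------

#' @rdname nFrames
setMethod("nFrames", "CovariateMatrix", function(x) nrow(x@values))
#' @rdname nFrames
setMethod("nFrames", "CoordinateTrajectory", function(x) nrow(x@xyz))
#' @rdname nFrames
setMethod("nCovariates", "CovariateMatrix", function(x) ncol(x@values))

#' @rdname covariateLabels
setMethod("covariateLabels", "CovariateMatrix", function(x) colnames(x@values))
#' @rdname covariateLabels
setMethod("covariateLabels", "GaussianGraphicalModel", function(x) x@labels)

#' @rdname covValues
setMethod("covValues", "CovariateMatrix", function(x) x@values)
#' @rdname frameIndex
setMethod("frameIndex", "CovariateMatrix", function(x) x@frameIndex)

setMethod("dim", "CovariateMatrix", function(x) dim(x@values))

#' @rdname ggm-accessors
setMethod("modelMean", "GaussianGraphicalModel", function(object) object@mean)
#' @rdname ggm-accessors
setMethod("precisionMatrix", "GaussianGraphicalModel", function(object) object@precision)
#' @rdname ggm-accessors
setMethod("covarianceMatrix", "GaussianGraphicalModel", function(object) object@covariance)
#' @rdname ggm-accessors
setMethod("naturalParam", "GaussianGraphicalModel", function(object) object@naturalParam)
#' @rdname ggm-accessors
setMethod("modelLambda", "GaussianGraphicalModel", function(object) object@lambda)
#' @rdname ggm-accessors
setMethod("modelDim", "GaussianGraphicalModel", function(object) length(object@mean))

#' @rdname windowModels
setMethod("windowModels", "TimeVaryingModel", function(object) object@models)

#' @rdname chain-accessors
setMethod("chainPrior", "MarkovChainModel", function(object) object@prior)
#' @rdname chain-accessors
setMethod("transitionMatrix", "MarkovChainModel", function(object) object@transition)
#' @rdname chain-accessors
setMethod("stateModels", "MarkovChainModel", function(object) object@stateModels)

setMethod("show", "CovariateMatrix", function(object) {
  cat(sprintf("CovariateMatrix: %d frames x %d covariates\n",
              nrow(object@values), ncol(object@values)))
  lab <- colnames(object@values)
  cat("  covariates:", paste(utils::head(lab, 6), collapse = ", "),
      if (length(lab) > 6) "..." else "", "\n")
})

setMethod("show", "GaussianGraphicalModel", function(object) {
  n <- length(object@mean)
  ne <- sum(abs(object@precision[upper.tri(object@precision)]) > 1e-8)
  cat(sprintf("GaussianGraphicalModel: n = %d covariates, %d edges (|prec| > 1e-8)\n",
              n, ne))
  if (length(object@lambda))
    cat(sprintf("  fitted with lambda = %g\n", object@lambda))
  cat(sprintf("  differential entropy: %.4f nats\n", differentialEntropy(object)))
})

setMethod("show", "TimeVaryingModel", function(object) {
  cat(sprintf("TimeVaryingModel: %d windows of %d frames, lambda = %g\n",
              object@windowSpec@count, object@windowSpec@width, object@lambda))
})

setMethod("show", "MarkovChainModel", function(object) {
  cat(sprintf("MarkovChainModel: %d states, %d frames per state\n",
              length(object@prior), object@framesPerState))
  cat("  prior:", paste(sprintf("%.3f", object@prior), collapse = " "), "\n")
})

setMethod("show", "CoordinateTrajectory", function(object) {
  cat(sprintf("CoordinateTrajectory: %d frames x %d atoms\n",
              nrow(object@xyz), ncol(object@xyz) / 3L))
})
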