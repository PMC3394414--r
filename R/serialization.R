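#' @include model-core.R
NULL

.pkg_version <- function() as.character(utils::packageVersion("mdggm"))

#' Write / read a model as JSON
#'
#' A model is stored as a single JSON document with fields \code{labels},
#' \code{mean}, \code{precision} (dense, row-major), \code{lambda} and
#' \code{meta}; the covariance is recomputed on load, not stored. Output
#' key order is fixed, so identical models serialize to identical bytes.
#'
#' @param model a [GaussianGraphicalModel-class].
#' @param path output / input file path.
#' @return \code{writeGGM} invisibly returns \code{path}; \code{readGGM}
#'   returns the model.
#' @export
writeGGM <- function(model, path) {
  n <- length(model@mean)
  doc <- list(
    labels = model@labels,
    mean = model@mean,
    precision = as.vector(t(model@precision)),   # row-major
    lambda = if (length(model@lambda)) model@lambda else NULL,
    meta = list(n = n, generator = "mdggm", version = .pkg_version()))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = FALSE)
  invisible(path)
}

#' @rdname writeGGM
#' @export
readGGM <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- length(doc$mean)
  P <- matrix(doc$precision, n, n, byrow = TRUE)
  ggm(precision = P, mean = doc$mean, labels = doc$labels,
      lambda = if (is.null(doc$lambda)) numeric() else doc$lambda)
}

#' Write an edge list as CSV
#'
#' Columns \code{i_label}, \code{j_label}, \code{weight} (the precision
#' entry of each edge).
#'
#' @param edges an edge-list data.frame from [edgeList()] or
#'   [thresholdBaseline()].
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeEdges <- function(edges, path) {
  utils::write.csv(edges[, c("i_label", "j_label", "weight")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a time-varying model
#'
#' One JSON model file per window (\code{window_0001.json}, ...) plus an
#' index manifest \code{manifest.json} recording the window layout, the
#' kernel and the shared penalty.
#'
#' @param tvm a [TimeVaryingModel-class].
#' @param dir output directory (created if needed).
#' @return \code{writeTimeVaryingModel} invisibly returns the manifest
#'   path; \code{readTimeVaryingModel} returns the model.
#' @export
writeTimeVaryingModel <- function(tvm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  T <- tvm@windowSpec@count
  files <- sprintf("window_%04d.json", seq_len(T))
  for (i in seq_len(T)) writeGGM(tvm@models[[i]], file.path(dir, files[i]))
  manifest <- list(
    models = files,
    window = list(width = tvm@windowSpec@width, count = T,
                  assignment = tvm@windowSpec@assignment),
    kernel = list(offsets = tvm@kernelSpec@offsets,
                  weights = tvm@kernelSpec@weights),
    lambda = tvm@lambda,
    meta = list(generator = "mdggm", version = .pkg_version()))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname writeTimeVaryingModel
#' @param manifest path to a \code{manifest.json}.
#' @export
readTimeVaryingModel <- function(manifest) {
  doc <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  dir <- dirname(manifest)
  models <- lapply(doc$models, function(f) readGGM(file.path(dir, f)))
  ws <- new("WindowSpec", width = as.integer(doc$window$width),
            count = as.integer(doc$window$count),
            assignment = as.integer(doc$window$assignment))
  ks <- kernelSpec(doc$kernel$offsets, doc$kernel$weights)
  new("TimeVaryingModel", models = models, windowSpec = ws,
      kernelSpec = ks, lambda = as.numeric(doc$lambda))
}

#' Write / read a Markov chain of models
#'
#' A JSON document with the prior, the row-major transition matrix, the
#' frames-per-state window width and one model file per state (written
#' next to the chain file as \code{state_<i>.json}).
#'
#' @param chain a [MarkovChainModel-class].
#' @param path output JSON file; state model files are written to the same
#'   directory.
#' @return \code{writeChain} invisibly returns \code{path};
#'   \code{readChain} returns the chain.
#' @export
writeChain <- function(chain, path) {
  dir <- dirname(path)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  k <- length(chain@prior)
  files <- sprintf("state_%02d.json", seq_len(k))
  for (i in seq_len(k)) writeGGM(chain@stateModels[[i]], file.path(dir, files[i]))
  doc <- list(prior = chain@prior,
              transition = as.vector(t(chain@transition)),
              k = k,
              frames_per_state = chain@framesPerState,
              state_models = files,
              labels = chain@stateModels[[1]]@labels,
              meta = list(generator = "mdggm", version = .pkg_version()))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeChain
#' @export
readChain <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  k <- doc$k
  dir <- dirname(path)
  models <- lapply(doc$state_models, function(f) readGGM(file.path(dir, f)))
  new("MarkovChainModel", prior = doc$prior,
      transition = matrix(doc$transition, k, k, byrow = TRUE),
      stateModels = models,
      framesPerState = as.integer(doc$frames_per_state))
}
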