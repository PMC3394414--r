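#' @include kinetics.R
NULL

#' Read an MD trajectory's selected-atom coordinates
#'
#' Thin adapter over the bio3d readers: parses a topology/reference PDB,
#' selects atoms (default: C-alpha), and reads coordinates either from the
#' PDB itself (multi-MODEL files) or from a separate DCD or NetCDF
#' trajectory file. The rest of the package never touches format
#' internals; covariates are extracted from the returned
#' [CoordinateTrajectory-class] with [extractFluctuations()].
#'
#' @param topology path to a PDB file (topology and, for multi-MODEL
#'   files, coordinates).
#' @param trajectory optional path to a DCD (.dcd) or NetCDF (.nc/.ncdf)
#'   coordinate file; if NULL, frames are taken from the PDB MODELs.
#' @param selection bio3d atom-selection string (default "calpha").
#' @return a [CoordinateTrajectory-class]; atom labels are residue numbers
#'   from the topology (1-based, as in the PDB).
#' @export
readTrajectory <- function(topology, trajectory = NULL, selection = "calpha") {
  if (!file.exists(topology)) stop("topology file not found: ", topology)
  pdb <- bio3d::read.pdb(topology, multi = TRUE)
  sel <- bio3d::atom.select(pdb, selection, verbose = FALSE)
  if (length(sel$atom) == 0) stop("atom selection '", selection,
                                  "' matched no atoms")
  if (is.null(trajectory)) {
    xyz <- pdb$xyz[, sel$xyz, drop = FALSE]
  } else {
    if (!file.exists(trajectory)) stop("trajectory file not found: ", trajectory)
    ext <- tolower(tools::file_ext(trajectory))
    xyz <- switch(ext,
      dcd = bio3d::read.dcd(trajectory, verbose = FALSE),
      nc = ,
      ncdf = bio3d::read.ncdf(trajectory),
      stop("unsupported trajectory format '.", ext,
           "'; supported: PDB (multi-MODEL), DCD, NetCDF"))
    if (ncol(xyz) < max(sel$xyz))
      stop("trajectory atom count does not match the topology")
    xyz <- xyz[, sel$xyz, drop = FALSE]
  }
  labels <- as.character(pdb$atom$resno[sel$atom])
  coordinateTrajectory(as.matrix(xyz), atomLabels = labels)
}

## Rigid-body least-squares superposition (Kabsch) of every frame onto the
## reference, delegated to bio3d::fit.xyz.
.superpose <- function(xyz, ref) {
  bio3d::fit.xyz(fixed = ref, mobile = xyz,
                 fixed.inds = seq_along(ref), mobile.inds = seq_along(ref))
}

#' Extract positional-fluctuation covariates
#'
#' Converts a coordinate trajectory into the covariate matrix the
#' estimators consume: per frame, optionally superpose rigidly
#' (least-squares rotation + translation) onto the reference, then take
#' each atom's deviation from its reference position. With
#' \code{mode = "magnitude"} the covariates are the per-atom Euclidean
#' displacements (n = m variables, Angstrom); with \code{mode = "xyz"}
#' they are the signed x/y/z deviations (n = 3m).
#'
#' @param traj a [CoordinateTrajectory-class].
#' @param reference \code{"first_frame"} (default) or \code{"supplied"}.
#' @param refXYZ length-3m reference coordinates, required when
#'   \code{reference = "supplied"}.
#' @param superpose remove rigid-body motion before measuring deviations
#'   (default TRUE; without it global tumbling dominates the
#'   fluctuations).
#' @param mode \code{"magnitude"} (default) or \code{"xyz"}.
#' @return a [CovariateMatrix-class]; magnitude-mode labels are the atom
#'   labels, xyz-mode labels are \code{<atom>_x/_y/_z}.
#' @export
extractFluctuations <- function(traj, reference = c("first_frame", "supplied"),
                                refXYZ = NULL, superpose = TRUE,
                                mode = c("magnitude", "xyz")) {
  reference <- match.arg(reference)
  mode <- match.arg(mode)
  xyz <- traj@xyz
  if (nrow(xyz) < 2L) stop("at least 2 frames required")
  ref <- if (reference == "first_frame") xyz[1, ] else {
    if (is.null(refXYZ)) stop("reference = 'supplied' requires refXYZ")
    as.numeric(refXYZ)
  }
  if (length(ref) != ncol(xyz))
    stop("reference atom count does not match the trajectory")
  if (superpose) xyz <- .superpose(xyz, ref)
  dev <- sweep(xyz, 2, ref)
  m <- ncol(xyz) / 3L
  if (mode == "magnitude") {
    mag <- vapply(seq_len(m), function(a) {
      cols <- (3 * (a - 1) + 1):(3 * a)
      sqrt(rowSums(dev[, cols, drop = FALSE]^2))
    }, numeric(nrow(dev)))
    covariateMatrix(mag, labels = traj@atomLabels)
  } else {
    labels <- as.vector(t(outer(traj@atomLabels, c("x", "y", "z"),
                                paste, sep = "_")))
    covariateMatrix(dev, labels = labels)
  }
}

#' Read a covariate matrix from delimited text
#'
#' Expects a header row of covariate labels and one row per frame;
#' an optional first column named \code{frame} (case-insensitive) carries
#' frame identifiers. Comma and tab separators are auto-detected from the
#' file extension (.csv vs .tsv/.txt) unless \code{sep} is given. Ragged
#' rows and non-numeric cells are reported with their line number.
#'
#' @param path input file.
#' @param sep field separator; default by extension.
#' @return a [CovariateMatrix-class].
#' @export
loadCovariates <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  nf <- utils::count.fields(path, sep = sep, blank.lines.skip = FALSE)
  if (length(nf) == 0) stop("parse error: ", path, " is empty")
  if (any(bad <- nf != nf[1]))
    stop("parse error at line ", which(bad)[1], ": expected ", nf[1],
         " fields, found ", nf[which(bad)[1]])
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, colClasses = "character")
  if (nrow(df) == 0) stop("parse error: no frames (header-only file)")
  frameIndex <- NULL
  if (tolower(names(df)[1]) %in% c("frame", "frame_id", "frame_index")) {
    frameIndex <- as.numeric(df[[1]])
    df <- df[, -1, drop = FALSE]
  }
  vals <- suppressWarnings(
    vapply(df, as.numeric, numeric(nrow(df))))
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = nrow(df),
                                       dimnames = list(NULL, names(df)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop("parse error at line ", bad[1] + 1L, ": non-numeric value '",
         df[bad[1], bad[2]], "' in column '", names(df)[bad[2]], "'")
  }
  covariateMatrix(vals, labels = names(df), frameIndex = frameIndex)
}

#' Write a covariate matrix as delimited text
#'
#' Round-trip-lossless writer: values are serialized with 17 significant
#' digits, so [loadCovariates()] restores them bit for bit. The first
#' column is the frame index.
#'
#' @param data a [CovariateMatrix-class].
#' @param path output file; extension .csv selects comma, anything else
#'   tab, unless \code{sep} is given.
#' @param sep field separator; default by extension.
#' @return invisibly, \code{path}.
#' @export
writeCovariates <- function(data, path, sep = NULL) {
  if (is.null(sep))
    sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  x <- covValues(data)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("frame", colnames(x)), collapse = sep), con)
  body <- cbind(sprintf("%.17g", frameIndex(data)),
                matrix(sprintf("%.17g", x), nrow(x), ncol(x)))
  writeLines(apply(body, 1, paste, collapse = sep), con)
  invisible(path)
}
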