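#' @import methods
#' @importFrom stats median mad rnorm rpois runif sd t.test setNames quantile pnorm ave
#' @importFrom utils write.table read.delim head
#' @useDynLib foci3d, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

setClassUnion("arrayOrNULL", c("array", "NULL"))

#' Ellipsoidal nucleus geometry
#'
#' Describes the voxel grid and the ellipsoid used to build a synthetic
#' nuclear mask: grid dimensions in (z, y, x) order, voxel size in micrometres
#' (dz, dy, dx), ellipsoid semi-axes and centre in physical coordinates.
#' The default voxel size (0.13, 0.06, 0.06) um corresponds to standard
#' high-resolution confocal sampling (60 nm pixels, 130 nm z-step).
#'
#' @slot dim integer(3), grid dimensions (z, y, x).
#' @slot voxelSize numeric(3), voxel extents (dz, dy, dx) in um.
#' @slot semiAxes numeric(3), ellipsoid semi-axes (z, y, x) in um.
#' @slot center numeric(3), ellipsoid centre (z, y, x) in um.
#' @exportClass NucleusGeometry
setClass("NucleusGeometry",
  representation(dim = "integer", voxelSize = "numeric",
                 semiAxes = "numeric", center = "numeric"))

setValidity("NucleusGeometry", function(object) {
  msg <- character()
  if (length(object@dim) != 3L || any(object@dim < 1L))
    msg <- c(msg, "dim must be three positive integers (z, y, x)")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three strictly positive values (um)")
  if (length(object@semiAxes) != 3L || any(object@semiAxes <= 0))
    msg <- c(msg, "semiAxes must be three strictly positive values (um)")
  if (length(object@center) != 3L)
    msg <- c(msg, "center must have three coordinates (um)")
  if (!length(msg)) {
    extent <- object@dim * object@voxelSize
    if (any(object@center - object@semiAxes < 0) ||
        any(object@center + object@semiAxes > extent))
      msg <- c(msg, "ellipsoid exceeds the voxel grid")
  }
  if (length(msg)) msg else TRUE
})

#' Nuclear mask
#'
#' A calibrated boolean 3D region marking the nucleus interior; the spatial
#' domain for focus detection and for all spatial statistics.
#'
#' @slot mask logical 3D array in (z, y, x) order.
#' @slot voxelSize numeric(3), voxel extents (dz, dy, dx) in um.
#' @exportClass NuclearMask
setClass("NuclearMask",
  representation(mask = "array", voxelSize = "numeric"))

setValidity("NuclearMask", function(object) {
  msg <- character()
  if (!is.logical(object@mask) || length(dim(object@mask)) != 3L)
    msg <- c(msg, "mask must be a logical 3D array")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three strictly positive values (um)")
  if (length(msg)) msg else TRUE
})

#' Calibrated single-channel intensity stack
#'
#' One channel of one nucleus: a 3D integer-valued intensity array (arbitrary
#' units on the acquisition bit depth) with its physical voxel calibration.
#'
#' @slot values numeric 3D array in (z, y, x) order.
#' @slot voxelSize numeric(3), voxel extents (dz, dy, dx) in um.
#' @slot channel character(1) channel label.
#' @slot bitDepth integer(1), 8 or 16.
#' @exportClass VoxelGrid
setClass("VoxelGrid",
  representation(values = "array", voxelSize = "numeric",
                 channel = "character", bitDepth = "integer"))

setValidity("VoxelGrid", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3D array")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three strictly positive values (um)")
  if (!object@bitDepth %in% c(8L, 16L))
    msg <- c(msg, "bitDepth must be 8 or 16")
  if (!length(msg) && any(object@values < 0 | object@values > 2^object@bitDepth - 1))
    msg <- c(msg, "values outside the bit-depth range")
  if (length(msg)) msg else TRUE
})

setClassUnion("NuclearMaskOrNULL", c("NuclearMask", "NULL"))

.TREATMENTS <- c("untreated", "CPT", "ETP", "MTX")
.SUBSTAGES  <- c("nonreplicating", "S-I", "S-II", "S-III", "S-IV", "S-V")
.CHANNELS   <- c("53BP1", "gammaH2AX", "EdU")

#' One imaged nucleus with its metadata
#'
#' Bundles the three channel stacks (53BP1, gammaH2AX, EdU) of one nucleus,
#' optional raw (pre-deconvolution) counterparts used for intensity
#' measurement, the nuclear mask, and the experimental labels: treatment
#' (untreated or a topoisomerase inhibitor) and S-phase substage as assessed
#' from the replication labeling pattern.
#'
#' @slot id character(1) nucleus identifier.
#' @slot treatment one of untreated, CPT, ETP, MTX.
#' @slot substage one of nonreplicating, S-I..S-V.
#' @slot channels named list of \linkS4class{VoxelGrid} (analysis grids).
#' @slot raw named list of \linkS4class{VoxelGrid} (raw grids; may be empty,
#'   in which case the analysis grids double as raw).
#' @slot mask \linkS4class{NuclearMask} or NULL.
#' @exportClass NucleusRecord
setClass("NucleusRecord",
  representation(id = "character", treatment = "character",
                 substage = "character", channels = "list",
                 raw = "list", mask = "NuclearMaskOrNULL"))

setValidity("NucleusRecord", function(object) {
  msg <- character()
  if (!object@treatment %in% .TREATMENTS)
    msg <- c(msg, paste("treatment must be one of:",
                        paste(.TREATMENTS, collapse = ", ")))
  if (!object@substage %in% .SUBSTAGES)
    msg <- c(msg, paste("substage must be one of:",
                        paste(.SUBSTAGES, collapse = ", ")))
  if (!all(vapply(object@channels, is, TRUE, "VoxelGrid")))
    msg <- c(msg, "channels must be a list of VoxelGrid")
  dims <- lapply(object@channels, function(g) dim(g@values))
  if (length(dims) > 1L &&
      !all(vapply(dims, identical, TRUE, dims[[1L]])))
    msg <- c(msg, "all channels must share one grid shape")
  if (!is.null(object@mask) && length(dims) &&
      !identical(dim(object@mask@mask), dims[[1L]]))
    msg <- c(msg, "mask shape must equal the grid shape")
  if (length(msg)) msg else TRUE
})

#' Detected intensity peaks of one channel
#'
#' Peak voxel coordinates (z, y, x; 1-based) and physical centres (um) of the
#' local maxima retained by the orthogonal-section conjunction search,
#' together with the prominence used.
#'
#' @slot coords integer matrix, one row per peak, columns z, y, x (voxels).
#' @slot centers numeric matrix, columns z, y, x (um).
#' @slot values numeric vector of peak intensities.
#' @slot prominence numeric(1) prominence (noise tolerance) used.
#' @slot channel character(1).
#' @exportClass PeakSet
setClass("PeakSet",
  representation(coords = "matrix", centers = "matrix", values = "numeric",
                 prominence = "numeric", channel = "character"))

setValidity("PeakSet", function(object) {
  msg <- character()
  if (ncol(object@coords) != 3L || ncol(object@centers) != 3L)
    msg <- c(msg, "coords and centers must have columns z, y, x")
  if (nrow(object@coords) != nrow(object@centers) ||
      nrow(object@coords) != length(object@values))
    msg <- c(msg, "coords, centers and values must agree in length")
  if (anyDuplicated(object@coords))
    msg <- c(msg, "peak coordinates must be pairwise distinct")
  if (length(msg)) msg else TRUE
})

#' Normalized Ripley L-function of one nucleus
#'
#' L(r) = observed pair count / CSR-expected pair count - 1 on a distance
#' grid, for one channel pair (auto-correlation when source and target
#' coincide). L = 0 is random association; L = 1 means twice as many pairs
#' as expected at random. Values are NA where the CSR reference is zero.
#'
#' @slot r numeric distance grid (um).
#' @slot L numeric, same length as r.
#' @slot nSource,nTarget integer point counts.
#' @slot pair character(2): source and target labels.
#' @slot nucleus character(1) nucleus identifier.
#' @exportClass LCurve
setClass("LCurve",
  representation(r = "numeric", L = "numeric", nSource = "integer",
                 nTarget = "integer", pair = "character",
                 nucleus = "character"))

setValidity("LCurve", function(object) {
  msg <- character()
  if (length(object@r) != length(object@L))
    msg <- c(msg, "r and L must have the same length")
  if (is.unsorted(object@r, strictly = TRUE))
    msg <- c(msg, "r must be strictly increasing")
  if (any(object@L < -1, na.rm = TRUE))
    msg <- c(msg, "L cannot fall below -1")
  if (length(msg)) msg else TRUE
})
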