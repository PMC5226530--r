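#' Accessors for foci3d classes
#'
#' Small accessor generics: \code{voxelSize} returns the physical voxel
#' extents (dz, dy, dx) in um; \code{maskArray} the logical 3D array of a
#' \linkS4class{NuclearMask}; \code{maskVolume} its physical volume in um^3;
#' \code{intensities} the 3D intensity array of a \linkS4class{VoxelGrid};
#' \code{channelName} its channel label; \code{peakCoords} /
#' \code{peakCenters} the voxel / physical peak coordinates of a
#' \linkS4class{PeakSet} and \code{nPeaks} their number; \code{lValues} and
#' \code{rGrid} the components of an \linkS4class{LCurve}.
#'
#' @param x an object of the documented class.
#' @return See the description per accessor.
#' @name accessors
#' @aliases voxelSize maskArray maskVolume intensities channelName
#'   peakCoords peakCenters nPeaks lValues rGrid
NULL

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' @rdname accessors
#' @export
setGeneric("maskVolume", function(x) standardGeneric("maskVolume"))

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setGeneric("channelName", function(x) standardGeneric("channelName"))

#' @rdname accessors
#' @export
setGeneric("peakCoords", function(x) standardGeneric("peakCoords"))

#' @rdname accessors
#' @export
setGeneric("peakCenters", function(x) standardGeneric("peakCenters"))

#' @rdname accessors
#' @export
setGeneric("nPeaks", function(x) standardGeneric("nPeaks"))

#' @rdname accessors
#' @export
setGeneric("lValues", function(x) standardGeneric("lValues"))

#' @rdname accessors
#' @export
setGeneric("rGrid", function(x) standardGeneric("rGrid"))

#' @rdname accessors
setMethod("voxelSize", "NuclearMask", function(x) x@voxelSize)
#' @rdname accessors
setMethod("voxelSize", "VoxelGrid", function(x) x@voxelSize)
#' @rdname accessors
setMethod("voxelSize", "NucleusGeometry", function(x) x@voxelSize)
#' @rdname accessors
setMethod("maskArray", "NuclearMask", function(x) x@mask)
#' @rdname accessors
setMethod("maskVolume", "NuclearMask",
          function(x) sum(x@mask) * prod(x@voxelSize))
#' @rdname accessors
setMethod("intensities", "VoxelGrid", function(x) x@values)
#' @rdname accessors
setMethod("channelName", "VoxelGrid", function(x) x@channel)
#' @rdname accessors
setMethod("peakCoords", "PeakSet", function(x) x@coords)
#' @rdname accessors
setMethod("peakCenters", "PeakSet", function(x) x@centers)
#' @rdname accessors
setMethod("nPeaks", "PeakSet", function(x) nrow(x@coords))
#' @rdname accessors
setMethod("lValues", "LCurve", function(x) x@L)
#' @rdname accessors
setMethod("rGrid", "LCurve", function(x) x@r)

setMethod("show", "NucleusGeometry", function(object) {
  cat("NucleusGeometry:", paste(object@dim, collapse = " x "),
      "voxels (z y x) at", paste(object@voxelSize, collapse = " x "),
      "um\n  semi-axes", paste(object@semiAxes, collapse = ", "),
      "um; centre", paste(round(object@center, 2), collapse = ", "), "um\n")
})

setMethod("show", "NuclearMask", function(object) {
  cat("NuclearMask:", paste(dim(object@mask), collapse = " x "),
      "voxels;", sum(object@mask), "in mask (",
      sprintf("%.1f", maskVolume(object)), "um^3 )\n")
})

setMethod("show", "VoxelGrid", function(object) {
  cat("VoxelGrid [", object@channel, "]: ",
      paste(dim(object@values), collapse = " x "), " voxels, ",
      object@bitDepth, "-bit, range ", min(object@values), "-",
      max(object@values), "\n", sep = "")
})

setMethod("show", "NucleusRecord", function(object) {
  cat("NucleusRecord", object@id, "-", object@treatment, "/",
      object@substage, "\n  channels:",
      paste(names(object@channels), collapse = ", "),
      if (is.null(object@mask)) "\n  mask: none" else "\n  mask: present",
      "\n")
})

setMethod("show", "PeakSet", function(object) {
  cat("PeakSet [", object@channel, "]: ", nrow(object@coords),
      " peaks (prominence ", signif(object@prominence, 3), ")\n", sep = "")
})

setMethod("show", "LCurve", function(object) {
  cat("LCurve", paste(object@pair, collapse = " x "), "nucleus",
      object@nucleus, ":", length(object@r), "distances,",
      "L range", paste(signif(range(object@L, na.rm = TRUE), 3),
                       collapse = " to "), "\n")
})
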