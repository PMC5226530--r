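# --- iterative-flooding segmentation and per-focus measurement --------------

#' Segment focus regions by iterative flooding of detected peaks
#'
#' Starting from the seed peaks, thresholds descend from the brightest peak
#' intensity towards \code{floorLevel} in decrements of \code{step}. At each
#' level, unassigned voxels at or above the level that are 26-connected to
#' exactly one region join that region (growth within a level proceeds in
#' synchronous sweeps, so the result is independent of voxel order); a voxel
#' touching two or more regions is frozen as a boundary voxel and assigned
#' to the region whose seed peak is physically nearer (tie: brighter peak).
#' Frozen voxels do not conduct further growth, so regions stay disjoint.
#' Flooding stops at the floor, whose default is the in-mask median plus
#' three robust background sds: high enough that background voxels stay
#' below the 26-connectivity percolation threshold (about 10 percent
#' occupancy), so regions cannot leak into connected noise clusters.
#'
#' @param grid a \linkS4class{VoxelGrid} or 3D array.
#' @param peaks a \linkS4class{PeakSet} detected on this grid.
#' @param floorLevel flooding stop level in intensity units; default
#'   median + 3 background sd inside \code{mask}.
#' @param step level decrement (default 1 code value; must be >= 1 for
#'   integer data).
#' @param mask optional \linkS4class{NuclearMask} or logical array limiting
#'   growth.
#' @return list with \code{labels} (integer array, 0 = unassigned, k = the
#'   k-th peak's region), \code{frozen} (logical array of contested
#'   boundary voxels), \code{floorLevel} and \code{step}. A peak below the
#'   floor keeps a single-voxel region, with a warning.
#' @export
floodRegions <- function(grid, peaks, floorLevel = NULL, step = 1,
                         mask = NULL) {
  arr <- if (is(grid, "VoxelGrid")) grid@values else grid
  vs <- if (is(grid, "VoxelGrid")) grid@voxelSize
        else if (is(peaks, "PeakSet") && nrow(peaks@coords))
          peaks@centers[1, ] / (peaks@coords[1, ] - 0.5)
        else c(1, 1, 1)
  stopifnot(is(peaks, "PeakSet"), step >= 1)
  marr <- if (is.null(mask)) NULL
          else if (is(mask, "NuclearMask")) maskArray(mask) else mask
  if (is.null(floorLevel))
    floorLevel <- .backgroundMedian(arr, marr) +
      3 * .backgroundSigma(arr, marr)
  if (floorLevel < 0) stop("floorLevel must be >= 0")
  d <- dim(arr)
  co <- peaks@coords
  n <- nrow(co)
  if (n == 0L)
    return(list(labels = array(0L, d), frozen = array(FALSE, d),
                floorLevel = floorLevel, step = step))
  pv <- arr[co]
  below <- pv < floorLevel
  if (any(below))
    warning(sum(below), " peak(s) below the flooding floor; kept as ",
            "single-voxel regions")
  allowed <- if (is.null(marr)) rep(TRUE, prod(d)) else as.logical(marr)
  res <- cpp_flood_regions(as.numeric(arr), as.integer(d),
                           as.integer(.linearIndex(co[!below, , drop = FALSE],
                                                   d) - 1L),
                           as.numeric(pv[!below]), floorLevel,
                           as.numeric(step), as.numeric(vs), allowed)
  labels <- res$labels
  if (any(below)) {
    # renumber grown regions to original peak order, insert floor peaks
    mapIdx <- which(!below)
    lab2 <- array(0L, d)
    pos <- labels > 0L
    lab2[pos] <- mapIdx[labels[pos]]
    for (k in which(below)) lab2[co[k, 1L], co[k, 2L], co[k, 3L]] <- k
    labels <- lab2
  }
  list(labels = labels, frozen = array(as.logical(res$frozen), d),
       floorLevel = floorLevel, step = step)
}

#' Measure a single focus region
#'
#' Physical volume is the voxel count times the voxel volume; mean
#' intensity is taken from the raw grid over the unsaturated region voxels
#' only. A region whose voxels are all saturated is reported at the top
#' code value and flagged.
#'
#' @param region integer/logical index of region voxels: a logical array,
#'   or a matrix of (z, y, x) voxel coordinates.
#' @param rawGrid a \linkS4class{VoxelGrid} or 3D array of raw intensities.
#' @param saturationMask logical array flagging saturated voxels (optional).
#' @param voxelSize numeric(3) (dz, dy, dx) um; taken from \code{rawGrid}
#'   when it is a \linkS4class{VoxelGrid}.
#' @return one-row data.frame: \code{nVoxels}, \code{volume} (um^3),
#'   \code{meanIntensity} (a.u.), \code{allSaturated} (logical).
#' @export
measureFocus <- function(region, rawGrid, saturationMask = NULL,
                         voxelSize = NULL) {
  arr <- if (is(rawGrid, "VoxelGrid")) rawGrid@values else rawGrid
  if (is(rawGrid, "VoxelGrid")) voxelSize <- rawGrid@voxelSize
  if (is.null(voxelSize)) stop("voxelSize required")
  if (is.array(region) && is.logical(region)) {
    idx <- which(region)
  } else {
    region <- rbind(region)
    d <- dim(arr)
    for (j in 1:3)
      if (any(region[, j] < 1L | region[, j] > d[j]))
        stop("region outside grid bounds")
    idx <- .linearIndex(region, d)
  }
  if (!length(idx)) stop("empty region")
  sat <- if (is.null(saturationMask)) rep(FALSE, length(idx))
         else saturationMask[idx]
  vals <- arr[idx]
  allSat <- all(sat)
  top <- if (is(rawGrid, "VoxelGrid")) 2^rawGrid@bitDepth - 1 else 255
  data.frame(nVoxels = length(idx),
             volume = length(idx) * prod(voxelSize),
             meanIntensity = if (allSat) top else mean(vals[!sat]),
             allSaturated = allSat)
}

#' Measure all flooded focus regions of one channel
#'
#' @param flood result of \code{\link{floodRegions}}.
#' @param rawGrid raw-intensity \linkS4class{VoxelGrid} (mean intensity is
#'   always taken from raw data, even when detection ran on a processed
#'   grid).
#' @param peaks the \linkS4class{PeakSet} that seeded the flooding.
#' @param saturationMask optional logical array from
#'   \code{\link{correctSaturation}}.
#' @return data.frame, one row per focus: \code{focus}, \code{channel},
#'   peak voxel coordinates \code{z, y, x}, physical peak position
#'   \code{z_um, y_um, x_um}, \code{nVoxels}, \code{volume},
#'   \code{meanIntensity}, \code{allSaturated}.
#' @export
measureFoci <- function(flood, rawGrid, peaks, saturationMask = NULL) {
  arr <- if (is(rawGrid, "VoxelGrid")) rawGrid@values else rawGrid
  vs <- if (is(rawGrid, "VoxelGrid")) rawGrid@voxelSize
        else stop("rawGrid must be a VoxelGrid")
  lab <- flood$labels
  n <- nPeaks(peaks)
  if (n == 0L)
    return(data.frame(focus = integer(), channel = character(),
                      z = integer(), y = integer(), x = integer(),
                      z_um = numeric(), y_um = numeric(), x_um = numeric(),
                      peakIntensity = numeric(), nVoxels = integer(),
                      volume = numeric(), meanIntensity = numeric(),
                      allSaturated = logical()))
  pos <- which(lab > 0L)
  byLab <- split(pos, lab[pos])
  top <- 2^rawGrid@bitDepth - 1
  rows <- lapply(seq_len(n), function(k) {
    idx <- byLab[[as.character(k)]]
    if (is.null(idx)) idx <- .linearIndex(peaks@coords[k, , drop = FALSE],
                                          dim(arr))
    sat <- if (is.null(saturationMask)) rep(FALSE, length(idx))
           else saturationMask[idx]
    allSat <- all(sat)
    data.frame(nVoxels = length(idx),
               volume = length(idx) * prod(vs),
               meanIntensity = if (allSat) top else mean(arr[idx][!sat]),
               allSaturated = allSat)
  })
  meas <- do.call(rbind, rows)
  cbind(data.frame(focus = seq_len(n), channel = peaks@channel,
                   z = peaks@coords[, 1L], y = peaks@coords[, 2L],
                   x = peaks@coords[, 3L],
                   z_um = peaks@centers[, 1L], y_um = peaks@centers[, 2L],
                   x_um = peaks@centers[, 3L],
                   peakIntensity = peaks@values,
                   stringsAsFactors = FALSE),
        meas)
}
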