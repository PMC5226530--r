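# --- calibrated TIFF stacks, sidecar metadata, preprocessing ----------------

#' Write a nucleus to a multi-page TIFF with a sidecar metadata file
#'
#' Pages are written channel-fastest within each z-slice, channels in the
#' fixed order 53BP1, gammaH2AX, EdU; the sidecar YAML (\code{<path>.yaml})
#' records grid shape, voxel size, channel order, bit depth and the
#' treatment / substage labels, so a stack round-trips losslessly together
#' with its calibration.
#'
#' @param record a \linkS4class{NucleusRecord}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeNucleusStack <- function(record, path) {
  stopifnot(is(record, "NucleusRecord"))
  chs <- record@channels
  d <- dim(chs[[1L]]@values)
  bits <- chs[[1L]]@bitDepth
  scale <- 2^bits - 1
  pages <- vector("list", d[1L] * length(chs))
  k <- 0L
  for (z in seq_len(d[1L]))
    for (ch in seq_along(chs)) {
      k <- k + 1L
      pages[[k]] <- chs[[ch]]@values[z, , ] / scale
    }
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  meta <- list(id = record@id, treatment = record@treatment,
               substage = record@substage,
               channels = names(chs),
               dim = as.integer(d),
               voxel_size_um = as.numeric(chs[[1L]]@voxelSize),
               bit_depth = as.integer(bits))
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a nucleus stack with calibration and metadata
#'
#' Reads a multi-channel 3D TIFF written by \code{\link{writeNucleusStack}}
#' (or any stack with an equivalent sidecar). Calibration must be explicit —
#' there is no silent default voxel size, because physical volume thresholds
#' are meaningless without it. Exactly three channels are required. If no
#' mask is supplied the nuclear mask is computed with
#' \code{\link{maskFromStack}}.
#'
#' @param path TIFF path; \code{<path>.yaml} is read as sidecar unless
#'   \code{metadata} is given.
#' @param metadata optional named list overriding the sidecar (fields as in
#'   \code{\link{writeNucleusStack}}).
#' @param computeMask compute the nuclear mask from the stack (default
#'   TRUE).
#' @return A \linkS4class{NucleusRecord}.
#' @export
readNucleus <- function(path, metadata = NULL, computeMask = TRUE) {
  if (is.null(metadata)) {
    side <- paste0(path, ".yaml")
    if (!file.exists(side))
      stop("no calibration for ", path,
           ": sidecar ", side, " missing and no metadata supplied")
    metadata <- yaml::read_yaml(side)
  }
  need <- c("voxel_size_um", "channels")
  miss <- setdiff(need, names(metadata))
  if (length(miss))
    stop("metadata for ", path, " lacks: ", paste(miss, collapse = ", "))
  chNames <- metadata$channels
  if (length(chNames) != 3L)
    stop(path, ": expected 3 channels, metadata declares ",
         length(chNames))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  nch <- length(chNames)
  if (length(pages) %% nch != 0L)
    stop(path, ": page count ", length(pages),
         " is not a multiple of the declared ", nch, " channels")
  nz <- length(pages) %/% nch
  d <- c(nz, dim(pages[[1L]]))
  bits <- if (!is.null(metadata$bit_depth)) as.integer(metadata$bit_depth)
          else if (max(unlist(pages)) > 255) 16L else 8L
  vs <- as.numeric(metadata$voxel_size_um)
  grids <- lapply(seq_len(nch), function(ch) {
    a <- array(0L, d)
    for (z in seq_len(nz)) a[z, , ] <- as.integer(pages[[(z - 1L) * nch + ch]])
    new("VoxelGrid", values = a, voxelSize = vs, channel = chNames[ch],
        bitDepth = bits)
  })
  names(grids) <- chNames
  mask <- if (computeMask) maskFromStack(grids) else NULL
  new("NucleusRecord",
      id = if (!is.null(metadata$id)) metadata$id else basename(path),
      treatment = if (!is.null(metadata$treatment)) metadata$treatment
                  else "untreated",
      substage = if (!is.null(metadata$substage)) metadata$substage
                 else "nonreplicating",
      channels = grids, raw = list(), mask = mask)
}

#' Segment the nuclear mask from the image content
#'
#' Channels are summed, smoothed with a physical-size Gaussian, thresholded
#' with Otsu's method on the volumetric histogram, and the largest
#' 26-connected foreground component is kept as the nucleus.
#'
#' @param grids list of \linkS4class{VoxelGrid} (at least one channel).
#' @param smoothSigmaUm isotropic smoothing sd in um (default 0.2,
#'   about twice the lateral PSF width: wide enough to bridge foci and
#'   diffuse staining, narrow enough not to blur the nuclear boundary).
#' @return A \linkS4class{NuclearMask} (a single connected component).
#' @export
maskFromStack <- function(grids, smoothSigmaUm = 0.2) {
  if (is(grids, "VoxelGrid")) grids <- list(grids)
  stopifnot(length(grids) >= 1L)
  vs <- grids[[1L]]@voxelSize
  total <- Reduce(`+`, lapply(grids, function(g) g@values))
  d <- dim(total)
  sm <- cpp_sep_conv3d(total, as.integer(d),
                       .gaussKernel1d(smoothSigmaUm / vs[1L]),
                       .gaussKernel1d(smoothSigmaUm / vs[2L]),
                       .gaussKernel1d(smoothSigmaUm / vs[3L]))
  if (max(sm) == min(sm)) stop("empty foreground: stack is constant")
  thr <- .otsuThreshold(round(sm), maxValue = as.integer(max(round(sm))))
  fg <- sm > thr
  if (!any(fg)) stop("empty foreground above the Otsu threshold")
  lab <- cpp_label3d(fg, as.integer(d))
  big <- which.max(tabulate(lab[lab > 0L]))
  new("NuclearMask", mask = array(lab == big, d), voxelSize = vs)
}

#' Flag oversaturated voxels
#'
#' Voxels at the top code value of the bit depth (255 for 8-bit) are
#' flagged; intensities are never altered. The flag mask is consumed by
#' focus measurement, which excludes saturated voxels from mean-intensity
#' numerators and denominators, and by background estimation.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @return list with elements \code{grid} (unchanged) and
#'   \code{saturationMask} (logical array).
#' @export
correctSaturation <- function(grid) {
  stopifnot(is(grid, "VoxelGrid"))
  top <- 2^grid@bitDepth - 1
  list(grid = grid, saturationMask = grid@values >= top)
}

#' Correct a channel-to-channel registration shift
#'
#' Finds the integer-voxel 3D translation of \code{moving} that maximizes
#' the cross-correlation with \code{reference} within \code{maxShift}
#' voxels per axis, and applies it with zero fill. Integer shifts are used
#' deliberately: sub-voxel interpolation would resample the raw intensities
#' that feed the bright/dim classifier.
#'
#' @param reference,moving \linkS4class{VoxelGrid}s of identical shape.
#' @param maxShift integer(3) maximum shift per axis (z, y, x), default
#'   c(2, 2, 2).
#' @return list with \code{grid} (shifted \linkS4class{VoxelGrid}),
#'   \code{shift} (integer(3), the translation applied to moving) and
#'   \code{status} ("ok" or "flat" when the moving image has no contrast,
#'   in which case the shift is 0 and a warning is raised).
#' @export
correctRegistrationShift <- function(reference, moving,
                                     maxShift = c(2L, 2L, 2L)) {
  stopifnot(is(reference, "VoxelGrid"), is(moving, "VoxelGrid"))
  a <- reference@values; b <- moving@values
  if (!identical(dim(a), dim(b))) stop("grids must have identical shape")
  d <- dim(a)
  if (sd(b) == 0) {
    warning("moving image is flat; applying zero shift")
    return(list(grid = moving, shift = c(0L, 0L, 0L), status = "flat"))
  }
  ac <- a - mean(a)
  best <- c(0L, 0L, 0L); bestCor <- -Inf
  ms <- as.integer(maxShift)
  for (sz in -ms[1L]:ms[1L]) for (sy in -ms[2L]:ms[2L])
    for (sx in -ms[3L]:ms[3L]) {
      az <- max(1L, 1L + sz):min(d[1L], d[1L] + sz)
      ay <- max(1L, 1L + sy):min(d[2L], d[2L] + sy)
      axx <- max(1L, 1L + sx):min(d[3L], d[3L] + sx)
      bz <- az - sz; by <- ay - sy; bx <- axx - sx
      va <- ac[az, ay, axx]; vb <- b[bz, by, bx]
      if (sd(vb) == 0) next
      cc <- sum((va - mean(va)) * (vb - mean(vb))) /
        (length(va) * sd(va) * sd(vb))
      if (cc > bestCor) { bestCor <- cc; best <- c(sz, sy, sx) }
    }
  out <- array(0, d)
  az <- max(1L, 1L + best[1L]):min(d[1L], d[1L] + best[1L])
  ay <- max(1L, 1L + best[2L]):min(d[2L], d[2L] + best[2L])
  axx <- max(1L, 1L + best[3L]):min(d[3L], d[3L] + best[3L])
  out[az, ay, axx] <- b[az - best[1L], ay - best[2L], axx - best[3L]]
  shifted <- new("VoxelGrid", values = out, voxelSize = moving@voxelSize,
                 channel = moving@channel, bitDepth = moving@bitDepth)
  list(grid = shifted, shift = best, status = "ok")
}

#' Write a study of synthetic nuclei to disk
#'
#' One TIFF + sidecar per nucleus, a pooled ground-truth TSV, and a run
#' parameter file recording the seed.
#'
#' @param study result of \code{\link{simulateStudy}}.
#' @param dir output directory (created if needed).
#' @param params list of run parameters (seed etc.) stored as YAML.
#' @return data.frame manifest (id, treatment, substage, path).
#' @export
writeStudy <- function(study, dir, params = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(names(study), function(id) {
    rec <- study[[id]]$record
    path <- file.path(dir, paste0(id, ".tif"))
    writeNucleusStack(rec, path)
    tr <- study[[id]]$truth
    tr$nucleus <- id
    list(manifest = data.frame(id = id, treatment = rec@treatment,
                               substage = rec@substage, path = path,
                               stringsAsFactors = FALSE),
         truth = tr)
  })
  truth <- do.call(rbind, lapply(rows, `[[`, "truth"))
  write.table(truth, file.path(dir, "ground_truth.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  yaml::write_yaml(params, file.path(dir, "run_params.yaml"))
  do.call(rbind, lapply(rows, `[[`, "manifest"))
}
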