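# --- synthetic nuclei with known ground truth -------------------------------

.insideMask <- function(pos, mask, vs) {
  pos <- rbind(pos)
  d <- dim(mask)
  v <- floor(sweep(pos, 2L, vs, "/")) + 1
  ok <- v[, 1L] >= 1 & v[, 1L] <= d[1L] &
        v[, 2L] >= 1 & v[, 2L] <= d[2L] &
        v[, 3L] >= 1 & v[, 3L] <= d[3L]
  ok[ok] <- mask[cbind(v[ok, 1L], v[ok, 2L], v[ok, 3L])]
  ok
}

#' Sample focus positions inside a nuclear mask
#'
#' Draws point positions (physical um coordinates, columns z, y, x) inside
#' the mask under one of three spatial models:
#' \describe{
#'   \item{csr}{complete spatial randomness: uniform over mask voxel centres
#'     with continuous sub-voxel jitter — the null model of the L-function.}
#'   \item{clustered}{a Thomas-like process: Poisson-distributed parents
#'     placed CSR, Gaussian offspring around them (sd \code{clusterSigma}),
#'     offspring falling outside the mask are redrawn until \code{n} points
#'     are obtained.}
#'   \item{colocalized}{\code{round(fraction * n)} points are drawn as
#'     reference points plus isotropic Gaussian offsets of sd
#'     \code{offsetSigma} (redrawn while outside the mask); the remainder is
#'     CSR. This is the generator for cross-channel association.}
#' }
#'
#' @param mask a \linkS4class{NuclearMask}.
#' @param n number of positions.
#' @param mode one of "csr", "clustered", "colocalized".
#' @param reference matrix of reference positions (um, columns z, y, x);
#'   required for colocalized mode.
#' @param fraction colocalized fraction in [0, 1].
#' @param offsetSigma sd (um) of the colocalization offset.
#' @param meanOffspring mean points per cluster parent (clustered mode).
#' @param clusterSigma cluster dispersion sd in um.
#' @param seed optional integer seed; the draw is reproducible given it.
#' @return numeric matrix n x 3, columns z, y, x (um); a matrix of
#'   colocalization link indices into \code{reference} is attached as
#'   attribute \code{"link"} (NA for CSR-drawn points).
#' @export
samplePositions <- function(mask, n, mode = c("csr", "clustered",
                                              "colocalized"),
                            reference = NULL, fraction = 1,
                            offsetSigma = 0.15, meanOffspring = 5,
                            clusterSigma = 0.3, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(is(mask, "NuclearMask"), n >= 0)
  vs <- voxelSize(mask)
  arr <- maskArray(mask)
  empty <- matrix(numeric(), 0L, 3L, dimnames = list(NULL, c("z", "y", "x")))
  if (n == 0) return(structure(empty, link = integer()))
  idx <- which(arr)
  if (!length(idx)) stop("mask is empty: cannot place ", n, " positions")
  d <- dim(arr)

  csrDraw <- function(m) {
    s <- idx[sample.int(length(idx), m, replace = TRUE)]
    co <- arrayInd(s, d)
    jit <- matrix(runif(3 * m), m, 3L)
    sweep(co - 1 + jit, 2L, vs, "*")
  }

  .withSeed(seed, {
    link <- rep(NA_integer_, n)
    if (mode == "csr") {
      pos <- csrDraw(n)
    } else if (mode == "clustered") {
      nPar <- max(1L, rpois(1L, n / meanOffspring))
      parents <- csrDraw(nPar)
      pos <- matrix(NA_real_, n, 3L)
      got <- 0L
      while (got < n) {
        need <- n - got
        p <- parents[sample.int(nPar, need, replace = TRUE), , drop = FALSE]
        cand <- p + matrix(rnorm(3 * need, sd = clusterSigma), need, 3L)
        ok <- .insideMask(cand, arr, vs)
        keep <- which(ok)
        if (length(keep)) {
          pos[got + seq_along(keep), ] <- cand[keep, , drop = FALSE]
          got <- got + length(keep)
        }
      }
    } else {
      if (is.null(reference) || nrow(reference) == 0L)
        stop("colocalized mode requires a nonempty reference position set")
      if (fraction < 0 || fraction > 1)
        stop("fraction must lie in [0, 1]")
      k <- round(fraction * n)
      pos <- matrix(NA_real_, n, 3L)
      if (k > 0) {
        nref <- nrow(reference)
        pick <- if (nref >= k) sample.int(nref, k)
                else sample.int(nref, k, replace = TRUE)
        got <- 0L
        while (got < k) {
          todo <- which(is.na(pos[seq_len(k), 1L]))
          p <- reference[pick[todo], , drop = FALSE]
          cand <- p + matrix(rnorm(3 * length(todo), sd = offsetSigma),
                             length(todo), 3L)
          ok <- if (offsetSigma == 0) rep(TRUE, length(todo))
                else .insideMask(cand, arr, vs)
          pos[todo[ok], ] <- cand[ok, , drop = FALSE]
          got <- sum(!is.na(pos[seq_len(k), 1L]))
        }
        link[seq_len(k)] <- pick
      }
      if (k < n) pos[(k + 1L):n, ] <- csrDraw(n - k)
    }
    colnames(pos) <- c("z", "y", "x")
    structure(pos, link = link)
  })
}

#' Default focus population parameters for the generator
#'
#' Two gamma-H2AX populations are drawn from lognormal amplitude / width
#' distributions chosen so that, rendered at the default noise level, they
#' straddle the bright/dim classifier thresholds (0.25 um^3, 35 a.u.):
#' "bright" foci are large and intense, "dim" foci small and faint but still
#' well above background. 53BP1 and EdU (replication) foci each use a single
#' intermediate population. Amplitudes are post-PSF peak heights in 8-bit
#' a.u.; widths are Gaussian sd in um (axial width = 1.8 x lateral,
#' reflecting confocal axial elongation).
#'
#' @param nBright,nDim,n53BP1,nEdU focus counts per nucleus. Defaults
#'   keep the per-volume densities of a drug-treated mid-S nucleus (about
#'   0.1 gamma-H2AX and 0.2 replication foci per um^3) at the scaled-down
#'   default geometry, so the fraction of foci lying within one optical
#'   resolution element of a neighbour matches full-size acquisitions.
#' @param colocBrightEdU fraction of bright gamma-H2AX foci placed at EdU
#'   sites. @param colocBright53BP1 fraction of 53BP1 foci placed at bright
#'   gamma-H2AX foci. @param colocDimEdU,colocDim53BP1 same for dim foci
#'   (via EdU) and dim-associated 53BP1; defaults 0 (CSR dim population).
#' @param offsetSigma colocalization offset sd (um).
#' @param psfSigmaXY,psfSigmaZ Gaussian PSF sd (um).
#' @param noise list(offset, poissonScale, gaussianSD) — constant camera
#'   offset (a.u.), photon scaling of the Poisson shot-noise term
#'   (0 disables), and Gaussian read-noise sd (a.u.).
#' @param nuclearBackground diffuse nucleoplasmic staining level in a.u.,
#'   rendered inside the mask only; it is what makes the nucleus
#'   segmentable from the image content.
#' @return A parameter list consumed by \code{\link{simulateGroundTruth}}.
#' @export
fociSimConfig <- function(nBright = 15L, nDim = 25L, n53BP1 = 15L,
                          nEdU = 80L,
                          colocBrightEdU = 0.8, colocBright53BP1 = 0.9,
                          colocDimEdU = 0, colocDim53BP1 = 0,
                          offsetSigma = 0.15,
                          psfSigmaXY = 0.08, psfSigmaZ = 0.18,
                          noise = list(offset = 4, poissonScale = 4,
                                       gaussianSD = 1),
                          nuclearBackground = 10) {
  list(
    counts = c(bright = nBright, dim = nDim, `53BP1` = n53BP1, EdU = nEdU),
    coloc = c(brightEdU = colocBrightEdU, bright53BP1 = colocBright53BP1,
              dimEdU = colocDimEdU, dim53BP1 = colocDim53BP1),
    offsetSigma = offsetSigma,
    populations = list(
      bright = list(ampMeanLog = log(120), ampSdLog = 0.30,
                    sxyMeanLog = log(0.17), sxySdLog = 0.15, szFactor = 1.8),
      dim    = list(ampMeanLog = log(30),  ampSdLog = 0.25,
                    sxyMeanLog = log(0.09), sxySdLog = 0.15, szFactor = 1.8),
      `53BP1` = list(ampMeanLog = log(80), ampSdLog = 0.30,
                    sxyMeanLog = log(0.12), sxySdLog = 0.15, szFactor = 1.8),
      EdU    = list(ampMeanLog = log(60),  ampSdLog = 0.30,
                    sxyMeanLog = log(0.10), sxySdLog = 0.15, szFactor = 1.8)),
    psfSigmaXY = psfSigmaXY, psfSigmaZ = psfSigmaZ,
    noise = noise, nuclearBackground = nuclearBackground)
}

.drawPopulation <- function(p, n) {
  sxy <- exp(rnorm(n, p$sxyMeanLog, p$sxySdLog))
  data.frame(amplitude = exp(rnorm(n, p$ampMeanLog, p$ampSdLog)),
             sigma_xy = sxy, sigma_z = p$szFactor * sxy)
}

#' Generate ground-truth foci for one synthetic nucleus
#'
#' Places EdU (replication) foci first (CSR), then gamma-H2AX foci of the
#' bright and dim populations — bright foci colocalized with EdU sites at
#' the configured fraction — and finally 53BP1 foci colocalized with bright
#' gamma-H2AX foci. Colocalization links are recorded in \code{link_id}.
#'
#' @param mask a \linkS4class{NuclearMask}.
#' @param config a list from \code{\link{fociSimConfig}}.
#' @param seed optional integer seed.
#' @return data.frame with one row per true focus: \code{focus} (id),
#'   \code{channel}, \code{population}, physical coordinates \code{z, y, x}
#'   (um), \code{amplitude}, \code{sigma_xy}, \code{sigma_z} and
#'   \code{link_id} (id of the reference focus for colocalized draws).
#' @export
simulateGroundTruth <- function(mask, config = fociSimConfig(),
                                seed = NULL) {
  stopifnot(is(mask, "NuclearMask"))
  .withSeed(seed, {
    cnt <- config$counts
    edu <- samplePositions(mask, cnt[["EdU"]], "csr")
    bright <- samplePositions(mask, cnt[["bright"]], "colocalized",
                              reference = edu,
                              fraction = config$coloc[["brightEdU"]],
                              offsetSigma = config$offsetSigma)
    dimF <- if (config$coloc[["dimEdU"]] > 0)
      samplePositions(mask, cnt[["dim"]], "colocalized", reference = edu,
                      fraction = config$coloc[["dimEdU"]],
                      offsetSigma = config$offsetSigma)
    else samplePositions(mask, cnt[["dim"]], "csr")
    p53 <- if (config$coloc[["bright53BP1"]] > 0 && nrow(bright) > 0)
      samplePositions(mask, cnt[["53BP1"]], "colocalized",
                      reference = bright,
                      fraction = config$coloc[["bright53BP1"]],
                      offsetSigma = config$offsetSigma)
    else samplePositions(mask, cnt[["53BP1"]], "csr")

    pops <- config$populations
    blk <- function(pos, channel, population, pars, linkPrefix) {
      n <- nrow(pos)
      if (n == 0)
        return(data.frame(channel = character(), population = character(),
                          z = numeric(), y = numeric(), x = numeric(),
                          amplitude = numeric(), sigma_xy = numeric(),
                          sigma_z = numeric(), link_id = character(),
                          stringsAsFactors = FALSE))
      lk <- attr(pos, "link")
      cbind(data.frame(channel = channel, population = population,
                       stringsAsFactors = FALSE),
            as.data.frame(pos), .drawPopulation(pars, n),
            data.frame(link_id = ifelse(is.na(lk), NA_character_,
                                        paste0(linkPrefix, lk)),
                       stringsAsFactors = FALSE))
    }
    truth <- rbind(
      blk(edu, "EdU", "EdU", pops$EdU, ""),
      blk(bright, "gammaH2AX", "bright", pops$bright, "EdU_"),
      blk(dimF, "gammaH2AX", "dim", pops$dim,
          if (config$coloc[["dimEdU"]] > 0) "EdU_" else ""),
      blk(p53, "53BP1", "53BP1", pops$`53BP1`, "gammaH2AX_bright_"))
    truth$focus <- paste0(truth$channel, "_",
                          ave(seq_len(nrow(truth)), truth$channel,
                              FUN = seq_along))
    rownames(truth) <- NULL
    truth[, c("focus", "channel", "population", "z", "y", "x",
              "amplitude", "sigma_xy", "sigma_z", "link_id")]
  })
}

#' Render one channel of a synthetic nucleus
#'
#' The clean image is a sum of anisotropic 3D Gaussian spots convolved with
#' a Gaussian PSF; because the convolution of two Gaussians is the Gaussian
#' with quadrature-summed widths, spots are rendered directly at combined
#' widths, which is exact. Each spot's \code{amplitude} is its post-PSF peak
#' height. Noise follows the standard confocal approximation
#' Poisson(scale x signal) / scale plus Gaussian read noise plus a constant
#' offset, then quantization to the bit depth with saturation at the top
#' code value.
#'
#' @param mask a \linkS4class{NuclearMask} (defines grid and calibration).
#' @param foci data.frame with columns z, y, x (um), amplitude, sigma_xy,
#'   sigma_z — e.g. one channel's rows of
#'   \code{\link{simulateGroundTruth}} output. All foci must lie inside the
#'   mask.
#' @param psfSigmaXY,psfSigmaZ Gaussian PSF sd in um.
#' @param noise list(offset, poissonScale, gaussianSD); set
#'   \code{poissonScale = 0} and \code{gaussianSD = 0} for a noiseless
#'   rendering.
#' @param nuclearBackground diffuse in-nucleus signal in a.u. added inside
#'   the mask before noise, emulating nucleoplasmic staining (0 disables).
#' @param bitDepth 8 or 16.
#' @param channel channel label stored in the result.
#' @param seed optional integer seed for the noise draw.
#' @return A \linkS4class{VoxelGrid}.
#' @export
renderStack <- function(mask, foci, psfSigmaXY = 0.08, psfSigmaZ = 0.18,
                        noise = list(offset = 4, poissonScale = 4,
                                     gaussianSD = 1),
                        nuclearBackground = 0,
                        bitDepth = 8L, channel = "", seed = NULL) {
  stopifnot(is(mask, "NuclearMask"))
  if (!bitDepth %in% c(8L, 16L)) stop("bitDepth must be 8 or 16")
  vs <- voxelSize(mask)
  d <- dim(maskArray(mask))
  if (nrow(foci) > 0) {
    pos <- as.matrix(foci[, c("z", "y", "x")])
    if (!all(.insideMask(pos, maskArray(mask), vs)))
      stop("all foci must lie inside the mask")
  }
  clean <- array(0, d)
  zc <- (seq_len(d[1L]) - 0.5) * vs[1L]
  yc <- (seq_len(d[2L]) - 0.5) * vs[2L]
  xc <- (seq_len(d[3L]) - 0.5) * vs[3L]
  for (i in seq_len(nrow(foci))) {
    sz <- sqrt(foci$sigma_z[i]^2 + psfSigmaZ^2)
    sxy <- sqrt(foci$sigma_xy[i]^2 + psfSigmaXY^2)
    iz <- which(abs(zc - foci$z[i]) <= 4.5 * sz)
    iy <- which(abs(yc - foci$y[i]) <= 4.5 * sxy)
    ix <- which(abs(xc - foci$x[i]) <= 4.5 * sxy)
    if (!length(iz) || !length(iy) || !length(ix)) next
    gz <- exp(-(zc[iz] - foci$z[i])^2 / (2 * sz^2))
    gy <- exp(-(yc[iy] - foci$y[i])^2 / (2 * sxy^2))
    gx <- exp(-(xc[ix] - foci$x[i])^2 / (2 * sxy^2))
    clean[iz, iy, ix] <- clean[iz, iy, ix] +
      foci$amplitude[i] * outer(outer(gz, gy), gx)
  }
  if (nuclearBackground > 0)
    clean <- clean + nuclearBackground * maskArray(mask)
  .withSeed(seed, {
    img <- clean + noise$offset
    if (!is.null(noise$poissonScale) && noise$poissonScale > 0)
      img <- rpois(length(img), noise$poissonScale * img) /
        noise$poissonScale
    if (!is.null(noise$gaussianSD) && noise$gaussianSD > 0)
      img <- img + rnorm(length(img), sd = noise$gaussianSD)
    img <- round(img)
    img <- pmin(pmax(img, 0), 2^bitDepth - 1)
    img <- array(as.integer(img), d)  # integer storage halves memory
    new("VoxelGrid", values = img, voxelSize = vs, channel = channel,
        bitDepth = as.integer(bitDepth))
  })
}

#' Simulate one complete synthetic nucleus
#'
#' Builds the ellipsoidal mask, draws ground-truth foci for the three
#' channels and renders the three stacks. Bit-identical output for a fixed
#' seed and parameter set.
#'
#' @param geometry a \linkS4class{NucleusGeometry}.
#' @param config a \code{\link{fociSimConfig}} list.
#' @param id nucleus identifier.
#' @param treatment,substage metadata labels (closed vocabularies).
#' @param seed optional integer seed.
#' @return list with elements \code{record} (a
#'   \linkS4class{NucleusRecord} carrying the true mask) and \code{truth}
#'   (the ground-truth data.frame).
#' @examples
#' sim <- simulateNucleus(NucleusGeometry(dim = c(32, 96, 96),
#'                                        semiAxes = c(1.8, 2.6, 2.6)),
#'                        fociSimConfig(nBright = 5, nDim = 8,
#'                                      n53BP1 = 5, nEdU = 20), seed = 1)
#' sim$record
#' @export
simulateNucleus <- function(geometry = NucleusGeometry(),
                            config = fociSimConfig(), id = "nucleus_1",
                            treatment = "CPT", substage = "S-IV",
                            seed = NULL) {
  .withSeed(seed, {
    mask <- makeNuclearMask(geometry)
    truth <- simulateGroundTruth(mask, config)
    channels <- lapply(.CHANNELS, function(ch) {
      renderStack(mask, truth[truth$channel == ch, , drop = FALSE],
                  psfSigmaXY = config$psfSigmaXY,
                  psfSigmaZ = config$psfSigmaZ,
                  noise = config$noise,
                  nuclearBackground =
                    if (is.null(config$nuclearBackground)) 0
                    else config$nuclearBackground,
                  channel = ch)
    })
    names(channels) <- .CHANNELS
    rec <- new("NucleusRecord", id = id, treatment = treatment,
               substage = substage, channels = channels,
               raw = list(), mask = mask)
    list(record = rec, truth = truth)
  })
}

#' Preset per-treatment generator conditions
#'
#' Study-design presets for the four treatment labels: CPT-like nuclei have
#' bright gamma-H2AX foci strongly colocalized with replication sites and
#' 53BP1; ETP weaker EdU association; MTX no association (CSR bright foci);
#' untreated few foci. Dim foci are CSR in all presets.
#'
#' @param treatment one of untreated, CPT, ETP, MTX.
#' @param ... overrides passed to \code{\link{fociSimConfig}}.
#' @return A \code{\link{fociSimConfig}} list.
#' @export
treatmentPreset <- function(treatment = c("CPT", "ETP", "MTX", "untreated"),
                            ...) {
  treatment <- match.arg(treatment)
  base <- switch(treatment,
    CPT = list(colocBrightEdU = 0.8, colocBright53BP1 = 0.9),
    ETP = list(colocBrightEdU = 0.3, colocBright53BP1 = 0.9),
    MTX = list(colocBrightEdU = 0, colocBright53BP1 = 0),
    untreated = list(nBright = 3L, nDim = 6L, n53BP1 = 4L,
                     colocBrightEdU = 0.6, colocBright53BP1 = 0.8))
  do.call(fociSimConfig, utils::modifyList(base, list(...)))
}

#' Simulate a multi-nucleus study
#'
#' Generates \code{nNuclei} nuclei per stratum (treatment label), all at the
#' given substage, with per-nucleus seeds derived deterministically from
#' \code{seed}.
#'
#' @param geometry a \linkS4class{NucleusGeometry}.
#' @param treatments character vector of treatment labels; each becomes a
#'   stratum simulated under \code{\link{treatmentPreset}}.
#' @param nNuclei nuclei per stratum.
#' @param substage substage label applied to all nuclei.
#' @param seed integer seed for the whole study.
#' @param configOverrides named list of \code{\link{fociSimConfig}}
#'   overrides applied to every preset.
#' @return list of \code{\link{simulateNucleus}} results, one per nucleus.
#' @export
simulateStudy <- function(geometry = NucleusGeometry(),
                          treatments = c("CPT", "MTX"), nNuclei = 20L,
                          substage = "S-IV", seed = 1L,
                          configOverrides = list()) {
  out <- list()
  k <- 0L
  for (tr in treatments) {
    cfg <- do.call(treatmentPreset, c(list(treatment = tr),
                                      configOverrides))
    for (i in seq_len(nNuclei)) {
      k <- k + 1L
      id <- sprintf("%s_%02d", tr, i)
      out[[id]] <- simulateNucleus(geometry, cfg, id = id, treatment = tr,
                                   substage = substage,
                                   seed = as.integer((as.numeric(seed) *
                                     10007 + k) %% 2147483587))
    }
  }
  out
}
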