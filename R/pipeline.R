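# --- per-nucleus orchestration and cross-nucleus aggregation ----------------

#' Analysis run configuration
#'
#' Single source of parameters for the pipeline. Every field is echoed into
#' the per-nucleus log.
#'
#' @param prominence fixed detection prominence, or NULL to derive it per
#'   nucleus from background statistics (\code{\link{autoProminence}}).
#' @param autoProminenceK multiplier for the data-driven prominence.
#' @param mergeRadius,minSepXY,minSepZ detection geometry, in voxels.
#' @param conjunction orthogonal-family confirmation rule for
#'   \code{\link{findMaxima3D}}; the pipeline default "either" accepts an
#'   xy maximum confirmed in xz or yz sections.
#' @param detectSmoothVox Gaussian sd (voxels, per axis z, y, x) of the
#'   pre-detection smoothing (\code{\link{smoothForDetection}}); NULL
#'   disables it. Peak coordinates come from the smoothed grid; flooding
#'   and measurement use the unsmoothed grids.
#' @param floodStep,floorLevel flooding parameters
#'   (\code{\link{floodRegions}}); NULL floor = median + 3 background sd.
#' @param thresholds \code{\link{classThresholds}} for bright/dim.
#' @param inclusive inclusive classifier boundaries (default TRUE).
#' @param rGrid distance grid for L-functions (um).
#' @param binWidth,rMax nearest-neighbour histogram geometry (um).
#' @param nSims Monte-Carlo draws for each CSR reference.
#' @param minNuclei minimum nuclei per stratum before an aggregate is
#'   flagged under-powered (default 18).
#' @param registration correct channel-to-channel registration shifts
#'   against the first channel before detection.
#' @param alpha significance level.
#' @param seed integer seed controlling every stochastic step.
#' @return named list of parameters.
#' @export
runConfig <- function(prominence = NULL, autoProminenceK = 5,
                      mergeRadius = 1L, minSepXY = 2, minSepZ = 1,
                      conjunction = "either",
                      detectSmoothVox = c(0.5, 1, 1),
                      floodStep = 1, floorLevel = NULL,
                      thresholds = classThresholds(), inclusive = TRUE,
                      rGrid = seq(0.1, 2, by = 0.1),
                      binWidth = 0.1, rMax = 2, nSims = 100L,
                      minNuclei = 18L, registration = FALSE,
                      alpha = 0.05, seed = 1L) {
  list(prominence = prominence, autoProminenceK = autoProminenceK,
       mergeRadius = mergeRadius, minSepXY = minSepXY, minSepZ = minSepZ,
       conjunction = conjunction, detectSmoothVox = detectSmoothVox,
       floodStep = floodStep, floorLevel = floorLevel,
       thresholds = thresholds, inclusive = inclusive, rGrid = rGrid,
       binWidth = binWidth, rMax = rMax, nSims = nSims,
       minNuclei = minNuclei, registration = registration, alpha = alpha,
       seed = seed)
}

.classPositions <- function(foci, channel, class = NULL) {
  sel <- foci$channel == channel
  if (!is.null(class)) sel <- sel & foci$class == class
  as.matrix(foci[sel, c("z_um", "y_um", "x_um"), drop = FALSE])
}

.nucleusSeed <- function(seed, id, salt = 0L) {
  as.integer((as.numeric(seed) * 7919 + sum(utf8ToInt(id)) * 131 +
                salt) %% 2147483587)
}

#' Run the full analysis of one nucleus
#'
#' Preprocessing (saturation flagging, optional registration correction)
#' -> nuclear mask -> per-channel peak detection -> iterative flooding ->
#' measurement -> bright/dim classification of gamma-H2AX ->
#' nearest-neighbour distances (gamma-H2AX by class to EdU and to 53BP1)
#' -> L-functions (auto: bright, dim, 53BP1; cross: bright and dim vs EdU
#' and 53BP1). Stages that cannot run (e.g. a channel without foci) are
#' skipped with a log entry; they never abort the nucleus.
#'
#' @param record a \linkS4class{NucleusRecord}.
#' @param config a \code{\link{runConfig}} list.
#' @return list: \code{id}, \code{foci} (classified focus table),
#'   \code{counts}, \code{occupancy} (fraction of nuclear volume claimed
#'   by bright regions — a dim-count underestimation indicator),
#'   \code{prominence} (named per channel), \code{nn} (named list of
#'   nearest-neighbour results), \code{lcurves} (named list of
#'   \linkS4class{LCurve}), \code{log} (character).
#' @export
runNucleus <- function(record, config = runConfig()) {
  stopifnot(is(record, "NucleusRecord"))
  log <- .logCollector()
  mask <- record@mask
  if (is.null(mask)) {
    mask <- maskFromStack(record@channels)
    log$add("mask computed from stack")
  }
  chs <- record@channels
  if (config$registration && length(chs) > 1L) {
    for (ch in names(chs)[-1L]) {
      reg <- correctRegistrationShift(chs[[1L]], chs[[ch]])
      chs[[ch]] <- reg$grid
      log$add("registration shift ", ch, ": ",
              paste(reg$shift, collapse = ","), " (", reg$status, ")")
    }
  }
  fociAll <- list()
  prominences <- numeric()
  brightVoxels <- 0L
  for (ch in names(chs)) {
    grid <- chs[[ch]]
    raw <- if (length(record@raw) && !is.null(record@raw[[ch]]))
      record@raw[[ch]] else grid
    sat <- correctSaturation(raw)$saturationMask
    detGrid <- if (is.null(config$detectSmoothVox)) grid
               else smoothForDetection(grid, config$detectSmoothVox)
    prom <- if (is.null(config$prominence))
      autoProminence(detGrid, mask, config$autoProminenceK)
    else config$prominence
    prominences[ch] <- prom
    log$add("prominence ", ch, ": ", signif(prom, 4))
    peaks <- findMaxima3D(detGrid, mask, prom,
                          mergeRadius = config$mergeRadius,
                          minSepXY = config$minSepXY,
                          minSepZ = config$minSepZ,
                          conjunction = config$conjunction)
    flood <- floodRegions(grid, peaks, floorLevel = config$floorLevel,
                          step = config$floodStep, mask = mask)
    foci <- measureFoci(flood, raw, peaks, saturationMask = sat)
    if (ch == "gammaH2AX" && nrow(foci)) {
      cls <- classifyFocus(foci$volume, foci$meanIntensity,
                           config$thresholds, config$inclusive)
      bright <- which(cls == "bright")
      if (length(bright))
        brightVoxels <- sum(flood$labels %in% bright)
    }
    fociAll[[ch]] <- foci
  }
  foci <- do.call(rbind, fociAll)
  rownames(foci) <- NULL
  foci <- classifyFoci(foci, config$thresholds, config$inclusive)
  foci$nucleus <- record@id
  counts <- countByClass(foci)
  counts$nucleus <- record@id
  occupancy <- brightVoxels / sum(maskArray(mask))

  pos <- list(bright = .classPositions(foci, "gammaH2AX", "bright"),
              dim = .classPositions(foci, "gammaH2AX", "dim"),
              `53BP1` = .classPositions(foci, "53BP1"),
              EdU = .classPositions(foci, "EdU"))

  nn <- list()
  for (src in c("bright", "dim")) for (tgt in c("EdU", "53BP1")) {
    key <- paste0(src, "_to_", tgt)
    if (nrow(pos[[src]]) == 0L) {
      log$add("nn ", key, ": skipped, no source foci"); next
    }
    if (nrow(pos[[tgt]]) == 0L) {
      log$add("nn ", key, ": skipped, no target foci in nucleus"); next
    }
    d <- nnDistances(pos[[src]], pos[[tgt]])
    nn[[key]] <- c(nnHistogram(d, config$binWidth, config$rMax),
                   list(distances = d, source = src, target = tgt))
  }

  pairs <- list(bright = c("bright", NA), dim = c("dim", NA),
                `53BP1` = c("53BP1", NA),
                bright_x_EdU = c("bright", "EdU"),
                dim_x_EdU = c("dim", "EdU"),
                bright_x_53BP1 = c("bright", "53BP1"),
                dim_x_53BP1 = c("dim", "53BP1"))
  lcurves <- list()
  salt <- 0L
  for (key in names(pairs)) {
    salt <- salt + 1L
    srcName <- pairs[[key]][1L]
    tgtName <- pairs[[key]][2L]
    a <- pos[[srcName]]
    autoMode <- is.na(tgtName)
    b <- if (autoMode) NULL else pos[[tgtName]]
    if ((autoMode && nrow(a) < 2L) ||
        (!autoMode && (nrow(a) < 1L || nrow(b) < 1L))) {
      log$add("L ", key, ": skipped, too few points"); next
    }
    obs <- ripleyK(a, b, config$rGrid)
    ref <- csrReference(mask, nrow(a),
                        if (autoMode) NULL else nrow(b),
                        config$rGrid, nSims = config$nSims,
                        seed = .nucleusSeed(config$seed, record@id, salt))
    lcurves[[key]] <- normalizeL(obs, ref$mean, config$rGrid,
                                 nSource = nrow(a),
                                 nTarget = if (autoMode) nrow(a)
                                           else nrow(b),
                                 pair = c(srcName,
                                          if (autoMode) srcName
                                          else tgtName),
                                 nucleus = record@id)
  }
  list(id = record@id, treatment = record@treatment,
       substage = record@substage, foci = foci, counts = counts,
       occupancy = occupancy, prominence = prominences, nn = nn,
       lcurves = lcurves, log = log$get())
}

#' Analyze every nucleus of a study
#'
#' Applies \code{\link{runNucleus}} to each record (or TIFF path); a
#' failing nucleus is marked failed in the manifest and the run continues.
#'
#' @param records list of \linkS4class{NucleusRecord}s, or character
#'   vector of TIFF paths read with \code{\link{readNucleus}}.
#' @param config a \code{\link{runConfig}} list.
#' @return list with \code{results} (per-nucleus lists) and
#'   \code{manifest} (data.frame id/status/message).
#' @export
analyzeStudy <- function(records, config = runConfig()) {
  results <- list()
  manifest <- list()
  for (item in records) {
    # paths are read one nucleus at a time to bound memory use
    if (is.character(item)) {
      rec <- tryCatch(readNucleus(item), error = function(e) e)
      if (inherits(rec, "error")) {
        manifest[[item]] <- data.frame(id = item, status = "failed",
                                       message = conditionMessage(rec),
                                       stringsAsFactors = FALSE)
        next
      }
    } else {
      rec <- item
    }
    st <- tryCatch(
      list(res = runNucleus(rec, config), status = "ok", msg = ""),
      error = function(e) list(res = NULL, status = "failed",
                               msg = conditionMessage(e)))
    if (!is.null(st$res)) results[[rec@id]] <- st$res
    manifest[[rec@id]] <- data.frame(id = rec@id, status = st$status,
                                     message = st$msg,
                                     stringsAsFactors = FALSE)
  }
  list(results = results, manifest = do.call(rbind, manifest))
}

#' Aggregate per-nucleus results into a study summary
#'
#' Strata are treatment x substage. Focus counts are averaged per stratum
#' with SD; nearest-neighbour distances are pooled over nuclei before
#' histogramming (the per-nucleus histograms can be averaged instead via
#' \code{pooled = FALSE}); per-nucleus L-curves are summarized with
#' \code{\link{testLvsZero}}; gamma-H2AX counts are compared between
#' strata with \code{\link{compareCounts}}. Strata with fewer than
#' \code{config$minNuclei} nuclei are flagged under-powered.
#'
#' @param analysis output of \code{\link{analyzeStudy}}.
#' @param config a \code{\link{runConfig}} list.
#' @param pooled pool NN distances across nuclei before histogramming
#'   (default TRUE).
#' @return list: \code{counts} (per-stratum mean/sd/n with
#'   \code{underPowered} flag), \code{nn} (pooled histograms and medians
#'   per stratum and channel pair), \code{lsummaries} (per stratum and
#'   pair, \code{\link{testLvsZero}} tables), \code{comparisons}
#'   (pairwise stratum contrasts of bright/dim counts), \code{occupancy}.
#' @export
aggregateStudy <- function(analysis, config = runConfig(),
                           pooled = TRUE) {
  res <- analysis$results
  if (!length(res)) stop("no analyzable nuclei")
  meta <- data.frame(
    id = vapply(res, `[[`, "", "id"),
    treatment = vapply(res, `[[`, "", "treatment"),
    substage = vapply(res, `[[`, "", "substage"),
    occupancy = vapply(res, `[[`, 0, "occupancy"),
    stringsAsFactors = FALSE)
  meta$stratum <- paste(meta$treatment, meta$substage, sep = ":")
  strata <- unique(meta$stratum)

  countsLong <- do.call(rbind, lapply(res, function(r) {
    cc <- r$counts
    cc$stratum <- paste(r$treatment, r$substage, sep = ":")
    cc
  }))
  key <- interaction(countsLong$stratum, countsLong$channel,
                     countsLong$class, drop = TRUE)
  counts <- do.call(rbind, lapply(split(countsLong, key), function(g) {
    data.frame(stratum = g$stratum[1L], channel = g$channel[1L],
               class = g$class[1L], n = nrow(g), mean = mean(g$count),
               sd = if (nrow(g) > 1L) sd(g$count) else 0,
               underPowered = nrow(g) < config$minNuclei,
               stringsAsFactors = FALSE)
  }))
  rownames(counts) <- NULL

  nnSummaries <- list()
  for (st in strata) {
    ids <- meta$id[meta$stratum == st]
    for (key in c("bright_to_EdU", "dim_to_EdU", "bright_to_53BP1",
                  "dim_to_53BP1")) {
      per <- lapply(res[ids], function(r) r$nn[[key]])
      per <- per[!vapply(per, is.null, TRUE)]
      if (!length(per)) next
      if (pooled) {
        d <- unlist(lapply(per, `[[`, "distances"))
        h <- nnHistogram(d, config$binWidth, config$rMax)
      } else {
        cs <- do.call(rbind, lapply(per, `[[`, "counts"))
        h <- list(breaks = per[[1L]]$breaks, counts = colMeans(cs),
                  median = median(vapply(per, `[[`, 0, "median")),
                  n = sum(vapply(per, `[[`, 0L, "n")))
      }
      nnSummaries[[paste(st, key, sep = "|")]] <-
        c(h, list(stratum = st, pair = key, nNuclei = length(per)))
    }
  }

  lsummaries <- list()
  for (st in strata) {
    ids <- meta$id[meta$stratum == st]
    pairKeys <- unique(unlist(lapply(res[ids],
                                     function(r) names(r$lcurves))))
    for (key in pairKeys) {
      lcs <- lapply(res[ids], function(r) r$lcurves[[key]])
      lcs <- lcs[!vapply(lcs, is.null, TRUE)]
      if (length(lcs) < 2L) next
      tab <- testLvsZero(lcs, alpha = config$alpha)
      attr(tab, "stratum") <- st
      attr(tab, "pair") <- key
      attr(tab, "nNuclei") <- length(lcs)
      attr(tab, "underPowered") <- length(lcs) < config$minNuclei
      lsummaries[[paste(st, key, sep = "|")]] <- tab
    }
  }

  comparisons <- list()
  if (length(strata) > 1L) {
    for (cls in c("bright", "dim")) {
      sub <- countsLong[countsLong$channel == "gammaH2AX" &
                          countsLong$class == cls, ]
      for (i in seq_along(strata)) for (j in seq_along(strata)) {
        if (i >= j) next
        a <- sub$count[sub$stratum == strata[i]]
        b <- sub$count[sub$stratum == strata[j]]
        if (length(a) < 2L || length(b) < 2L) next
        comparisons[[paste(cls, strata[i], "vs", strata[j])]] <-
          compareCounts(a, b)
      }
    }
  }
  list(counts = counts, nn = nnSummaries, lsummaries = lsummaries,
       comparisons = comparisons,
       occupancy = meta[, c("id", "stratum", "occupancy")])
}

#' Simulate, analyze and aggregate a synthetic study
#'
#' Convenience wrapper: \code{\link{simulateStudy}} ->
#' \code{\link{analyzeStudy}} -> \code{\link{aggregateStudy}}, optionally
#' persisting focus tables, count tables and L summaries as TSV under
#' \code{outDir}.
#'
#' @param geometry a \linkS4class{NucleusGeometry}.
#' @param treatments character vector of strata.
#' @param nNuclei nuclei per stratum.
#' @param config a \code{\link{runConfig}}; its seed drives everything.
#' @param outDir optional output directory for TSV tables.
#' @param configOverrides generator overrides per
#'   \code{\link{simulateStudy}}.
#' @return list with \code{study} (simulated nuclei), \code{analysis},
#'   \code{summary}.
#' @export
runStudy <- function(geometry = NucleusGeometry(),
                     treatments = c("CPT", "MTX"), nNuclei = 20L,
                     config = runConfig(), outDir = NULL,
                     configOverrides = list()) {
  study <- simulateStudy(geometry, treatments, nNuclei,
                         seed = config$seed,
                         configOverrides = configOverrides)
  analysis <- analyzeStudy(lapply(study, `[[`, "record"), config)
  summary <- aggregateStudy(analysis, config)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    foci <- do.call(rbind, lapply(analysis$results, `[[`, "foci"))
    write.table(foci, file.path(outDir, "foci.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write.table(summary$counts, file.path(outDir, "counts.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    ls <- do.call(rbind, lapply(names(summary$lsummaries), function(k) {
      tab <- summary$lsummaries[[k]]
      cbind(stratum = attr(tab, "stratum"), pair = attr(tab, "pair"), tab)
    }))
    if (!is.null(ls))
      write.table(ls, file.path(outDir, "l_summary.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
    write.table(analysis$manifest, file.path(outDir, "manifest.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    yaml::write_yaml(config[!vapply(config, is.null, TRUE)],
                     file.path(outDir, "config.yaml"))
  }
  list(study = study, analysis = analysis, summary = summary)
}

#' Plot a mean L-curve with significance flags
#'
#' @param lsummary a table from \code{\link{testLvsZero}}.
#' @param main plot title.
#' @return invisibly, \code{lsummary}.
#' @importFrom graphics abline lines plot points
#' @export
plotLSummary <- function(lsummary, main = "") {
  plot(lsummary$r, lsummary$meanL, type = "l", xlab = "r (um)",
       ylab = "mean L(r)", main = main)
  abline(h = 0, lty = 2)
  sig <- which(lsummary$significant)
  if (length(sig)) points(lsummary$r[sig], lsummary$meanL[sig], pch = 16)
  invisible(lsummary)
}

#' Plot a nearest-neighbour distance histogram
#'
#' The empirical median is annotated in the top right, following the usual
#' presentation of such panels.
#'
#' @param nnResult a result of \code{\link{nnHistogram}} (optionally with
#'   the pooling metadata added by \code{\link{aggregateStudy}}).
#' @param main plot title.
#' @return invisibly, \code{nnResult}.
#' @importFrom graphics barplot legend mtext
#' @export
plotNNHistogram <- function(nnResult, main = "") {
  barplot(nnResult$counts,
          names.arg = c(sprintf("%.1f", nnResult$breaks[-1L]), ">"),
          xlab = "distance to nearest neighbour (um)", ylab = "count",
          main = main)
  mtext(sprintf("median %.3f um", nnResult$median), side = 3, adj = 1,
        line = -1.5)
  invisible(nnResult)
}
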