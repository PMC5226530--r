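# --- bright/dim classification of gamma-H2AX foci ---------------------------

#' Classification thresholds for bright vs dim foci
#'
#' A gamma-H2AX focus is "bright" when its volume reaches \code{volume}
#' um^3 or its raw-image mean intensity reaches \code{intensity} a.u. on
#' the 8-bit scale; otherwise it is "dim". Defaults 0.25 um^3 and 35 a.u.
#'
#' @param volume volume threshold in um^3 (> 0).
#' @param intensity mean-intensity threshold in a.u. (> 0).
#' @return named list used by \code{\link{classifyFocus}}.
#' @export
classThresholds <- function(volume = 0.25, intensity = 35) {
  if (volume <= 0 || intensity <= 0)
    stop("thresholds must be strictly positive")
  list(volume = volume, intensity = intensity)
}

#' Classify foci as bright or dim
#'
#' Bright iff volume >= V or mean intensity >= I (inclusive boundaries by
#' default; set \code{inclusive = FALSE} for strict >). The intensity
#' threshold applies to the raw-image mean intensity — measure foci on raw
#' grids even when detection ran on processed data.
#'
#' @param volume focus volume(s) in um^3 (>= 0).
#' @param meanIntensity raw mean intensity(ies) in a.u. (>= 0).
#' @param thresholds a \code{\link{classThresholds}} list.
#' @param inclusive logical; boundary values count as bright when TRUE.
#' @return character vector, "bright" or "dim".
#' @examples
#' classifyFocus(0.30, 20)  # bright by volume
#' classifyFocus(0.10, 40)  # bright by intensity
#' classifyFocus(0.10, 20)  # dim
#' @export
classifyFocus <- function(volume, meanIntensity,
                          thresholds = classThresholds(),
                          inclusive = TRUE) {
  if (any(volume < 0) || any(meanIntensity < 0))
    stop("volume and meanIntensity must be non-negative")
  bright <- if (inclusive)
    volume >= thresholds$volume | meanIntensity >= thresholds$intensity
  else
    volume > thresholds$volume | meanIntensity > thresholds$intensity
  ifelse(bright, "bright", "dim")
}

#' Add the bright/dim class to a focus table
#'
#' gamma-H2AX rows are classified with \code{\link{classifyFocus}}; other
#' channels are left "unclassified".
#'
#' @param foci data.frame from \code{\link{measureFoci}} (columns
#'   \code{channel}, \code{volume}, \code{meanIntensity}).
#' @param thresholds,inclusive see \code{\link{classifyFocus}}.
#' @return \code{foci} with a \code{class} column.
#' @export
classifyFoci <- function(foci, thresholds = classThresholds(),
                         inclusive = TRUE) {
  cls <- rep("unclassified", nrow(foci))
  g <- foci$channel == "gammaH2AX"
  if (any(g))
    cls[g] <- classifyFocus(foci$volume[g], foci$meanIntensity[g],
                            thresholds, inclusive)
  foci$class <- cls
  foci
}

#' Per-channel, per-class focus counts of one nucleus
#'
#' Bright + dim always equals the gamma-H2AX total; 53BP1 and EdU counts
#' are reported unclassified.
#'
#' @param foci classified focus table (\code{\link{classifyFoci}}).
#' @return data.frame with columns \code{channel}, \code{class},
#'   \code{count}, including zero rows for absent combinations.
#' @export
countByClass <- function(foci) {
  combos <- rbind(
    data.frame(channel = "gammaH2AX", class = c("bright", "dim"),
               stringsAsFactors = FALSE),
    data.frame(channel = c("53BP1", "EdU"), class = "unclassified",
               stringsAsFactors = FALSE))
  combos$count <- vapply(seq_len(nrow(combos)), function(i) {
    sum(foci$channel == combos$channel[i] & foci$class == combos$class[i])
  }, integer(1L))
  combos
}
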