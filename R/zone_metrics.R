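# Per-eye quantities: zone areas, total dropout area per zone, mean
# choroidal flow density, dropout presence.

#' Physical area of one pixel
#'
#' @param image an \code{\linkS4class{EnFaceImage}}.
#' @return pixel area in square micrometres (pitch squared); 126.5625 um^2
#'   at the default 11.25 um pitch.
#' @export
pixelAreaUm2 <- function(image) {
  pixelPitchUm(image)^2
}

#' Area of a binary mask in mm^2
#'
#' Pixel counting: number of \code{TRUE} pixels times the pixel area.
#'
#' @param mask logical matrix congruent with the image.
#' @param image an \code{\linkS4class{EnFaceImage}} supplying the pitch.
#' @return area in mm^2.
#' @export
zoneAreaMm2 <- function(mask, image) {
  if (!identical(dim(mask), dim(image)))
    stop("mask shape does not match the image", call. = FALSE)
  sum(mask) * pixelAreaUm2(image) / 1e6
}

#' Mean choroidal flow density within a zone
#'
#' The area occupied by blood signal: the number of valid (non-vessel) zone
#' pixels with grey value \code{>= signalThreshold}. A normalized variant
#' (count divided by the zone pixel count) is returned alongside for
#' unit-robust comparisons.
#'
#' @param image an \code{\linkS4class{EnFaceImage}}.
#' @param zoneMask logical matrix for the zone of interest.
#' @param vessels optional \code{\linkS4class{VesselMask}}.
#' @param signalThreshold grey value, default 50.
#' @return list with \code{count}, \code{fraction} and \code{empty_zone}.
#'   An empty zone yields count 0 with \code{empty_zone = TRUE} and a
#'   warning.
#' @export
meanFlowDensity <- function(image, zoneMask, vessels = NULL,
                            signalThreshold = 50) {
  if (!identical(dim(zoneMask), dim(image)))
    stop("zone mask shape does not match the image", call. = FALSE)
  assertScalarInRange(signalThreshold, 0, 255, "signalThreshold")
  if (!is.null(vessels)) image <- applyVesselMask(image, vessels)
  nZone <- sum(zoneMask)
  if (nZone == 0L) {
    warning("empty zone: flow density reported as 0")
    return(list(count = 0L, fraction = 0, empty_zone = TRUE))
  }
  signal <- validMask(image) & zoneMask & greyValues(image) >= signalThreshold
  list(count = sum(signal), fraction = sum(signal) / nZone,
       empty_zone = FALSE)
}

#' Summarize one eye into per-eye metrics
#'
#' Totals detected dropout area by zone, attaches zone areas, presence
#' booleans and flow densities. Eyes with no detected dropout contribute 0
#' to the area columns and remain in the cohort (presence is reported
#' separately).
#'
#' @param regions an \code{\linkS4class{MvDRegions}} object.
#' @param zones a \code{\linkS4class{ZoneSet}}.
#' @param image an \code{\linkS4class{EnFaceImage}}.
#' @param vessels optional \code{\linkS4class{VesselMask}}.
#' @param signalThreshold flow-signal grey threshold, default 50.
#' @return one-row data.frame with columns \code{eye_id},
#'   \code{ppa_beta_area_mm2}, \code{ppa_alpha_area_mm2},
#'   \code{mvd_total_area_beta_mm2}, \code{mvd_total_area_alpha_mm2},
#'   \code{mvd_n_regions}, \code{mvd_present}, \code{mvd_present_alpha},
#'   \code{density_beta}, \code{density_alpha}, \code{density_beta_fraction},
#'   \code{density_alpha_fraction}.
#' @export
summarizeEye <- function(regions, zones, image, vessels = NULL,
                         signalThreshold = 50) {
  tab <- regionTable(regions)
  betaMaskM <- zoneMask(zones, "beta")
  alphaMaskM <- zoneMask(zones, "alpha")
  db <- if (sum(betaMaskM))
    meanFlowDensity(image, betaMaskM, vessels, signalThreshold)
  else list(count = 0L, fraction = 0, empty_zone = TRUE)
  da <- if (sum(alphaMaskM))
    meanFlowDensity(image, alphaMaskM, vessels, signalThreshold)
  else list(count = 0L, fraction = 0, empty_zone = TRUE)
  data.frame(
    eye_id = eyeId(image),
    ppa_beta_area_mm2 = zoneAreaMm2(betaMaskM, image),
    ppa_alpha_area_mm2 = zoneAreaMm2(alphaMaskM, image),
    mvd_total_area_beta_mm2 = sum(tab$area_mm2[tab$zone == "beta"]),
    mvd_total_area_alpha_mm2 = sum(tab$area_mm2[tab$zone == "alpha"]),
    mvd_n_regions = nrow(tab),
    mvd_present = nrow(tab) > 0,
    mvd_present_alpha = any(tab$zone == "alpha"),
    density_beta = db$count,
    density_alpha = da$count,
    density_beta_fraction = db$fraction,
    density_alpha_fraction = da$fraction,
    stringsAsFactors = FALSE)
}
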