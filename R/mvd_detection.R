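# Microvascular dropout detection: connected dark regions with grey value
# strictly below a threshold (default 50) whose pixel area strictly exceeds
# a minimum (default 20 px), restricted to the PPA zones.

#' Binarize dark pixels
#'
#' \code{TRUE} exactly at valid pixels with grey value strictly less than the
#' threshold. Invalid pixels (e.g. excluded vessels) are never dark.
#'
#' @param image an \code{\linkS4class{EnFaceImage}}.
#' @param greyThreshold grey-value threshold in \code{[0, 255]}; strict
#'   \code{<}, so a pixel exactly at the threshold is not dark.
#' @return logical matrix.
#' @export
binarizeDark <- function(image, greyThreshold = 50) {
  assertScalarInRange(greyThreshold, 0, 255, "greyThreshold")
  validMask(image) & greyValues(image) < greyThreshold
}

#' Label connected components of a binary grid
#'
#' Breadth-first labeling of maximal connected components under 4- or
#' 8-connectivity. Labels are dense from 1, assigned in column-major scan
#' order of the first pixel encountered in each component.
#'
#' @param mask logical matrix.
#' @param connectivity 4 (edge-adjacent) or 8 (edge- or corner-adjacent).
#' @return integer matrix of the same shape; 0 = background.
#' @export
labelComponents <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8))
    stop("connectivity must be 4 or 8", call. = FALSE)
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (!length(idx)) return(labels)
  off <- neighbourOffsets(connectivity, nr)
  nOff <- length(off$dr)
  lab <- 0L
  for (seed in idx) {
    if (labels[seed] != 0L) next
    lab <- lab + 1L
    labels[seed] <- lab
    frontier <- seed
    while (length(frontier)) {
      r <- (frontier - 1L) %% nr + 1L
      cc <- (frontier - 1L) %/% nr + 1L
      nxt <- integer(0)
      for (k in seq_len(nOff)) {
        rr <- r + off$dr[k]
        ccn <- cc + off$dc[k]
        ok <- rr >= 1L & rr <= nr & ccn >= 1L & ccn <= nc
        if (!any(ok)) next
        cand <- (ccn[ok] - 1L) * nr + rr[ok]
        cand <- cand[mask[cand] & labels[cand] == 0L]
        if (length(cand)) {
          labels[cand] <- lab
          nxt <- c(nxt, cand)
        }
      }
      frontier <- unique(nxt)
    }
  }
  labels
}

#' Assign a detected region to a PPA zone by pixel majority
#'
#' The zone containing the majority of the region's pixels wins; an exact
#' tie goes to the beta zone (the zone in which dropout is primarily
#' measured). A region intersecting neither zone is an error.
#'
#' @param pixels two-column (row, col) matrix of region pixels.
#' @param zones a \code{\linkS4class{ZoneSet}}.
#' @return \code{"beta"} or \code{"alpha"}.
#' @export
assignZone <- function(pixels, zones) {
  b <- zoneMask(zones, "beta")
  a <- zoneMask(zones, "alpha")
  nb <- sum(b[pixels])
  na <- sum(a[pixels])
  if (nb + na == 0L)
    stop("region lies outside both PPA zones", call. = FALSE)
  if (na > nb) "alpha" else "beta"
}

#' Detect microvascular dropout regions
#'
#' Implements the dropout rule: within the PPA zones (beta union alpha),
#' after excluding large-vessel pixels, find connected components of pixels
#' with grey value strictly below \code{greyThreshold} whose area strictly
#' exceeds \code{minAreaPx}, and assign each to a zone by pixel majority.
#'
#' By default the dark mask is clipped to the zone pixels before components
#' are labeled, so a dark structure spilling out of the atrophy zones is
#' measured only inside them; set \code{clipZonesFirst = FALSE} to label on
#' the full grid and then intersect. Pixels invalidated by the vessel mask
#' can split a dark structure in two; each part is area-filtered
#' independently.
#'
#' @param image an \code{\linkS4class{EnFaceImage}}.
#' @param zones a \code{\linkS4class{ZoneSet}} congruent with the image.
#' @param vessels optional \code{\linkS4class{VesselMask}} to exclude.
#' @param greyThreshold dropout grey threshold (strict \code{<}), default 50.
#' @param minAreaPx minimum area in pixels (strict \code{>}), default 20.
#' @param connectivity 4 or 8 (default 8).
#' @param clipZonesFirst see Details.
#' @return an \code{\linkS4class{MvDRegions}} object; regions sorted by
#'   area descending, ties broken by centroid (row, then column).
#' @examples
#' g <- matrix(200L, 60, 60)
#' g[20:29, 20:24] <- 30L                     # 50-px dark blob
#' img <- EnFaceImage(g)
#' beta <- matrix(FALSE, 60, 60); beta[10:50, 10:50] <- TRUE
#' z <- ZoneSet(matrix(FALSE, 60, 60), matrix(FALSE, 60, 60), beta)
#' regionTable(detectMvd(img, z))
#' @export
detectMvd <- function(image, zones, vessels = NULL, greyThreshold = 50,
                      minAreaPx = 20, connectivity = 8,
                      clipZonesFirst = TRUE) {
  if (!identical(dim(image), dim(zoneMask(zones, "beta"))))
    stop("zone masks are not congruent with the image", call. = FALSE)
  if (minAreaPx < 0) stop("minAreaPx must be >= 0", call. = FALSE)
  if (!is.null(vessels)) image <- applyVesselMask(image, vessels)
  zoneUnion <- zoneMask(zones, "beta") | zoneMask(zones, "alpha")
  dark <- binarizeDark(image, greyThreshold)
  if (clipZonesFirst) {
    labels <- labelComponents(dark & zoneUnion, connectivity)
  } else {
    labels <- labelComponents(dark, connectivity)
    labels[!zoneUnion] <- 0L
  }
  nLab <- max(labels)
  grid <- greyValues(image)
  pitch <- pixelPitchUm(image)
  pxMm2 <- pitch^2 / 1e6
  rows <- list(); pix <- list()
  kept <- 0L
  for (l in seq_len(nLab)) {
    idx <- which(labels == l)
    if (length(idx) <= minAreaPx) next
    kept <- kept + 1L
    rc <- cbind(row = (idx - 1L) %% nrow(grid) + 1L,
                col = (idx - 1L) %/% nrow(grid) + 1L)
    rows[[kept]] <- data.frame(
      zone = assignZone(rc, zones),
      area_px = length(idx),
      area_mm2 = length(idx) * pxMm2,
      centroid_row = mean(rc[, "row"]),
      centroid_col = mean(rc[, "col"]),
      min_grey = min(grid[idx]),
      mean_grey = mean(grid[idx]),
      stringsAsFactors = FALSE)
    pix[[kept]] <- rc
  }
  if (kept) {
    tab <- do.call(rbind, rows)
    ord <- order(-tab$area_px, tab$centroid_row, tab$centroid_col)
    tab <- tab[ord, , drop = FALSE]
    pix <- pix[ord]
    tab <- cbind(region_id = seq_len(nrow(tab)), tab)
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(region_id = integer(0), zone = character(0),
                      area_px = integer(0), area_mm2 = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      min_grey = numeric(0), mean_grey = numeric(0),
                      stringsAsFactors = FALSE)
    pix <- list()
  }
  new("MvDRegions", table = tab, pixels = pix, eyeId = eyeId(image),
      greyThreshold = greyThreshold, minAreaPx = minAreaPx,
      connectivity = as.integer(connectivity))
}
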