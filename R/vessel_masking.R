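# Large choroidal vessels appear as bright elongated structures in en-face
# OCTA. They are excluded (pixels invalidated), never inpainted: inpainting
# would fabricate signal that feeds the absolute grey-value threshold.

#' Segment large vessels as bright elongated components
#'
#' Thresholds bright pixels (grey >= \code{brightThreshold}), labels
#' connected components (8-connectivity), and keeps components that are long
#' and wide enough to be large vessels: estimated skeleton length
#' \code{L >= minLengthPx}, estimated width \code{area / L >= minWidthPx},
#' and elongation \code{L / width >= elongationMin} (which rejects compact
#' bright speckle clusters). The length estimate is moment-based:
#' \code{L = sqrt(12 * var)} along the principal axis of the component's
#' pixel coordinates, which is exact for a straight ribbon.
#'
#' @param image an \code{\linkS4class{EnFaceImage}}.
#' @param brightThreshold grey value in \code{[0, 255]}; default 180.
#' @param minWidthPx minimum estimated width, default 4 px.
#' @param minLengthPx minimum estimated length, default 30 px.
#' @param elongationMin minimum length/width ratio, default 3.
#' @return a \code{\linkS4class{VesselMask}}.
#' @export
segmentLargeVessels <- function(image, brightThreshold = 180,
                                minWidthPx = 4, minLengthPx = 30,
                                elongationMin = 3) {
  assertScalarInRange(brightThreshold, 0, 255, "brightThreshold")
  bright <- validMask(image) & greyValues(image) >= brightThreshold
  labels <- labelComponents(bright, 8)
  keep <- matrix(FALSE, nrow(labels), ncol(labels))
  nLab <- max(labels)
  if (nLab > 0) {
    idxAll <- which(labels > 0L)
    labVec <- labels[idxAll]
    byLab <- split(idxAll, labVec)
    nr <- nrow(labels)
    for (idx in byLab) {
      n <- length(idx)
      if (n < minLengthPx * minWidthPx) next   # cannot satisfy both bounds
      r <- (idx - 1L) %% nr + 1L
      cc <- (idx - 1L) %/% nr + 1L
      cv <- stats::cov(cbind(r, cc)) * (n - 1) / n  # population moments
      lambda <- max(eigen(cv, symmetric = TRUE, only.values = TRUE)$values)
      L <- sqrt(12 * lambda)
      if (L < minLengthPx) next
      W <- n / L
      if (W < minWidthPx) next
      if (L / W < elongationMin) next
      keep[idx] <- TRUE
    }
  }
  VesselMask(keep)
}

#' Exclude vessel pixels from an image
#'
#' Clears the image's valid mask at vessel pixels; grey values are untouched.
#' Downstream operations (dropout detection, flow density) ignore invalid
#' pixels. Idempotent.
#'
#' @param image an \code{\linkS4class{EnFaceImage}}.
#' @param vessels a \code{\linkS4class{VesselMask}} of the same shape.
#' @return the image with an updated valid mask.
#' @export
applyVesselMask <- function(image, vessels) {
  if (!identical(dim(image), dim(vessels@mask)))
    stop("vessel mask shape does not match the image", call. = FALSE)
  validMask(image) <- validMask(image) & !vessels@mask
  image
}
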