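#' Construct an EnFaceImage
#'
#' @param grid numeric matrix of integer grey values in \code{[0, 255]}.
#' @param eyeId character identifier.
#' @param pixelPitchUm physical pixel side length in micrometres; the default
#'   11.25 um corresponds to a 4.5 mm field sampled at 400 pixels.
#' @param validMask optional logical matrix; defaults to all-\code{TRUE}.
#' @return an \code{\linkS4class{EnFaceImage}}.
#' @examples
#' img <- EnFaceImage(matrix(128L, 10, 10))
#' pixelAreaUm2(img)
#' @export
EnFaceImage <- function(grid, eyeId = "eye", pixelPitchUm = 11.25,
                        validMask = NULL) {
  storage.mode(grid) <- "integer"
  if (is.null(validMask))
    validMask <- matrix(TRUE, nrow(grid), ncol(grid))
  new("EnFaceImage", eyeId = eyeId, grid = grid,
      pixelPitchUm = pixelPitchUm, validMask = validMask)
}

#' @rdname EnFaceImage-class
#' @aliases greyValues,EnFaceImage-method
setMethod("greyValues", "EnFaceImage", function(x) x@grid)

#' @rdname EnFaceImage-class
#' @aliases validMask,EnFaceImage-method
setMethod("validMask", "EnFaceImage", function(x) x@validMask)

#' @rdname EnFaceImage-class
#' @aliases validMask<-,EnFaceImage-method
setReplaceMethod("validMask", "EnFaceImage", function(x, value) {
  x@validMask <- value
  validObject(x)
  x
})

#' @rdname EnFaceImage-class
#' @aliases pixelPitchUm,EnFaceImage-method
setMethod("pixelPitchUm", "EnFaceImage", function(x) x@pixelPitchUm)

#' @rdname EnFaceImage-class
#' @aliases eyeId,EnFaceImage-method
setMethod("eyeId", "EnFaceImage", function(x) x@eyeId)

#' @rdname EnFaceImage-class
#' @aliases dim,EnFaceImage-method
setMethod("dim", "EnFaceImage", function(x) dim(x@grid))

setMethod("show", "EnFaceImage", function(object) {
  d <- dim(object@grid)
  cat(sprintf(
    "EnFaceImage '%s': %d x %d px, pitch %.4g um (field %.3g x %.3g mm)\n",
    object@eyeId, d[1], d[2], object@pixelPitchUm,
    d[2] * object@pixelPitchUm / 1000, d[1] * object@pixelPitchUm / 1000))
  cat(sprintf("  grey range [%d, %d]; %d/%d pixels valid\n",
              min(object@grid), max(object@grid),
              sum(object@validMask), length(object@validMask)))
})

#' Construct a ZoneSet from logical masks
#'
#' @param discMask,alphaMask,betaMask logical matrices of identical
#'   dimensions, pairwise disjoint. \code{alphaMask} and \code{betaMask} mark
#'   the PPA-alpha and PPA-beta zones.
#' @return a \code{\linkS4class{ZoneSet}}.
#' @export
ZoneSet <- function(discMask, alphaMask, betaMask) {
  new("ZoneSet", discMask = discMask, alphaMask = alphaMask,
      betaMask = betaMask)
}

#' @rdname ZoneSet-class
#' @aliases zoneMask,ZoneSet-method
setMethod("zoneMask", "ZoneSet", function(x, zone) {
  switch(match.arg(zone, c("disc", "alpha", "beta")),
         disc = x@discMask, alpha = x@alphaMask, beta = x@betaMask)
})

setMethod("show", "ZoneSet", function(object) {
  cat(sprintf("ZoneSet %d x %d px: disc %d px, PPA-alpha %d px, PPA-beta %d px\n",
              nrow(object@discMask), ncol(object@discMask),
              sum(object@discMask), sum(object@alphaMask),
              sum(object@betaMask)))
})

#' Construct a VesselMask
#'
#' @param mask logical matrix, \code{TRUE} at large-vessel pixels.
#' @return a \code{\linkS4class{VesselMask}}.
#' @export
VesselMask <- function(mask) {
  new("VesselMask", mask = mask, vesselFraction = mean(mask))
}

#' @rdname VesselMask-class
#' @aliases vesselFraction,VesselMask-method
setMethod("vesselFraction", "VesselMask", function(x) x@vesselFraction)

setMethod("show", "VesselMask", function(object) {
  cat(sprintf("VesselMask: %d vessel pixels (%.2f%% of image)\n",
              sum(object@mask), 100 * object@vesselFraction))
})

#' @rdname MvDRegions-class
#' @aliases regionTable,MvDRegions-method
setMethod("regionTable", "MvDRegions", function(x) x@table)

#' @rdname MvDRegions-class
#' @aliases regionPixels,MvDRegions-method
setMethod("regionPixels", "MvDRegions", function(x) x@pixels)

#' @rdname MvDRegions-class
#' @aliases nRegions,MvDRegions-method
setMethod("nRegions", "MvDRegions", function(x) nrow(x@table))

setMethod("show", "MvDRegions", function(object) {
  cat(sprintf(
    "MvDRegions '%s': %d region(s) (grey < %g, area > %g px, %d-connectivity)\n",
    object@eyeId, nrow(object@table), object@greyThreshold,
    object@minAreaPx, object@connectivity))
  if (nrow(object@table))
    print(utils::head(object@table, 5), row.names = FALSE)
})

setMethod("show", "CohortSummary", function(object) {
  cat("CohortSummary\n")
  n <- object@nByGroup
  cat("  eyes analyzed:", paste(sprintf("%s=%d", names(n), n),
                                collapse = ", "), "\n")
  cat(sprintf("  MvD prevalence: %.1f%%\n", 100 * object@prevalence))
  cat("  group comparisons:\n")
  print(object@tests, row.names = FALSE)
  cat("  simple-fit correlations with MvD area:\n")
  print(object@simpleFits, row.names = FALSE)
})
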