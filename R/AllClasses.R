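#' @import methods
NULL

#' En-face OCTA image
#'
#' Container for one 8-bit grayscale en-face OCTA image of the peripapillary
#' region. The grid stores integer grey values in \code{[0, 255]}; the
#' physical side length of one pixel (\code{pixelPitchUm}, micrometres)
#' converts pixel counts into areas. \code{validMask} marks pixels eligible
#' for analysis; large-vessel exclusion clears entries of this mask rather
#' than altering grey values.
#'
#' The default acquisition is a 4.5 x 4.5 mm cube sampled as a 400 x 400
#' grid, giving a pitch of 11.25 um and a pixel area of 126.5625 um^2.
#' Coordinates are row/column with the origin at the top-left corner.
#'
#' @slot eyeId character identifier of the eye.
#' @slot grid integer matrix of grey values in \code{[0, 255]}.
#' @slot pixelPitchUm positive numeric, physical pixel side length in um.
#' @slot validMask logical matrix congruent with \code{grid}.
#'
#' @exportClass EnFaceImage
setClass("EnFaceImage",
         representation(eyeId = "character",
                        grid = "matrix",
                        pixelPitchUm = "numeric",
                        validMask = "matrix"))

setValidity("EnFaceImage", function(object) {
  g <- object@grid
  v <- object@validMask
  msg <- character()
  if (!is.numeric(g)) msg <- c(msg, "grid must be a numeric matrix")
  else {
    if (anyNA(g) || any(g < 0) || any(g > 255))
      msg <- c(msg, "grey values must lie in [0, 255]")
    if (any(g != round(g)))
      msg <- c(msg, "grey values must be integers (8-bit)")
  }
  if (!is.logical(v) || !identical(dim(v), dim(g)))
    msg <- c(msg, "validMask must be a logical matrix congruent with grid")
  if (length(object@pixelPitchUm) != 1L || !is.finite(object@pixelPitchUm) ||
      object@pixelPitchUm <= 0)
    msg <- c(msg, "pixelPitchUm must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Peripapillary zone masks
#'
#' Binary masks, congruent with the image grid, for the optic disc and the
#' peripapillary atrophy (PPA) alpha and beta zones. The three masks must be
#' pairwise disjoint; overlap is an error, never silently resolved.
#'
#' @slot discMask,alphaMask,betaMask logical matrices of identical dimensions.
#'
#' @exportClass ZoneSet
setClass("ZoneSet",
         representation(discMask = "matrix",
                        alphaMask = "matrix",
                        betaMask = "matrix"))

setValidity("ZoneSet", function(object) {
  d <- object@discMask; a <- object@alphaMask; b <- object@betaMask
  msg <- character()
  for (m in list(d, a, b))
    if (!is.logical(m)) return("zone masks must be logical matrices")
  if (!identical(dim(d), dim(a)) || !identical(dim(d), dim(b)))
    msg <- c(msg, "zone masks must share the same dimensions")
  else if (any(d & a) || any(d & b) || any(a & b))
    msg <- c(msg, "zone masks must be pairwise disjoint")
  if (length(msg)) msg else TRUE
})

#' Large-vessel exclusion mask
#'
#' Marks pixels occupied by large (bright, elongated) choroidal vessels.
#' These pixels are invalidated before dropout detection and flow-density
#' computation.
#'
#' @slot mask logical matrix; \code{TRUE} at vessel pixels.
#' @slot vesselFraction fraction of image pixels marked as vessel.
#'
#' @exportClass VesselMask
setClass("VesselMask",
         representation(mask = "matrix", vesselFraction = "numeric"))

setValidity("VesselMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  f <- object@vesselFraction
  if (length(f) != 1L || f < 0 || f >= 1)
    return("vesselFraction must lie in [0, 1)")
  if (abs(f - mean(object@mask)) > 1e-12)
    return("vesselFraction inconsistent with mask")
  TRUE
})

#' Detected microvascular dropout regions
#'
#' Result of \code{\link{detectMvd}}: one row per connected dark region that
#' passed the grey-value and area filters, with the pixel sets retained for
#' auditing. Regions are sorted by area (descending), ties broken by
#' centroid row then column.
#'
#' @slot table data.frame with columns \code{region_id}, \code{zone},
#'   \code{area_px}, \code{area_mm2}, \code{centroid_row},
#'   \code{centroid_col}, \code{min_grey}, \code{mean_grey}.
#' @slot pixels list of two-column (row, col) integer matrices, parallel to
#'   \code{table}.
#' @slot eyeId character.
#' @slot greyThreshold,minAreaPx,connectivity detection parameters used.
#'
#' @exportClass MvDRegions
setClass("MvDRegions",
         representation(table = "data.frame",
                        pixels = "list",
                        eyeId = "character",
                        greyThreshold = "numeric",
                        minAreaPx = "numeric",
                        connectivity = "integer"))

setValidity("MvDRegions", function(object) {
  if (nrow(object@table) != length(object@pixels))
    return("table and pixels must be parallel")
  TRUE
})

#' Cohort-level summary statistics
#'
#' Group descriptive statistics, two-sample comparisons, dropout prevalence,
#' Spearman correlations and simple/joint linear fits of MvD area on
#' covariates, for one analyzed cohort.
#'
#' @slot groupStats data.frame: variable, group, n, mean, sd.
#' @slot tests data.frame: variable, t, df, p per group comparison.
#' @slot correlations data.frame: Spearman rho and p of MvD area vs
#'   predictors.
#' @slot simpleFits data.frame: per-predictor simple-fit Pearson r and p.
#' @slot jointModel data.frame: OLS coefficient table of the joint model.
#' @slot prevalence numeric, pooled fraction of eyes with detected MvD.
#' @slot prevalenceByGroup named numeric vector.
#' @slot nByGroup named integer vector of analyzed eyes per group.
#'
#' @exportClass CohortSummary
setClass("CohortSummary",
         representation(groupStats = "data.frame",
                        tests = "data.frame",
                        correlations = "data.frame",
                        simpleFits = "data.frame",
                        jointModel = "data.frame",
                        prevalence = "numeric",
                        prevalenceByGroup = "numeric",
                        nByGroup = "integer"))
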