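#' @rdname EnFaceImage-class
#' @param x an object.
#' @export
setGeneric("greyValues", function(x) standardGeneric("greyValues"))

#' @rdname EnFaceImage-class
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname EnFaceImage-class
#' @param value replacement value.
#' @export
setGeneric("validMask<-", function(x, value) standardGeneric("validMask<-"))

#' @rdname EnFaceImage-class
#' @export
setGeneric("pixelPitchUm", function(x) standardGeneric("pixelPitchUm"))

#' @rdname EnFaceImage-class
#' @export
setGeneric("eyeId", function(x) standardGeneric("eyeId"))

#' @rdname ZoneSet-class
#' @param x a \code{ZoneSet}.
#' @param zone one of \code{"disc"}, \code{"alpha"}, \code{"beta"}.
#' @export
setGeneric("zoneMask", function(x, zone) standardGeneric("zoneMask"))

#' @rdname VesselMask-class
#' @param x a \code{VesselMask}.
#' @export
setGeneric("vesselFraction", function(x) standardGeneric("vesselFraction"))

#' @rdname MvDRegions-class
#' @param x an \code{MvDRegions} object.
#' @export
setGeneric("regionTable", function(x) standardGeneric("regionTable"))

#' @rdname MvDRegions-class
#' @export
setGeneric("regionPixels", function(x) standardGeneric("regionPixels"))

#' @rdname MvDRegions-class
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))
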