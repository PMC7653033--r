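#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers. Slot access via
#' \code{@} is discouraged in user code; these accessors are the stable
#' interface.
#'
#' @param object,x an object of one of the package's S4 classes
#' @param ... further arguments for methods
#' @return The slot value documented in each method.
#' @name accessors
#' @keywords internal
NULL

#' @rdname accessors
#' @export
setGeneric("wavelength", function(object) standardGeneric("wavelength"))

#' @rdname accessors
#' @export
setGeneric("qMap", function(object) standardGeneric("qMap"))

#' @rdname accessors
#' @export
setGeneric("phiMap", function(object) standardGeneric("phiMap"))

#' @rdname accessors
#' @export
setGeneric("thetaMap", function(object) standardGeneric("thetaMap"))

#' @rdname accessors
#' @export
setGeneric("beamGeometry", function(object) standardGeneric("beamGeometry"))

#' @rdname accessors
#' @export
setGeneric("detectorMask", function(object) standardGeneric("detectorMask"))

#' @rdname accessors
#' @export
setGeneric("emptyFlags", function(object) standardGeneric("emptyFlags"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("scanShape", function(object) standardGeneric("scanShape"))

#' @rdname accessors
#' @export
setGeneric("getFrame", function(object, iy, ix) standardGeneric("getFrame"))

#' @rdname accessors
#' @export
setGeneric("spacingMap", function(object) standardGeneric("spacingMap"))

#' @rdname accessors
#' @export
setGeneric("anisotropyMap", function(object) standardGeneric("anisotropyMap"))

#' @rdname accessors
#' @export
setGeneric("orientationMapDeg", function(object) standardGeneric("orientationMapDeg"))

#' @rdname accessors
#' @export
setGeneric("peakIntensityMap", function(object) standardGeneric("peakIntensityMap"))

#' @rdname accessors
#' @export
setGeneric("validMap", function(object) standardGeneric("validMap"))

#' @rdname accessors
#' @export
setGeneric("atBoundMap", function(object) standardGeneric("atBoundMap"))

#' @rdname accessors
#' @export
setGeneric("fitTable", function(object) standardGeneric("fitTable"))

#' @rdname accessors
#' @export
setGeneric("indicatorScalar", function(object) standardGeneric("indicatorScalar"))

#' @rdname accessors
#' @export
setGeneric("indicatorCurve", function(object) standardGeneric("indicatorCurve"))

#' @rdname accessors
#' @export
setGeneric("principalAxesOf", function(object) standardGeneric("principalAxesOf"))
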