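#' @include AllClasses.R
NULL

#' Accessors for imaging objects
#'
#' `voxelData()` returns the intensity array of an [ImageScene-class];
#' `fieldData()` the 4D displacement array of a [DeformationField-class];
#' `spacing()` and `origin()` the grid geometry in mm; `protocol()` the
#' protocol tag; `labelData()`, `brainMask()` and `labelDict()` the parts of
#' a [SegmentationMap-class]; `bandIndex()`, `bandWidth()` and `nBands()`
#' the parts of an [AnnularBandMap-class].
#'
#' @param x an object of the relevant class.
#' @return The slot contents described above.
#' @name accessors
#' @aliases voxelData spacing origin protocol fieldData labelData brainMask
#'   labelDict bandIndex bandWidth nBands
#' @examples
#' sc <- ImageScene(array(0, c(2, 2, 2)), spacing = 2)
#' spacing(sc)
NULL

#' @rdname accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname accessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))
#' @rdname accessors
#' @export
setGeneric("protocol", function(x) standardGeneric("protocol"))
#' @rdname accessors
#' @export
setGeneric("fieldData", function(x) standardGeneric("fieldData"))
#' @rdname accessors
#' @export
setGeneric("labelData", function(x) standardGeneric("labelData"))
#' @rdname accessors
#' @export
setGeneric("brainMask", function(x) standardGeneric("brainMask"))
#' @rdname accessors
#' @export
setGeneric("labelDict", function(x) standardGeneric("labelDict"))
#' @rdname accessors
#' @export
setGeneric("bandIndex", function(x) standardGeneric("bandIndex"))
#' @rdname accessors
#' @export
setGeneric("bandWidth", function(x) standardGeneric("bandWidth"))
#' @rdname accessors
#' @export
setGeneric("nBands", function(x) standardGeneric("nBands"))

#' @rdname accessors
setMethod("voxelData", "ImageScene", function(x) x@voxels)
#' @rdname accessors
setMethod("spacing", "ImageScene", function(x) x@spacing)
#' @rdname accessors
setMethod("origin", "ImageScene", function(x) x@origin)
#' @rdname accessors
setMethod("protocol", "ImageScene", function(x) x@protocol)
#' @rdname accessors
setMethod("spacing", "DeformationField", function(x) x@spacing)
#' @rdname accessors
setMethod("origin", "DeformationField", function(x) x@origin)
#' @rdname accessors
setMethod("fieldData", "DeformationField", function(x) x@field)
#' @rdname accessors
setMethod("spacing", "SegmentationMap", function(x) x@spacing)
#' @rdname accessors
setMethod("origin", "SegmentationMap", function(x) x@origin)
#' @rdname accessors
setMethod("labelData", "SegmentationMap", function(x) x@labels)
#' @rdname accessors
setMethod("brainMask", "SegmentationMap", function(x) x@brain)
#' @rdname accessors
setMethod("labelDict", "SegmentationMap", function(x) x@labelDict)
#' @rdname accessors
setMethod("spacing", "AnnularBandMap", function(x) x@spacing)
#' @rdname accessors
setMethod("origin", "AnnularBandMap", function(x) x@origin)
#' @rdname accessors
setMethod("bandIndex", "AnnularBandMap", function(x) x@bands)
#' @rdname accessors
setMethod("bandWidth", "AnnularBandMap", function(x) x@width)
#' @rdname accessors
setMethod("nBands", "AnnularBandMap", function(x) as.integer(x@nBands))

#' Accessors for RampCoxFit
#'
#' @param x,object a [RampCoxFit-class].
#' @param ... ignored.
#' @return `selectedFeatures()` the selected feature names; `coef()` their
#'   coefficients (standardized scale); `riskThreshold()` the frozen
#'   dichotomization threshold.
#' @name fit-accessors
#' @aliases selectedFeatures riskThreshold
NULL

#' @rdname fit-accessors
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))
#' @rdname fit-accessors
#' @export
setGeneric("riskThreshold", function(x) standardGeneric("riskThreshold"))
#' @rdname fit-accessors
setMethod("selectedFeatures", "RampCoxFit", function(x) x@selected)
#' @rdname fit-accessors
setMethod("riskThreshold", "RampCoxFit", function(x) x@threshold)
#' @rdname fit-accessors
#' @export
setMethod("coef", "RampCoxFit", function(object, ...) object@coefficients)
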