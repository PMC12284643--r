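#' @include rampmri-package.R
NULL

.PROTOCOLS <- c("GdT1w", "T2w", "FLAIR")
.REGIONS <- c("En", "Ed", "NC", "H")
.STAT_NAMES <- c("mean", "median", "sd", "skewness", "kurtosis")

#' ImageScene: a 3D intensity grid with physical geometry
#'
#' Container for one MRI volume. Physical coordinates of voxel index
#' `(i, j, k)` (1-based) are `origin + (index - 1) * spacing`; all distances
#' in the package are in mm, so spacing must be honoured.
#'
#' @slot voxels 3D numeric array of intensities.
#' @slot spacing per-axis voxel size in mm (length 3, strictly positive).
#' @slot origin physical position of the first voxel in mm (length 3).
#' @slot protocol acquisition protocol tag, one of `"GdT1w"`, `"T2w"`,
#'   `"FLAIR"`.
#' @aliases ImageScene
#' @exportClass ImageScene
setClass("ImageScene",
  representation(voxels = "array", spacing = "numeric", origin = "numeric",
                 protocol = "character"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0), protocol = "GdT1w"))

setValidity("ImageScene", function(object) {
  d <- dim(object@voxels)
  if (length(d) != 3L) return("voxels must be a 3D array")
  if (any(d < 1L)) return("grid dimensions must be >= 1 per axis")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be 3 strictly positive finite values")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be 3 finite values")
  if (any(!is.finite(object@voxels)))
    return("all intensities must be finite")
  if (length(object@protocol) != 1L || !object@protocol %in% .PROTOCOLS)
    return(sprintf("protocol must be one of %s",
                   paste(.PROTOCOLS, collapse = ", ")))
  TRUE
})

#' Construct an ImageScene
#'
#' @param voxels 3D numeric array.
#' @param spacing voxel size in mm (length 3 or scalar).
#' @param origin physical position of the first voxel (mm).
#' @param protocol protocol tag.
#' @return An [ImageScene-class] object.
#' @examples
#' sc <- ImageScene(array(rnorm(27), c(3, 3, 3)), spacing = c(1, 1, 2))
#' spacing(sc)
#' @export
ImageScene <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       protocol = "GdT1w") {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("ImageScene", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin), protocol = protocol)
}

#' DeformationField: per-voxel 3-vector displacements
#'
#' Stores the displacement (mm) of every voxel as produced by a diffeomorphic
#' registration to a reference atlas, on the same grid as its paired
#' [ImageScene-class].
#'
#' @slot field 4D numeric array `[nx, ny, nz, 3]` of displacements in mm.
#' @slot spacing,origin grid geometry (mm), as for `ImageScene`.
#' @aliases DeformationField
#' @exportClass DeformationField
setClass("DeformationField",
  representation(field = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0)))

setValidity("DeformationField", function(object) {
  d <- dim(object@field)
  if (length(d) != 4L) return("field must be a 4D array")
  if (d[4L] != 3L) return("field must have exactly 3 vector components")
  if (any(!is.finite(object@field))) return("field values must be finite")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 strictly positive values")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be 3 finite values")
  TRUE
})

#' Construct a DeformationField
#'
#' @param field 4D numeric array `[nx, ny, nz, 3]`, displacements in mm.
#' @param spacing,origin grid geometry in mm.
#' @return A [DeformationField-class] object.
#' @export
DeformationField <- function(field, spacing = c(1, 1, 1),
                             origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("DeformationField", field = field, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' SegmentationMap: labeled tumor sub-compartments with a brain mask
#'
#' Integer label grid coding the enhancing lesion, peri-tumoral edema, and
#' non-enhancing tumor + cystic core, together with the brain mask on the
#' same grid. The tumor habitat is the union of the three sub-compartments;
#' the parenchyma is the brain minus the habitat.
#'
#' @slot labels 3D integer array; 0 = background, other codes per
#'   `labelDict`.
#' @slot brain 3D logical array, the brain mask.
#' @slot spacing,origin grid geometry (mm).
#' @slot labelDict named integer vector mapping compartments to label codes;
#'   names must be `"En"`, `"Ed"`, `"NC"`.
#' @aliases SegmentationMap
#' @exportClass SegmentationMap
setClass("SegmentationMap",
  representation(labels = "array", brain = "array", spacing = "numeric",
                 origin = "numeric", labelDict = "integer"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0),
            labelDict = c(En = 1L, Ed = 2L, NC = 3L)))

setValidity("SegmentationMap", function(object) {
  if (length(dim(object@labels)) != 3L) return("labels must be a 3D array")
  if (!identical(dim(object@labels), dim(object@brain)))
    return("labels and brain mask must share a grid")
  if (!all(c("En", "Ed", "NC") %in% names(object@labelDict)))
    return("labelDict must name codes for En, Ed, NC")
  if (anyDuplicated(object@labelDict))
    return("labelDict codes must be distinct")
  codes <- unique(as.vector(object@labels))
  if (!all(codes %in% c(0L, object@labelDict)))
    return("labels contain codes absent from labelDict")
  if (any(object@labels != 0L & !object@brain))
    return("tumor labels must lie inside the brain mask")
  TRUE
})

#' Construct a SegmentationMap from a label grid
#'
#' @param labels 3D integer array of compartment codes.
#' @param brain 3D logical brain mask on the same grid.
#' @param spacing,origin grid geometry in mm.
#' @param labelDict named integer vector with entries `En`, `Ed`, `NC`
#'   (defaults 1, 2, 3).
#' @return A [SegmentationMap-class] object.
#' @seealso [segmentationFromMasks()] to build one from three binary masks.
#' @export
SegmentationMap <- function(labels, brain, spacing = c(1, 1, 1),
                            origin = c(0, 0, 0),
                            labelDict = c(En = 1L, Ed = 2L, NC = 3L)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  storage.mode(labels) <- "integer"
  new("SegmentationMap", labels = labels, brain = array(as.logical(brain),
      dim(labels)), spacing = as.numeric(spacing),
      origin = as.numeric(origin),
      labelDict = setNames(as.integer(labelDict), names(labelDict)))
}

#' AnnularBandMap: equidistant annular bands of parenchyma
#'
#' Integer band index per voxel: band `a` (1..m) contains the parenchyma
#' voxels whose Euclidean distance `d` (mm) to the reference surface obeys
#' `(a-1)*w <= d < a*w`; 0 marks voxels beyond band `m`, inside the habitat,
#' or outside the brain.
#'
#' @slot bands 3D integer array of band indices.
#' @slot width band width `w` in mm.
#' @slot nBands band count `m`.
#' @slot spacing,origin grid geometry (mm).
#' @aliases AnnularBandMap
#' @exportClass AnnularBandMap
setClass("AnnularBandMap",
  representation(bands = "array", width = "numeric", nBands = "integer",
                 spacing = "numeric", origin = "numeric"))

setValidity("AnnularBandMap", function(object) {
  if (length(dim(object@bands)) != 3L) return("bands must be a 3D array")
  if (object@width <= 0) return("band width must be positive")
  if (object@nBands < 1L) return("band count must be >= 1")
  vals <- unique(as.vector(object@bands))
  if (any(vals < 0L | vals > object@nBands))
    return("band indices must lie in 0..nBands")
  TRUE
})

#' RampCoxFit: a trained penalized Cox risk model
#'
#' Holds everything estimated on the training set and frozen for test
#' subjects: feature standardization parameters, the selected features with
#' their coefficients, the penalty mixing `alpha`, the regularization
#' strength `lambda`, and the dichotomization threshold for the risk score.
#'
#' @slot features all feature names seen at training time (post filtering).
#' @slot center,scale per-feature standardization parameters.
#' @slot selected names of features with nonzero coefficients.
#' @slot coefficients named coefficients on the standardized scale.
#' @slot alpha elastic-net mixing parameter in \[0, 1\].
#' @slot lambda regularization strength chosen by cross-validation.
#' @slot threshold risk-score dichotomization threshold (training-derived).
#' @slot thresholdRule rule used to set the threshold.
#' @slot cvTable per-alpha cross-validation summary.
#' @aliases RampCoxFit
#' @exportClass RampCoxFit
setClass("RampCoxFit",
  representation(features = "character", center = "numeric",
                 scale = "numeric", selected = "character",
                 coefficients = "numeric", alpha = "numeric",
                 lambda = "numeric", threshold = "numeric",
                 thresholdRule = "character", cvTable = "data.frame"))

setValidity("RampCoxFit", function(object) {
  if (length(object@alpha) != 1L || object@alpha < 0 || object@alpha > 1)
    return("alpha must lie in [0, 1]")
  if (length(object@coefficients) != length(object@selected))
    return("one coefficient per selected feature is required")
  if (!all(object@selected %in% object@features))
    return("selected features must be a subset of the training features")
  TRUE
})

setMethod("show", "ImageScene", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageScene [%s]: %d x %d x %d voxels, spacing %s mm\n",
              object@protocol, d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x ")))
  cat(sprintf("  intensity range: [%.4g, %.4g]\n",
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "DeformationField", function(object) {
  d <- dim(object@field)
  mag <- sqrt(object@field[, , , 1]^2 + object@field[, , , 2]^2 +
              object@field[, , , 3]^2)
  cat(sprintf("DeformationField: %d x %d x %d voxels, |u| up to %.3g mm\n",
              d[1], d[2], d[3], max(mag)))
})

setMethod("show", "SegmentationMap", function(object) {
  counts <- vapply(c("En", "Ed", "NC"), function(r)
    sum(object@labels == object@labelDict[[r]]), integer(1))
  cat(sprintf(
    "SegmentationMap: |En|=%d |Ed|=%d |NC|=%d voxels, brain %d voxels\n",
    counts["En"], counts["Ed"], counts["NC"], sum(object@brain)))
})

setMethod("show", "AnnularBandMap", function(object) {
  tab <- tabulate(object@bands[object@bands > 0L], object@nBands)
  cat(sprintf("AnnularBandMap: %d bands of %.3g mm; voxels per band:\n",
              object@nBands, object@width))
  cat(" ", paste(tab, collapse = " "), "\n")
})

setMethod("show", "RampCoxFit", function(object) {
  cat(sprintf(
    "RampCoxFit: alpha=%.3g lambda=%.4g, %d/%d features selected\n",
    object@alpha, object@lambda, length(object@selected),
    length(object@features)))
  cat(sprintf("  threshold (%s rule): %.4g\n", object@thresholdRule,
              object@threshold))
  if (length(object@selected)) {
    idx <- order(abs(object@coefficients), decreasing = TRUE)
    top <- head(idx, 5L)
    cat("  top coefficients:\n")
    for (i in top)
      cat(sprintf("    %s: %+.4g\n", object@selected[i],
                  object@coefficients[i]))
  }
})
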