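#' @include AllClasses.R utils-geometry.R
NULL

#' Build a SegmentationMap from three binary compartment masks
#'
#' Rejects overlapping compartments: the enhancing lesion, edema, and
#' non-enhancing tumor + cystic core must be pairwise disjoint.
#'
#' @param en,ed,nc logical arrays for the three sub-compartments.
#' @param brain logical brain mask on the same grid.
#' @param spacing,origin grid geometry in mm.
#' @return A [SegmentationMap-class].
#' @export
segmentationFromMasks <- function(en, ed, nc, brain, spacing = c(1, 1, 1),
                                  origin = c(0, 0, 0)) {
  if (!identical(dim(en), dim(ed)) || !identical(dim(en), dim(nc)) ||
      !identical(dim(en), dim(brain)))
    stop("all masks must share a grid")
  en <- en > 0; ed <- ed > 0; nc <- nc > 0
  if (any(en & ed) || any(en & nc) || any(ed & nc))
    stop("sub-compartment masks overlap; labels must be pairwise disjoint")
  labels <- array(0L, dim(en))
  labels[en] <- 1L; labels[ed] <- 2L; labels[nc] <- 3L
  SegmentationMap(labels, brain, spacing = spacing, origin = origin)
}

#' Extract one region mask from a SegmentationMap
#'
#' @param seg a [SegmentationMap-class].
#' @param region `"En"`, `"Ed"`, `"NC"`, or `"H"` (the habitat union).
#' @return Logical array.
#' @export
regionMask <- function(seg, region = c("H", "En", "Ed", "NC")) {
  region <- match.arg(region)
  if (region == "H") return(buildHabitat(seg))
  labelData(seg) == labelDict(seg)[[region]]
}

#' Build the tumor habitat mask
#'
#' The habitat is the union of the three tumor sub-compartments. Because the
#' compartments live on one integer label grid they are disjoint by
#' construction, so the habitat voxel count is the sum of the compartment
#' counts.
#'
#' @param seg a [SegmentationMap-class].
#' @return Logical array; errors if the segmentation is empty.
#' @export
buildHabitat <- function(seg) {
  hab <- labelData(seg) %in% labelDict(seg)[c("En", "Ed", "NC")]
  hab <- array(hab, dim(labelData(seg)))
  if (!any(hab)) stop("empty segmentation: no tumor sub-compartment voxels")
  hab
}

#' Parenchyma mask (brain minus habitat)
#'
#' @param seg a [SegmentationMap-class].
#' @return Logical array of normal-appearing brain voxels.
#' @export
parenchymaMask <- function(seg) {
  brainMask(seg) & !buildHabitat(seg)
}

#' Tumor centroid in physical coordinates
#'
#' Unweighted mean of the physical (mm) coordinates of the habitat voxels.
#'
#' @param mask logical array (typically the habitat).
#' @param spacing,origin grid geometry in mm.
#' @return Numeric length-3 point in mm.
#' @export
tumorCentroid <- function(mask, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty habitat: centroid undefined")
  unname(colMeans(.physCoords(idx, spacing, origin)))
}

#' Euclidean distance (mm) to the nearest voxel of a mask
#'
#' Exact anisotropic Euclidean distance transform (lower-envelope
#' algorithm), honouring the per-axis spacing.
#'
#' @param mask logical array of reference voxels.
#' @param spacing per-axis spacing in mm.
#' @return Numeric array of distances in mm (0 inside the mask).
#' @export
distanceToMask <- function(mask, spacing = c(1, 1, 1)) {
  if (!any(mask)) stop("reference mask is empty")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  d2 <- .edt3d_sq(as.logical(mask), as.integer(dim(mask)),
                  as.numeric(spacing))
  array(sqrt(d2), dim(mask))
}

#' Build equidistant annular bands around the tumor
#'
#' Divides the parenchyma into `m` annular bands of width `w` mm measured by
#' Euclidean distance (in physical mm) from the outer surface of the
#' reference region: band `a` holds the parenchyma voxels with
#' `(a-1)*w <= d < a*w` (half-open bins). Voxels inside the habitat keep
#' index 0, as do voxels outside the brain or beyond band `m` ("to the skull
#' boundary": bands are clipped to the brain mask).
#'
#' @param habitat logical array: the reference region whose surface anchors
#'   the distance (usually the habitat union).
#' @param brain logical brain mask.
#' @param spacing per-axis spacing in mm.
#' @param width band width `w` in mm (default 5).
#' @param nBands band count `m` (default 12).
#' @param origin grid origin in mm.
#' @param exclude optional logical array removed from the banded domain in
#'   addition to `habitat` itself (e.g. the full habitat when banding from a
#'   single sub-compartment's surface).
#' @return An [AnnularBandMap-class].
#' @export
buildAnnularBands <- function(habitat, brain, spacing = c(1, 1, 1),
                              width = 5, nBands = 12L, origin = c(0, 0, 0),
                              exclude = NULL) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (width <= 0) stop("band width must be positive")
  if (nBands < 1L) stop("band count must be >= 1")
  if (!identical(dim(habitat), dim(brain)))
    stop("habitat and brain mask must share a grid")
  habitat <- habitat > 0
  if (any(habitat & !brain)) stop("habitat must lie inside the brain mask")
  domain <- brain & !habitat
  if (!is.null(exclude)) domain <- domain & !(exclude > 0)
  if (!any(domain))
    stop("no parenchyma voxels: habitat fills the brain mask")
  d <- distanceToMask(habitat, spacing)
  a <- floor(d / width) + 1
  bands <- array(0L, dim(habitat))
  keep <- domain & a >= 1 & a <= nBands
  bands[keep] <- as.integer(a[keep])
  new("AnnularBandMap", bands = bands, width = as.numeric(width),
      nBands = as.integer(nBands), spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}
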