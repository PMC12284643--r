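#' @include AllClasses.R utils-geometry.R
NULL

.niftiGeometry <- function(img) {
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("NIfTI header carries non-positive spacing; refusing to guess")
  xf <- RNifti::xform(img)
  list(spacing = as.numeric(sp), origin = as.numeric(xf[1:3, 4]))
}

#' Read a 3D NIfTI volume as an ImageScene
#'
#' Geometry (spacing, origin) is populated from the NIfTI header; the reader
#' fails rather than guessing missing or degenerate spacing.
#'
#' @param path path to a `.nii`/`.nii.gz` file containing a 3D payload.
#' @param protocol protocol tag to attach (`"GdT1w"`, `"T2w"`, `"FLAIR"`).
#' @return An [ImageScene-class].
#' @seealso [readDeformationField()] for 4D vector payloads,
#'   [writeVolume()] for the inverse operation.
#' @export
readVolume <- function(path, protocol = "GdT1w") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4L] == 1L) {
    img <- array(img, d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L)
    stop("expected a 3D payload, got ", length(d), " dimensions: ", path)
  vox <- array(as.numeric(img), d)
  if (any(!is.finite(vox))) stop("non-finite voxels in ", path)
  geo <- .niftiGeometry(img)
  ImageScene(vox, spacing = geo$spacing, origin = geo$origin,
             protocol = protocol)
}

#' Read a 3-component displacement field from a 4D NIfTI
#'
#' @param path path to a 4D NIfTI whose 4th dimension holds the 3 vector
#'   components.
#' @param voxelUnits if `TRUE` the stored components are in voxel units and
#'   are converted to mm by multiplying with the axis spacing; the default
#'   expects mm.
#' @return A [DeformationField-class] with displacements in mm.
#' @export
readDeformationField <- function(path, voxelUnits = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 5L && d[4L] == 1L && d[5L] == 3L) {
    # ITK-style vector image (x, y, z, 1, 3)
    img <- array(img, c(d[1:3], 3L))
    d <- dim(img)
  }
  if (length(d) != 4L || d[4L] != 3L)
    stop("expected a 4D NIfTI with 3 components, got dims ",
         paste(d, collapse = "x"), ": ", path)
  fld <- array(as.numeric(img), d)
  if (any(!is.finite(fld))) stop("non-finite field values in ", path)
  geo <- .niftiGeometry(img)
  if (voxelUnits)
    for (k in 1:3) fld[, , , k] <- fld[, , , k] * geo$spacing[k]
  DeformationField(fld, spacing = geo$spacing, origin = geo$origin)
}

.writeNifti <- function(arr, spacing, origin, path) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(spacing, rep(1, length(dim(arr)) - 3L))
  m <- diag(4)
  diag(m)[1:3] <- spacing
  m[1:3, 4] <- origin
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write imaging objects to NIfTI
#'
#' @param x an [ImageScene-class], [DeformationField-class], or a bare
#'   array (then `spacing`/`origin` apply).
#' @param path output `.nii`/`.nii.gz` path.
#' @param spacing,origin geometry used when `x` is a bare array.
#' @return The path, invisibly.
#' @export
writeVolume <- function(x, path, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is(x, "ImageScene"))
    return(.writeNifti(voxelData(x), spacing(x), origin(x), path))
  if (is(x, "DeformationField"))
    return(.writeNifti(fieldData(x), spacing(x), origin(x), path))
  .writeNifti(x, spacing, origin, path)
}

#' Read a multi-label segmentation plus brain mask
#'
#' @param path NIfTI with integer compartment labels.
#' @param brainPath NIfTI with a binary brain mask on the same grid.
#' @param labelDict named integer vector with entries `En`, `Ed`, `NC`;
#'   default `c(En = 1, Ed = 2, NC = 3)`.
#' @return A [SegmentationMap-class].
#' @export
readSegmentation <- function(path, brainPath,
                             labelDict = c(En = 1L, Ed = 2L, NC = 3L)) {
  seg <- readVolume(path)
  brain <- readVolume(brainPath)
  .stopIfGeometryMismatch(seg, brain, "segmentation and brain mask")
  lab <- voxelData(seg)
  if (any(abs(lab - round(lab)) > 1e-6))
    stop("segmentation labels must be integers")
  SegmentationMap(array(as.integer(round(lab)), dim(lab)),
                  voxelData(brain) > 0.5, spacing = spacing(seg),
                  origin = origin(seg), labelDict = labelDict)
}

#' Z-score intensity standardization within a mask
#'
#' Standardizes the in-mask intensities to mean 0 and standard deviation 1;
#' out-of-mask voxels are set to 0. This is the per-scan intensity
#' harmonization step applied before texture extraction so that scans from
#' different scanners and field strengths share one intensity scale.
#'
#' @param scene an [ImageScene-class].
#' @param mask logical array on the same grid (typically the brain mask).
#' @return A standardized [ImageScene-class].
#' @export
zNormalize <- function(scene, mask) {
  vox <- voxelData(scene)
  if (!identical(dim(vox), dim(mask)))
    stop("mask grid does not match the scene")
  mask <- array(as.logical(mask), dim(mask))
  v <- vox[mask]
  if (length(v) < 2L) stop("mask must contain at least 2 voxels")
  s <- sd(v)
  if (!is.finite(s) || s <= 0)
    stop("constant in-mask intensities; z-normalization undefined")
  out <- array(0, dim(vox))
  out[mask] <- (v - mean(v)) / s
  ImageScene(out, spacing = spacing(scene), origin = origin(scene),
             protocol = protocol(scene))
}
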