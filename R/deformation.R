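#' @include AllClasses.R utils-geometry.R utils-stats.R habitat.R
NULL

.ANGLE_EPS <- 1e-8

#' Per-voxel deformation magnitude
#'
#' Euclidean norm (mm) of the 3-component displacement at every voxel.
#'
#' @param field a [DeformationField-class].
#' @return Numeric 3D array of magnitudes (mm).
#' @export
deformationMagnitude <- function(field) {
  f <- fieldData(field)
  array(sqrt(f[, , , 1]^2 + f[, , , 2]^2 + f[, , , 3]^2), dim(f)[1:3])
}

#' Per-voxel deformation angle relative to the tumor centroid
#'
#' The angle `theta = arccos(x . y / (|x| |y|))` (degrees) between each
#' displacement vector `x` and the vector `y` that connects the voxel to the
#' tumor centroid (`y = centroid - voxel position`). Under this convention a
#' purely outward displacement (mass effect pushing tissue away from the
#' tumor) yields angles near 180 degrees and a purely inward one angles near
#' 0. Voxels where `|x|` or `|y|` falls below 1e-8 mm get `NA` and are
#' excluded from angle statistics and histograms downstream.
#'
#' @param field a [DeformationField-class].
#' @param centroid tumor centroid in physical mm (length 3).
#' @return Numeric 3D array of angles in `[0, 180]` degrees, `NA` where
#'   undefined.
#' @export
deformationAngle <- function(field, centroid) {
  if (length(centroid) != 3L || any(!is.finite(centroid)))
    stop("centroid must be a finite 3D point")
  f <- fieldData(field)
  dims <- dim(f)[1:3]
  g <- .coordGrids(dims, spacing(field), origin(field))
  yx <- centroid[1] - g$x
  yy <- centroid[2] - g$y
  yz <- centroid[3] - g$z
  nx <- sqrt(f[, , , 1]^2 + f[, , , 2]^2 + f[, , , 3]^2)
  ny <- sqrt(yx^2 + yy^2 + yz^2)
  dt <- f[, , , 1] * yx + f[, , , 2] * yy + f[, , , 3] * yz
  cosv <- dt / (nx * ny)
  cosv[nx <= .ANGLE_EPS | ny <= .ANGLE_EPS] <- NA_real_
  cosv <- pmin(1, pmax(-1, cosv))
  array(acos(cosv) * 180 / pi, dims)
}

#' Five summary statistics of a scalar map within one band
#'
#' @param values numeric 3D array (e.g. deformation magnitudes or angles;
#'   `NA`s are excluded).
#' @param bands an [AnnularBandMap-class].
#' @param a band index (1..m). An empty band yields the all-zero fill.
#' @return Named numeric vector of length 5 (see [fiveStats()]).
#' @export
bandStatistics <- function(values, bands, a) {
  stopifnot(a >= 1L, a <= nBands(bands))
  fiveStats(values[bandIndex(bands) == a])
}

#' Fixed-width angle histogram within one band
#'
#' Counts the in-band angles over the six 30-degree intervals
#' `[0,30), [30,60), [60,90), [90,120), [120,150), [150,180]`. Masked
#' (undefined) angles are excluded; counts are raw by default.
#'
#' @param angles numeric array from [deformationAngle()].
#' @param bands an [AnnularBandMap-class].
#' @param a band index (1..m).
#' @param frequencies if `TRUE`, return relative frequencies instead of
#'   counts (an empty band then yields zeros).
#' @return Numeric vector of 6 counts (or frequencies).
#' @export
quantizeAngles <- function(angles, bands, a, frequencies = FALSE) {
  stopifnot(a >= 1L, a <= nBands(bands))
  v <- angles[bandIndex(bands) == a]
  v <- v[!is.na(v)]
  bin <- pmin(floor(v / 30) + 1L, 6L)
  counts <- tabulate(bin, 6L)
  names(counts) <- sprintf("bin%d", 1:6)
  if (frequencies && sum(counts) > 0) counts <- counts / sum(counts)
  counts
}

#' Assemble the deformation-heterogeneity descriptor F_B
#'
#' Concatenates, over the `m` annular bands, (1) the five statistics of the
#' per-voxel deformation magnitudes, (2) the five statistics of the
#' deformation angles, and (3) the 6-interval angle histogram. With the
#' defaults (m = 12 bands of 5 mm, 6 intervals) the descriptor has length
#' `12 * (5 + 5 + 6) = 192`, split 60/60/72 across the three blocks. Bands
#' are always iterated 1..m (empty bands contribute the zero fill) so the
#' length is constant across subjects.
#'
#' @param field a [DeformationField-class].
#' @param bands an [AnnularBandMap-class].
#' @param centroid tumor centroid in mm.
#' @param frequencies passed to [quantizeAngles()].
#' @return Named numeric vector with deterministic block order: all
#'   magnitude statistics by band, all angle statistics by band, all
#'   histogram bins by band.
#' @export
assembleFB <- function(field, bands, centroid, frequencies = FALSE) {
  m <- nBands(bands)
  mag <- deformationMagnitude(field)
  ang <- deformationAngle(field, centroid)
  bandIdx <- bandIndex(bands)
  magBlock <- numeric(0)
  angBlock <- numeric(0)
  histBlock <- numeric(0)
  for (a in seq_len(m)) {
    inBand <- bandIdx == a
    ms <- fiveStats(mag[inBand])
    as_ <- fiveStats(ang[inBand])
    hb <- quantizeAngles(ang, bands, a, frequencies = frequencies)
    names(ms) <- sprintf("mag.band%02d.%s", a, .STAT_NAMES)
    names(as_) <- sprintf("ang.band%02d.%s", a, .STAT_NAMES)
    names(hb) <- sprintf("angbin.band%02d.bin%d", a, 1:6)
    magBlock <- c(magBlock, ms)
    angBlock <- c(angBlock, as_)
    histBlock <- c(histBlock, hb)
  }
  out <- c(magBlock, angBlock, histBlock)
  attr(out, "blocks") <- c(magnitude = length(magBlock),
                           angle = length(angBlock),
                           histogram = length(histBlock))
  out
}
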