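#' @include AllClasses.R utils-geometry.R utils-stats.R
NULL

.HARALICK_STATS <- c("energy", "contrast", "correlation", "variance", "idm",
                     "sumAverage", "sumVariance", "sumEntropy", "entropy",
                     "differenceVariance", "differenceEntropy", "imc1",
                     "imc2")

.LAWS_KERNELS <- list(
  L5 = c(1, 4, 6, 4, 1),
  E5 = c(-1, -2, 0, 2, 1),
  S5 = c(-1, 0, 2, 0, -1),
  W5 = c(-1, 2, 0, -2, 1),
  R5 = c(1, -4, 6, -4, 1))

# the 13 unique 3D co-occurrence directions (half of the 26-neighbourhood)
.OFFSETS_3D <- local({
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- g[, 3] > 0 | (g[, 3] == 0 & (g[, 2] > 0 | (g[, 2] == 0 & g[, 1] > 0)))
  m <- g[keep, , drop = FALSE]
  storage.mode(m) <- "integer"
  m
})

.OFFSETS_2D <- local({
  m <- rbind(c(1L, 0L, 0L), c(1L, 1L, 0L), c(0L, 1L, 0L), c(-1L, 1L, 0L))
  colnames(m) <- c("dx", "dy", "dz")
  m
})

#' Texture family parameterization
#'
#' Collects the tunable parameters of the five texture families. With the
#' defaults the inventory has exactly `5 + 13*3 + 125 + 8*4 + 13 = 214`
#' per-voxel maps.
#'
#' @param haralickWindows sliding-window edge lengths for the co-occurrence
#'   maps (odd integers).
#' @param haralickLevels number of equal-width gray-level bins used for
#'   co-occurrence quantization (over the in-mask intensity range).
#' @param gaborOrientations number of in-plane Gabor orientations (evenly
#'   spaced over 0..180 degrees).
#' @param gaborWavelengths Gabor wavelengths in voxels.
#' @param collageWindow window edge length for the gradient-orientation
#'   co-occurrence (CoLlAGe) maps.
#' @param collageBins number of orientation bins over `[0, pi)`.
#' @return A list of class `rampTextureParams`.
#' @export
textureParams <- function(haralickWindows = c(3L, 5L, 7L),
                          haralickLevels = 64L,
                          gaborOrientations = 8L,
                          gaborWavelengths = c(2 * sqrt(2), 4, 4 * sqrt(2), 8),
                          collageWindow = 5L,
                          collageBins = 8L) {
  stopifnot(all(haralickWindows %% 2 == 1), haralickLevels >= 2,
            gaborOrientations >= 1, all(gaborWavelengths > 0),
            collageWindow %% 2 == 1, collageBins >= 2)
  structure(list(haralickWindows = as.integer(haralickWindows),
                 haralickLevels = as.integer(haralickLevels),
                 gaborOrientations = as.integer(gaborOrientations),
                 gaborWavelengths = as.numeric(gaborWavelengths),
                 collageWindow = as.integer(collageWindow),
                 collageBins = as.integer(collageBins)),
            class = "rampTextureParams")
}

.gaborAngles <- function(params)
  seq(0, 180, length.out = params$gaborOrientations + 1L)[
    seq_len(params$gaborOrientations)]

#' Advertised texture-map inventory
#'
#' @param params a [textureParams()] list.
#' @return A data.frame with columns `family` and `name`, one row per map;
#'   214 rows under the defaults.
#' @export
textureInventory <- function(params = textureParams()) {
  grad <- paste0("gradient.", c("dx", "dy", "dz", "magnitude", "laplacian"))
  har <- as.vector(t(outer(params$haralickWindows, .HARALICK_STATS,
                           function(w, s) sprintf("haralick.w%d.%s", w, s))))
  kn <- names(.LAWS_KERNELS)
  laws <- paste0("laws.", as.vector(outer(kn, outer(kn, kn, paste0),
                                          paste0)))
  laws <- sort(laws)
  ang <- .gaborAngles(params)
  gab <- as.vector(t(outer(seq_along(ang), seq_along(params$gaborWavelengths),
    function(i, j) sprintf("gabor.th%03d.wl%.4g", round(ang[i]),
                           params$gaborWavelengths[j]))))
  col <- paste0("collage.", .HARALICK_STATS)
  data.frame(
    family = rep(c("gradient", "haralick", "laws", "gabor", "collage"),
                 c(length(grad), length(har), length(laws), length(gab),
                   length(col))),
    name = c(grad, har, laws, gab, col),
    stringsAsFactors = FALSE)
}

# quantize in-mask intensities to 1..L over the in-mask range; 0 outside
.quantizeLevels <- function(vox, mask, levels) {
  lab <- array(0L, dim(vox))
  v <- vox[mask]
  rng <- range(v)
  if (diff(rng) <= 0) {
    lab[mask] <- 1L
  } else {
    q <- floor((v - rng[1]) / diff(rng) * levels) + 1L
    lab[mask] <- pmin(as.integer(q), levels)
  }
  lab
}

#' Gradient texture maps
#'
#' Finite-difference partial derivatives (per mm), gradient magnitude, and
#' Laplacian of the intensity volume.
#'
#' @param scene an [ImageScene-class] (typically z-normalized).
#' @return Named list of five 3D arrays.
#' @export
computeGradientMaps <- function(scene) {
  v <- voxelData(scene)
  sp <- spacing(scene)
  dx <- .diffAxis(v, 1L, sp[1])
  dy <- .diffAxis(v, 2L, sp[2])
  dz <- .diffAxis(v, 3L, sp[3])
  lap <- .diffAxis(dx, 1L, sp[1]) + .diffAxis(dy, 2L, sp[2]) +
    .diffAxis(dz, 3L, sp[3])
  list(gradient.dx = dx, gradient.dy = dy, gradient.dz = dz,
       gradient.magnitude = sqrt(dx^2 + dy^2 + dz^2),
       gradient.laplacian = lap)
}

#' Haralick co-occurrence texture maps
#'
#' For each sliding-window size, quantizes the in-mask intensities to
#' `haralickLevels` equal-width gray levels and computes the 13 classical
#' co-occurrence statistics of the symmetric, direction-averaged (13 3D
#' directions) gray-level co-occurrence matrix accumulated over the window
#' around each voxel. Windows are clipped at the volume border and pairs
#' must lie entirely inside the window and the mask.
#'
#' @param scene an [ImageScene-class].
#' @param mask logical array restricting both the quantization range and
#'   the computed voxels; defaults to the full grid.
#' @param params a [textureParams()] list.
#' @return Named list of `13 * length(haralickWindows)` 3D arrays
#'   (zero outside the mask).
#' @export
computeHaralickMaps <- function(scene, mask = NULL,
                                params = textureParams()) {
  v <- voxelData(scene)
  d <- dim(v)
  if (is.null(mask)) mask <- array(TRUE, d)
  if (!identical(dim(mask), d)) stop("mask grid does not match the scene")
  mask <- array(as.logical(mask), d)
  if (!any(mask)) stop("empty analysis mask")
  lab <- .quantizeLevels(v, mask, params$haralickLevels)
  out <- list()
  for (w in params$haralickWindows) {
    if (w > min(d)) stop("window larger than volume: ", w)
    stats <- .glcm_window_stats(as.integer(lab), as.integer(d),
                                as.logical(mask), as.integer((w - 1) / 2),
                                params$haralickLevels, .OFFSETS_3D)
    for (s in seq_along(.HARALICK_STATS)) {
      out[[sprintf("haralick.w%d.%s", w, .HARALICK_STATS[s])]] <-
        array(stats[, s], d)
    }
  }
  out
}

#' Laws texture-energy maps
#'
#' All `5^3 = 125` separable 3D filters built from the classical 1D kernels
#' L5 (level), E5 (edge), S5 (spot), W5 (wave), R5 (ripple), applied with
#' reflect padding. Map `laws.ABC` applies kernel A along x, B along y, C
#' along z.
#'
#' @param scene an [ImageScene-class].
#' @return Named list of 125 3D arrays (sorted by name).
#' @export
computeLawsMaps <- function(scene) {
  v <- voxelData(scene)
  out <- list()
  for (k1 in names(.LAWS_KERNELS)) {
    p1 <- .convAxis(v, .LAWS_KERNELS[[k1]], 1L)
    for (k2 in names(.LAWS_KERNELS)) {
      p2 <- .convAxis(p1, .LAWS_KERNELS[[k2]], 2L)
      for (k3 in names(.LAWS_KERNELS)) {
        out[[paste0("laws.", k1, k2, k3)]] <-
          .convAxis(p2, .LAWS_KERNELS[[k3]], 3L)
      }
    }
  }
  out[order(names(out))]
}

.gaborKernels <- function(theta, wavelength) {
  sigma <- 0.56 * wavelength
  r <- max(2L, ceiling(2.5 * sigma))
  x <- matrix(-r:r, 2 * r + 1, 2 * r + 1)
  y <- t(x)
  th <- theta * pi / 180
  xr <- x * cos(th) + y * sin(th)
  yr <- -x * sin(th) + y * cos(th)
  env <- exp(-(xr^2 + yr^2) / (2 * sigma^2))
  even <- env * cos(2 * pi * xr / wavelength)
  odd <- env * sin(2 * pi * xr / wavelength)
  even <- even - env * sum(even) / sum(env)  # remove the DC response
  list(even = even, odd = odd)
}

#' Gabor magnitude maps
#'
#' Quadrature Gabor filter bank applied per axial slice (2D), with
#' DC-corrected even kernels so a constant image gives zero response. Each
#' map is the magnitude `sqrt(even^2 + odd^2)` of the complex response for
#' one orientation/wavelength pair.
#'
#' @param scene an [ImageScene-class].
#' @param mask optional logical array: only slices intersecting the mask
#'   are processed and only in-mask pixels computed (others are 0).
#' @param params a [textureParams()] list.
#' @return Named list of `orientations * wavelengths` 3D arrays.
#' @export
computeGaborMaps <- function(scene, mask = NULL, params = textureParams()) {
  v <- voxelData(scene)
  d <- dim(v)
  angles <- .gaborAngles(params)
  slices <- seq_len(d[3])
  if (!is.null(mask)) {
    if (!identical(dim(mask), d)) stop("mask grid does not match the scene")
    slices <- which(apply(mask, 3L, any))
  }
  out <- list()
  for (i in seq_along(angles)) {
    for (wl in params$gaborWavelengths) {
      ker <- .gaborKernels(angles[i], wl)
      resp <- array(0, d)
      for (z in slices) {
        want <- if (is.null(mask)) NULL else mask[, , z]
        ev <- .conv2_reflect(v[, , z, drop = TRUE], ker$even, want)
        od <- .conv2_reflect(v[, , z, drop = TRUE], ker$odd, want)
        resp[, , z] <- sqrt(ev^2 + od^2)
      }
      out[[sprintf("gabor.th%03d.wl%.4g", round(angles[i]), wl)]] <- resp
    }
  }
  out
}

# 2D central differences with replicated edges
.diff2d <- function(m, axis) {
  n <- dim(m)[axis]
  ip <- pmin(seq_len(n) + 1L, n)
  im <- pmax(seq_len(n) - 1L, 1L)
  den <- ip - im
  if (axis == 1L) (m[ip, , drop = FALSE] - m[im, , drop = FALSE]) / den
  else sweep(m[, ip, drop = FALSE] - m[, im, drop = FALSE], 2L, den, `/`)
}

#' CoLlAGe maps: co-occurrence of local anisotropic gradient orientations
#'
#' Per axial slice: the dominant gradient orientation at each voxel is the
#' principal component of the local gradient vectors over the window
#' (computed via the windowed 2D structure tensor), mapped to `[0, pi)` and
#' quantized into `collageBins` orientation bins; the 13 co-occurrence
#' statistics of the quantized orientation labels over the same window give
#' the 13 maps. Voxels whose window carries no gradient energy are flagged
#' degenerate and set to 0.
#'
#' @param scene an [ImageScene-class].
#' @param mask optional logical array of voxels to compute.
#' @param params a [textureParams()] list.
#' @return Named list of 13 3D arrays; attribute `degenerate` marks flagged
#'   voxels.
#' @export
computeCollageMaps <- function(scene, mask = NULL,
                               params = textureParams()) {
  v <- voxelData(scene)
  d <- dim(v)
  if (is.null(mask)) mask <- array(TRUE, d)
  if (!identical(dim(mask), d)) stop("mask grid does not match the scene")
  mask <- array(as.logical(mask), d)
  w <- params$collageWindow
  rad <- as.integer((w - 1) / 2)
  box <- matrix(1, w, w)
  maps <- lapply(seq_len(13L), function(i) array(0, d))
  degenerate <- array(FALSE, d)
  for (z in which(apply(mask, 3L, any))) {
    sl <- v[, , z, drop = TRUE]
    gx <- .diff2d(sl, 1L)
    gy <- .diff2d(sl, 2L)
    jxx <- .conv2_reflect(gx * gx, box, NULL)
    jyy <- .conv2_reflect(gy * gy, box, NULL)
    jxy <- .conv2_reflect(gx * gy, box, NULL)
    energy <- jxx + jyy
    theta <- 0.5 * atan2(2 * jxy, jxx - jyy)
    theta[theta < 0] <- theta[theta < 0] + pi
    lab <- pmin(floor(theta / pi * params$collageBins) + 1L,
                params$collageBins)
    lab[energy <= 1e-12] <- 0L
    storage.mode(lab) <- "integer"
    mz <- mask[, , z]
    stats <- .glcm_window_stats(as.vector(lab), c(d[1:2], 1L),
                                as.vector(mz), rad, params$collageBins,
                                .OFFSETS_2D)
    deg <- mz & (lab == 0L)
    for (s in seq_len(13L)) {
      pl <- matrix(stats[, s], d[1], d[2])
      pl[deg] <- 0
      maps[[s]][, , z] <- pl
    }
    degenerate[, , z] <- deg
  }
  names(maps) <- paste0("collage.", .HARALICK_STATS)
  attr(maps, "degenerate") <- degenerate
  maps
}

#' Compute the full texture-map inventory
#'
#' Runs all five families and returns the maps in the fixed inventory order
#' (gradient, Haralick, Laws, Gabor, CoLlAGe); 214 maps under the default
#' parameters.
#'
#' @param scene an [ImageScene-class] (z-normalize first).
#' @param mask optional logical array restricting the windowed families
#'   (Haralick, Gabor, CoLlAGe) and their quantization range.
#' @param params a [textureParams()] list.
#' @return Named list of 3D arrays matching [textureInventory()].
#' @export
computeTextureMaps <- function(scene, mask = NULL,
                               params = textureParams()) {
  maps <- c(computeGradientMaps(scene),
            computeHaralickMaps(scene, mask, params),
            computeLawsMaps(scene),
            computeGaborMaps(scene, mask, params),
            computeCollageMaps(scene, mask, params))
  inv <- textureInventory(params)
  if (!identical(names(maps), inv$name))
    stop("internal error: realized inventory does not match the contract")
  maps
}

#' Summarize texture maps over a region
#'
#' Five first-order statistics (see [fiveStats()]) of each map over the
#' region voxels, in the fixed map order; `214 * 5 = 1070` values under the
#' default inventory.
#'
#' @param maps named list of 3D arrays from [computeTextureMaps()].
#' @param region nonempty logical array.
#' @return Named numeric vector (`<map>.<stat>`).
#' @export
summarizeTexture <- function(maps, region) {
  if (!any(region)) stop("empty region")
  out <- lapply(names(maps), function(nm) {
    s <- fiveStats(maps[[nm]][region])
    names(s) <- paste(nm, .STAT_NAMES, sep = ".")
    s
  })
  unlist(out)
}
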