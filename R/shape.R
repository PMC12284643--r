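#' @include AllClasses.R utils-geometry.R utils-stats.R
NULL

# first and second spacing-aware derivatives of a smoothed mask
.levelSetDerivs <- function(phi, sp) {
  fx <- .diffAxis(phi, 1L, sp[1]); fy <- .diffAxis(phi, 2L, sp[2])
  fz <- .diffAxis(phi, 3L, sp[3])
  list(fx = fx, fy = fy, fz = fz,
       fxx = .diffAxis(fx, 1L, sp[1]), fyy = .diffAxis(fy, 2L, sp[2]),
       fzz = .diffAxis(fz, 3L, sp[3]), fxy = .diffAxis(fx, 2L, sp[2]),
       fxz = .diffAxis(fx, 3L, sp[3]), fyz = .diffAxis(fy, 3L, sp[3]))
}

# voxels of the mask with at least one 6-neighbour outside it
.surfaceVoxels <- function(mask) {
  d <- dim(mask)
  shift <- function(ax, by) {
    idx <- pmax(pmin(seq_len(d[ax]) + by, d[ax]), 1L)
    args <- rep(list(quote(expr = )), 3L)
    args[[ax]] <- idx
    do.call(`[`, c(list(mask), args, list(drop = FALSE)))
  }
  interiorish <- shift(1L, 1L) & shift(1L, -1L) & shift(2L, 1L) &
    shift(2L, -1L) & shift(3L, 1L) & shift(3L, -1L)
  mask & !interiorish
}

#' Principal surface curvatures of a binary region
#'
#' Computes the principal curvatures (1/mm) of the implicit surface of the
#' region: the mask is smoothed with a separable Gaussian (sigma in voxels)
#' and the mean and Gaussian curvatures of its level set are evaluated at
#' the mask's surface voxels from spacing-aware first and second
#' derivatives; `kappa1 >= kappa2` with the convention that a convex region
#' (sphere) has positive curvatures.
#'
#' @param mask logical 3D array with at least 4 voxels.
#' @param spacing per-axis spacing in mm.
#' @param sigma Gaussian smoothing level in voxels (default 1.5).
#' @return A list with numeric vectors `k1`, `k2` (per surface voxel) and
#'   the surface voxel index matrix `surface`.
#' @export
surfaceCurvatures <- function(mask, spacing = c(1, 1, 1), sigma = 1.5) {
  mask <- mask > 0
  if (sum(mask) < 4L) stop("mask too small for a meaningful surface (< 4 voxels)")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  phi <- .gaussSmooth(array(as.numeric(mask), dim(mask)), sigma)
  dv <- .levelSetDerivs(phi, spacing)
  surf <- which(.surfaceVoxels(mask))
  fx <- dv$fx[surf]; fy <- dv$fy[surf]; fz <- dv$fz[surf]
  fxx <- dv$fxx[surf]; fyy <- dv$fyy[surf]; fzz <- dv$fzz[surf]
  fxy <- dv$fxy[surf]; fxz <- dv$fxz[surf]; fyz <- dv$fyz[surf]
  g2 <- fx^2 + fy^2 + fz^2
  ok <- g2 > 1e-12
  fx <- fx[ok]; fy <- fy[ok]; fz <- fz[ok]
  fxx <- fxx[ok]; fyy <- fyy[ok]; fzz <- fzz[ok]
  fxy <- fxy[ok]; fxz <- fxz[ok]; fyz <- fyz[ok]
  g2 <- g2[ok]
  g <- sqrt(g2)
  hnum <- fx^2 * (fyy + fzz) + fy^2 * (fxx + fzz) + fz^2 * (fxx + fyy) -
    2 * (fx * fy * fxy + fy * fz * fyz + fx * fz * fxz)
  # sign flipped so that convex surfaces carry positive curvature
  H <- -hnum / (2 * g^3)
  knum <- fx^2 * (fyy * fzz - fyz^2) + fy^2 * (fxx * fzz - fxz^2) +
    fz^2 * (fxx * fyy - fxy^2) +
    2 * (fx * fy * (fxz * fyz - fxy * fzz) +
         fy * fz * (fxy * fxz - fyz * fxx) +
         fx * fz * (fxy * fyz - fxz * fyy))
  K <- knum / g2^2
  disc <- sqrt(pmax(H^2 - K, 0))
  list(k1 = H + disc, k2 = H - disc,
       surface = which(.surfaceVoxels(mask), arr.ind = TRUE)[ok, ,
                                                             drop = FALSE])
}

#' Local surface-shape block (20 features)
#'
#' Per surface point: curvedness `sqrt((k1^2 + k2^2)/2)`, sharpness
#' `(k1 - k2)^2`, shape index `(2/pi) * atan((k1 + k2)/(k1 - k2))` (with the
#' umbilic convention `sign(k1 + k2)` when `k1 == k2`), and total curvature
#' `k1^2 + k2^2`; then the five statistics of each over the surface.
#'
#' @inheritParams surfaceCurvatures
#' @return Named numeric vector of length 20.
#' @export
localShapeBlock <- function(mask, spacing = c(1, 1, 1), sigma = 1.5) {
  cv <- surfaceCurvatures(mask, spacing, sigma)
  k1 <- cv$k1; k2 <- cv$k2
  curvedness <- sqrt((k1^2 + k2^2) / 2)
  sharpness <- (k1 - k2)^2
  dk <- k1 - k2
  shapeIndex <- ifelse(dk > 1e-12, (2 / pi) * atan((k1 + k2) / dk),
                       sign(k1 + k2))
  totalCurv <- k1^2 + k2^2
  blocks <- list(curvedness = curvedness, sharpness = sharpness,
                 shapeIndex = shapeIndex, totalCurvature = totalCurv)
  out <- lapply(names(blocks), function(nm) {
    s <- fiveStats(blocks[[nm]])
    names(s) <- sprintf("shape.local.%s.%s", nm, .STAT_NAMES)
    s
  })
  unlist(out)
}

#' Global morphology block (14 features)
#'
#' Connected-component style shape attributes of the region: volume (voxel
#' count x voxel volume, mm^3); major/minor axis lengths `2*sqrt(5*lambda)`
#' from the eigenvalues of the second-moment (covariance) ellipsoid of the
#' voxel coordinates (mm); eccentricity `sqrt(1 - (a3/a1)^2)`; elongation
#' `a2/a1` and flatness `a3/a2` (1 for a sphere); orientation = angle
#' (degrees) between the major axis and the grid z axis; perimeter =
#' surface area (mm^2) via the coarea integral of the smoothed mask;
#' roundness `pi^(1/3) (6V)^(2/3) / A`; equivalent spherical radius
#' `(3V/(4 pi))^(1/3)` and diameter; elongation shape factor `a1/a3`;
#' compactness `36 pi V^2 / A^3`; integrated intensity = sum of scene
#' intensities over the region.
#'
#' @param mask nonempty logical 3D array.
#' @param scene the [ImageScene-class] supplying intensities and geometry.
#' @param sigma smoothing (voxels) for the surface-area estimate.
#' @return Named numeric vector of length 14.
#' @export
globalShapeBlock <- function(mask, scene, sigma = 1.5) {
  mask <- mask > 0
  if (!any(mask)) stop("empty region")
  sp <- spacing(scene)
  vox <- voxelData(scene)
  if (!identical(dim(mask), dim(vox))) stop("mask grid does not match scene")
  voxVol <- prod(sp)
  V <- sum(mask) * voxVol
  idx <- which(mask, arr.ind = TRUE)
  co <- .physCoords(idx, sp, origin(scene))
  if (nrow(co) > 1L) {
    ev <- eigen(stats::cov(co), symmetric = TRUE)
    lam <- pmax(ev$values, 0)
    ax <- sqrt(5 * lam)
    vmax <- ev$vectors[, 1L]
  } else {
    ax <- c(0, 0, 0)
    vmax <- c(0, 0, 1)
  }
  a1 <- ax[1]; a2 <- ax[2]; a3 <- ax[3]
  degenerate <- a1 <= 1e-9
  phi <- .gaussSmooth(array(as.numeric(mask), dim(mask)), sigma)
  gx <- .diffAxis(phi, 1L, sp[1]); gy <- .diffAxis(phi, 2L, sp[2])
  gz <- .diffAxis(phi, 3L, sp[3])
  A <- sum(sqrt(gx^2 + gy^2 + gz^2)) * voxVol
  eqR <- (3 * V / (4 * pi))^(1 / 3)
  out <- c(
    volume = V,
    majorAxisLength = 2 * a1,
    minorAxisLength = 2 * a3,
    eccentricity = if (degenerate) 0 else sqrt(max(0, 1 - (a3 / a1)^2)),
    elongation = if (degenerate) 1 else a2 / a1,
    orientation = if (degenerate) 0 else
      acos(min(1, abs(vmax[3]))) * 180 / pi,
    perimeter = A,
    roundness = if (A > 0) pi^(1 / 3) * (6 * V)^(2 / 3) / A else 0,
    equivalentSphericalRadius = eqR,
    equivalentSphericalDiameter = 2 * eqR,
    flatness = if (degenerate || a2 <= 1e-9) 1 else a3 / a2,
    elongationShapeFactor = if (degenerate || a3 <= 1e-9) 1 else a1 / a3,
    compactness = if (A > 0) 36 * pi * V^2 / A^3 else 0,
    integratedIntensity = sum(vox[mask]))
  names(out) <- paste0("shape.global.", names(out))
  out
}

#' Assemble the 34-feature shape descriptor
#'
#' Concatenates the 20-feature local surface block and the 14-feature
#' global morphology block. Shape is computed once per region (it does not
#' depend on the MRI protocol beyond the integrated intensity, for which
#' the supplied scene is used).
#'
#' @inheritParams globalShapeBlock
#' @param sigma smoothing level in voxels.
#' @return Named numeric vector of length 34.
#' @export
shapeDescriptor <- function(mask, scene, sigma = 1.5) {
  c(localShapeBlock(mask, spacing(scene), sigma),
    globalShapeBlock(mask, scene, sigma))
}
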