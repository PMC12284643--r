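#' @include AllClasses.R
NULL

# physical coordinates (mm) of 1-based voxel indices (n x 3 matrix)
.physCoords <- function(idx, spacing, origin) {
  sweep(sweep(idx - 1, 2L, spacing, `*`), 2L, origin, `+`)
}

# three full coordinate grids as arrays matching dims
.coordGrids <- function(dims, spacing, origin) {
  cx <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1]
  cy <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2]
  cz <- origin[3] + (seq_len(dims[3]) - 1) * spacing[3]
  list(
    x = array(cx, dims),
    y = array(rep(rep(cy, each = dims[1]), dims[3]), dims),
    z = array(rep(cz, each = dims[1] * dims[2]), dims)
  )
}

.sameGeometry <- function(dimsA, spA, orA, dimsB, spB, orB, tol = 1e-6) {
  identical(as.integer(dimsA), as.integer(dimsB)) &&
    all(abs(spA - spB) < tol) && all(abs(orA - orB) < tol)
}

.stopIfGeometryMismatch <- function(a, b, what = "objects") {
  da <- if (is(a, "DeformationField")) dim(a@field)[1:3] else dim(voxelData(a))
  db <- if (is(b, "DeformationField")) dim(b@field)[1:3] else
    if (is(b, "SegmentationMap")) dim(b@labels) else dim(voxelData(b))
  if (!.sameGeometry(da, spacing(a), origin(a), db, spacing(b), origin(b)))
    stop(what, " do not share grid geometry (dims/spacing/origin)")
  invisible(TRUE)
}

# central differences with replicated edges, physical units (per mm)
.diffAxis <- function(arr, axis, h) {
  d <- dim(arr)
  n <- d[axis]
  ip <- pmin(seq_len(n) + 1L, n)
  im <- pmax(seq_len(n) - 1L, 1L)
  idx <- function(i) {
    args <- rep(list(quote(expr = )), 3L)
    args[[axis]] <- i
    do.call(`[`, c(list(arr), args, list(drop = FALSE)))
  }
  denom <- (ip - im) * h   # index gap is 1 at the borders, 2 inside
  out <- (idx(ip) - idx(im))
  den <- switch(axis,
    array(denom, d),
    array(rep(rep(denom, each = d[1]), d[3]), d),
    array(rep(denom, each = d[1] * d[2]), d))
  out / den
}

# 1D convolution along an axis with symmetric (reflect) padding
.convAxis <- function(arr, kernel, axis) {
  d <- dim(arr)
  n <- d[axis]
  r <- (length(kernel) - 1L) / 2L
  out <- array(0, d)
  reflectIdx <- function(i, n) {
    i <- ((i - 1L) %% (2L * n))
    ifelse(i >= n, 2L * n - 1L - i, i) + 1L
  }
  base <- seq_len(n)
  for (o in seq_along(kernel)) {
    off <- o - r - 1L
    src <- reflectIdx(base + off, n)
    args <- rep(list(quote(expr = )), 3L)
    args[[axis]] <- src
    out <- out + kernel[o] * do.call(`[`, c(list(arr), args, list(drop = FALSE)))
  }
  out
}

# separable Gaussian smoothing, sigma in voxels per axis
.gaussSmooth <- function(arr, sigmaVox) {
  if (length(sigmaVox) == 1L) sigmaVox <- rep(sigmaVox, 3L)
  for (ax in 1:3) {
    s <- sigmaVox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k <- k / sum(k)
    arr <- .convAxis(arr, k, ax)
  }
  arr
}

# bounding box of a mask expanded by `pad` voxels, clipped to the grid
.maskBBox <- function(mask, pad = 0L) {
  d <- dim(mask)
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0L) stop("mask is empty")
  lo <- pmax(apply(w, 2L, min) - pad, 1L)
  hi <- pmin(apply(w, 2L, max) + pad, d)
  list(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
}

.cropArray <- function(arr, bb) arr[bb$x, bb$y, bb$z, drop = FALSE]
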