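test_that("deformation magnitude is the per-voxel Euclidean norm", {
  f <- array(0, c(2, 2, 2, 3))
  f[1, 1, 1, ] <- c(3, 4, 0)
  f[2, 1, 1, ] <- c(1, 1, 1)
  fld <- DeformationField(f)
  mag <- deformationMagnitude(fld)
  expect_equal(mag[1, 1, 1], 5)
  expect_equal(mag[2, 1, 1], sqrt(3))
  expect_equal(mag[1, 2, 2], 0)
  expect_true(all(mag >= 0))
})

test_that("deformation angle matches closed-form cases and masks zero vectors", {
  f <- array(0, c(1, 1, 4, 3))
  f[1, 1, 1, ] <- c(0, 0, 1)    # toward the centroid (parallel to y)
  f[1, 1, 2, ] <- c(0, 0, -1)   # away from the centroid
  f[1, 1, 3, ] <- c(1, 0, 0)    # perpendicular
  fld <- DeformationField(f)
  ang <- deformationAngle(fld, centroid = c(0, 0, 50))
  expect_equal(ang[1, 1, 1], 0)
  expect_equal(ang[1, 1, 2], 180)
  expect_equal(ang[1, 1, 3], 90)
  expect_true(is.na(ang[1, 1, 4]))   # |x| = 0 -> undefined, masked
})

test_that("band statistics equal the direct moment formulas", {
  d <- c(5L, 5L, 5L)
  bands <- new("AnnularBandMap", bands = array(1L, d), width = 5,
               nBands = 2L, spacing = c(1, 1, 1), origin = c(0, 0, 0))
  vals <- array(2, d)
  expect_equal(unname(bandStatistics(vals, bands, 1)), c(2, 2, 0, 0, 0))
  expect_equal(unname(bandStatistics(vals, bands, 2)), rep(0, 5))

  v <- c(0, 0, 0, 10)
  m <- mean(v); m2 <- mean((v - m)^2)
  st <- fiveStats(v)
  expect_equal(unname(st["skewness"]), mean((v - m)^3) / m2^1.5)
  expect_equal(unname(st["kurtosis"]), mean((v - m)^4) / m2^2 - 3)
  expect_equal(unname(fiveStats(c(1, 2, 3))[1:3]), c(2, 2, 1))
})

test_that("angle quantization uses six 30-degree intervals and conserves counts", {
  d <- c(10L, 10L, 6L)
  bmap <- array(0L, d); bmap[, , 1:3] <- 1L
  bands <- new("AnnularBandMap", bands = bmap, width = 5, nBands = 2L,
               spacing = c(1, 1, 1), origin = c(0, 0, 0))
  ang <- array(NA_real_, d)
  ang[1:3] <- c(10, 45, 170)
  expect_equal(unname(quantizeAngles(ang, bands, 1)), c(1, 1, 0, 0, 0, 1))
  expect_equal(unname(quantizeAngles(ang, bands, 2)), rep(0, 6))

  set.seed(4)
  ang2 <- array(NA_real_, d)
  inband <- which(bmap == 1L)
  ang2[sample(inband, 280)] <- runif(280, 0, 180)
  expect_equal(sum(quantizeAngles(ang2, bands, 1)), 280)
  # 180 degrees falls in the last, closed interval
  ang3 <- array(NA_real_, d); ang3[inband[1]] <- 180
  expect_equal(unname(quantizeAngles(ang3, bands, 1)), c(0, 0, 0, 0, 0, 1))
})

test_that("F_B has the 60/60/72 block structure and scales with m", {
  ph <- tinyPhantom(5)
  hab <- buildHabitat(ph$seg)
  sp <- spacing(ph$seg)
  ctr <- tumorCentroid(hab, sp)
  bands <- buildAnnularBands(hab, brainMask(ph$seg), sp)
  fb <- assembleFB(ph$field, bands, ctr)
  expect_length(fb, 192L)
  expect_equal(unname(attr(fb, "blocks")), c(60L, 60L, 72L))
  expect_false(anyDuplicated(names(fb)) > 0)

  bands6 <- buildAnnularBands(hab, brainMask(ph$seg), sp, nBands = 6L)
  expect_length(assembleFB(ph$field, bands6, ctr), 6L * 16L)

  # per band, histogram counts equal the defined-angle voxel count
  ang <- deformationAngle(ph$field, ctr)
  for (a in c(1L, 3L, 5L)) {
    nDefined <- sum(!is.na(ang[bandIndex(bands) == a]))
    expect_equal(sum(quantizeAngles(ang, bands, a)), nDefined)
  }
})

test_that("rotating field and geometry together preserves the descriptor", {
  ph <- tinyPhantom(6)
  sp <- spacing(ph$seg)
  hab <- buildHabitat(ph$seg)
  brain <- brainMask(ph$seg)
  ctr <- tumorCentroid(hab, sp)
  bands <- buildAnnularBands(hab, brain, sp, nBands = 6L)
  fb <- assembleFB(ph$field, bands, ctr)

  # proper 90-degree rotation about z: index (i,j) -> (j, nx+1-i),
  # vector (vx,vy) -> (vy,-vx)
  rotA <- function(a) {
    nx <- dim(a)[1]
    aperm(a, c(2, 1, 3))[, nx:1, , drop = FALSE]
  }
  f <- fieldData(ph$field)
  fr <- array(0, dim(f))
  fr[, , , 1] <- rotA(f[, , , 2])
  fr[, , , 2] <- -rotA(f[, , , 1])
  fr[, , , 3] <- rotA(f[, , , 3])
  fldR <- DeformationField(fr, spacing = sp)
  habR <- rotA(hab); brainR <- rotA(brain)
  ctrR <- tumorCentroid(habR, sp)
  bandsR <- buildAnnularBands(habR, brainR, sp, nBands = 6L)
  fbR <- assembleFB(fldR, bandsR, ctrR)
  expect_equal(unname(fbR), unname(fb), tolerance = 1e-9)
})

test_that("outward fields fill the [150,180] bin and inward fields [0,30)", {
  for (mode in c("outward", "inward")) {
    ph <- tinyPhantom(7, orientation = mode)
    hab <- buildHabitat(ph$seg)
    sp <- spacing(ph$seg)
    ctr <- tumorCentroid(hab, sp)
    bands <- buildAnnularBands(hab, brainMask(ph$seg), sp)
    fb <- assembleFB(ph$field, bands, ctr)
    hist <- fb[grepl("^angbin", names(fb))]
    byBin <- vapply(1:6, function(b)
      sum(hist[grepl(sprintf("bin%d$", b), names(hist))]), numeric(1))
    expect_gt(sum(byBin), 0)
    if (mode == "outward") expect_equal(sum(byBin[1:5]), 0)
    else expect_equal(sum(byBin[2:6]), 0)
  }
})
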