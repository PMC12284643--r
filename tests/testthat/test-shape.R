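test_that("sphere curvatures recover 1/r within the voxelization band", {
  r <- 10
  sph <- sphereMask(r)
  cv <- surfaceCurvatures(sph, c(1, 1, 1))
  expect_lt(abs(mean(cv$k1) - 1 / r) / (1 / r), 0.15)
  expect_lt(abs(mean(cv$k2) - 1 / r) / (1 / r), 0.15)
  expect_true(all(cv$k1 >= cv$k2))

  lb <- localShapeBlock(sph)
  expect_length(lb, 20L)
  expect_lt(abs(lb[["shape.local.curvedness.mean"]] - 0.1) / 0.1, 0.15)
  expect_lt(lb[["shape.local.sharpness.mean"]], 0.01 * (1 / r)^2 * 100)
  # near-umbilic everywhere on a sphere: shape index close to +1
  expect_gt(lb[["shape.local.shapeIndex.mean"]], 0.7)
})

test_that("flat slab faces carry near-zero curvature", {
  d <- c(24L, 24L, 24L)
  slab <- array(FALSE, d)
  slab[4:21, 4:21, 10:15] <- TRUE
  cv <- surfaceCurvatures(slab, c(1, 1, 1))
  faceCenter <- cv$surface[, 1] %in% 10:15 & cv$surface[, 2] %in% 10:15
  expect_lt(max(abs(cv$k1[faceCenter])), 0.03)
  expect_lt(max(abs(cv$k2[faceCenter])), 0.03)
})

test_that("curvatures scale as 1/s and volumes as s^3 under rescaling", {
  sph <- sphereMask(8)
  cv1 <- surfaceCurvatures(sph, c(1, 1, 1))
  cv2 <- surfaceCurvatures(sph, c(2, 2, 2))
  expect_equal(cv2$k1, cv1$k1 / 2, tolerance = 1e-9)
  sc1 <- ImageScene(array(1, dim(sph)), spacing = 1)
  sc2 <- ImageScene(array(1, dim(sph)), spacing = 2)
  g1 <- globalShapeBlock(sph, sc1)
  g2 <- globalShapeBlock(sph, sc2)
  expect_equal(g2[["shape.global.volume"]],
               8 * g1[["shape.global.volume"]])
  expect_equal(g2[["shape.global.majorAxisLength"]],
               2 * g1[["shape.global.majorAxisLength"]], tolerance = 1e-9)
})

test_that("global morphology matches the analytic sphere", {
  r <- 10
  sph <- sphereMask(r)
  sc <- ImageScene(array(1, dim(sph)))
  g <- globalShapeBlock(sph, sc)
  expect_length(g, 14L)
  expect_lt(abs(g[["shape.global.volume"]] - 4 / 3 * pi * r^3) /
              (4 / 3 * pi * r^3), 0.05)
  expect_lt(g[["shape.global.eccentricity"]], 0.1)
  expect_gt(g[["shape.global.elongation"]], 0.95)
  expect_gt(g[["shape.global.flatness"]], 0.95)
  expect_equal(g[["shape.global.integratedIntensity"]], sum(sph))
  expect_lt(abs(g[["shape.global.equivalentSphericalRadius"]] - r) / r, 0.02)
  expect_gt(g[["shape.global.roundness"]], 0.9)
  expect_true(g[["shape.global.perimeter"]] > 0)
})

test_that("the shape descriptor is 34-long and rejects degenerate masks", {
  sph <- sphereMask(6)
  sc <- ImageScene(array(1, dim(sph)))
  fs <- shapeDescriptor(sph, sc)
  expect_length(fs, 34L)
  expect_false(anyDuplicated(names(fs)) > 0)
  tiny <- array(FALSE, c(5, 5, 5)); tiny[2, 2, 2] <- TRUE
  expect_error(shapeDescriptor(tiny, ImageScene(array(1, c(5, 5, 5)))),
               "too small")
  expect_error(globalShapeBlock(array(FALSE, c(5, 5, 5)),
                                ImageScene(array(1, c(5, 5, 5)))), "empty")
})

test_that("elongated ellipsoids report anisotropic axes", {
  d <- c(40L, 20L, 20L)
  g <- expand.grid(x = 1:40, y = 1:20, z = 1:20)
  ell <- array(((g$x - 20.5) / 15)^2 + ((g$y - 10.5) / 6)^2 +
                 ((g$z - 10.5) / 6)^2 <= 1, d)
  gb <- globalShapeBlock(ell, ImageScene(array(1, d)))
  expect_lt(abs(gb[["shape.global.majorAxisLength"]] - 30) / 30, 0.1)
  expect_lt(abs(gb[["shape.global.minorAxisLength"]] - 12) / 12, 0.1)
  expect_gt(gb[["shape.global.eccentricity"]], 0.8)
  expect_lt(gb[["shape.global.elongation"]], 0.5)
  expect_gt(gb[["shape.global.elongationShapeFactor"]], 2)
  # major axis along x -> 90 degrees from the z axis
  expect_gt(gb[["shape.global.orientation"]], 80)
})
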