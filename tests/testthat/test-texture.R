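test_that("default inventory totals 214 maps and tracks its parameters", {
  inv <- textureInventory()
  expect_equal(nrow(inv), 214L)
  expect_equal(as.integer(table(inv$family)[c("gradient", "haralick",
                                              "laws", "gabor", "collage")]),
               c(5L, 39L, 125L, 32L, 13L))
  inv2 <- textureInventory(textureParams(haralickWindows = c(3L, 5L)))
  expect_equal(nrow(inv2), 214L - 13L)
  inv3 <- textureInventory(textureParams(gaborOrientations = 4L))
  expect_equal(nrow(inv3), 214L - 16L)
  # realized maps match the advertised inventory
  set.seed(20)
  sc <- ImageScene(array(rnorm(10^3), c(10, 10, 10)))
  maps <- computeTextureMaps(sc)
  expect_identical(names(maps), textureInventory()$name)
})

test_that("gradient maps recover closed-form derivatives", {
  d <- c(8L, 8L, 8L)
  sc <- ImageScene(array(5, d))
  g <- computeGradientMaps(sc)
  for (m in g) expect_true(all(m == 0))

  grids <- expand.grid(x = 1:8, y = 1:8, z = 1:8)
  ramp <- array(grids$x * 2, d)    # slope 1/mm with 2 mm spacing
  g2 <- computeGradientMaps(ImageScene(ramp, spacing = 2))
  expect_true(all(abs(g2$gradient.dx - 1) < 1e-12))
  expect_true(all(abs(g2$gradient.dy) < 1e-12))

  ramp3 <- array(grids$x * 1 + grids$y * 2 + grids$z * 2, d)
  g3 <- computeGradientMaps(ImageScene(ramp3, spacing = 1))
  expect_equal(g3$gradient.magnitude[4, 4, 4], 3)
})

test_that("windowed Haralick statistics match brute-force pair enumeration", {
  # constant window: single-entry co-occurrence matrix
  sc <- ImageScene(array(3, c(7, 7, 7)))
  h <- computeHaralickMaps(sc, params = textureParams(haralickWindows = 3L))
  expect_equal(h[["haralick.w3.energy"]][4, 4, 4], 1)
  expect_equal(h[["haralick.w3.entropy"]][4, 4, 4], 0)
  expect_equal(h[["haralick.w3.contrast"]][4, 4, 4], 0)

  # random toy volume: window 5 at the center covers the whole 5^3 grid,
  # so the map value must equal the brute-force GLCM of the full grid
  set.seed(21)
  pars <- textureParams(haralickWindows = 5L, haralickLevels = 4L)
  vox <- array(sample(1:4, 125, replace = TRUE), c(5, 5, 5))
  sc2 <- ImageScene(vox + 0)
  h2 <- computeHaralickMaps(sc2, params = pars)
  lab <- 1L + ((vox - 1L) %/% 1L)  # 4 integer values -> labels 1..4
  oracle <- bruteHaralick(array(as.integer(vox), dim(vox)), 4L, offsets13())
  got <- vapply(names(oracle), function(s)
    h2[[paste0("haralick.w5.", s)]][3, 3, 3], numeric(1))
  expect_equal(got, oracle, tolerance = 1e-10)

  # a printed 4x4 checkerboard slab: hand-enumerated contrast
  cb <- array(rep(c(1, 2, 1, 2, 2, 1, 2, 1), 8), c(4, 4, 4))
  scc <- ImageScene(cb)
  pars2 <- textureParams(haralickWindows = 3L, haralickLevels = 2L)
  h3 <- computeHaralickMaps(scc, params = pars2)
  oracle2 <- bruteHaralick(array(as.integer(cb[1:3, 1:3, 1:3]), c(3, 3, 3)),
                           2L, offsets13())
  expect_equal(h3[["haralick.w3.contrast"]][2, 2, 2],
               unname(oracle2["contrast"]), tolerance = 1e-10)

  # bounds on arbitrary windows
  set.seed(22)
  sc3 <- ImageScene(array(rnorm(6^3), c(6, 6, 6)))
  h4 <- computeHaralickMaps(sc3, params = textureParams(
    haralickWindows = 3L, haralickLevels = 8L))
  en <- h4[["haralick.w3.energy"]]
  expect_true(all(en > 0 & en <= 1))
  expect_true(all(h4[["haralick.w3.entropy"]] >= 0))
  expect_error(computeHaralickMaps(sc3, params = textureParams(
    haralickWindows = 9L)), "window larger")
})

test_that("Laws filters are separable and vanish on constants except L5L5L5", {
  sc <- ImageScene(array(4, c(9, 9, 9)))
  lw <- computeLawsMaps(sc)
  nz <- names(lw)[vapply(lw, function(m) max(abs(m)) > 1e-9, logical(1))]
  expect_identical(nz, "laws.L5L5L5")

  set.seed(23)
  arr <- array(rnorm(9^3), c(9, 9, 9))
  lw2 <- computeLawsMaps(ImageScene(arr))
  kers <- list(L5 = c(1, 4, 6, 4, 1), E5 = c(-1, -2, 0, 2, 1),
               S5 = c(-1, 0, 2, 0, -1))
  for (combo in list(c("E5", "L5", "S5"), c("S5", "S5", "E5"))) {
    direct <- bruteConv3(arr, kers[[combo[1]]], kers[[combo[2]]],
                         kers[[combo[3]]])
    got <- lw2[[paste0("laws.", paste(combo, collapse = ""))]]
    interior <- !is.na(direct)
    expect_equal(got[interior], direct[interior], tolerance = 1e-10)
  }

  # impulse: interior response is the (flipped) separable kernel
  imp <- array(0, c(9, 9, 9)); imp[5, 5, 5] <- 1
  lw3 <- computeLawsMaps(ImageScene(imp))
  resp <- lw3[["laws.E5L5S5"]][3:7, 3:7, 3:7]
  expect_equal(resp, outer(outer(rev(kers$E5), rev(kers$L5)), rev(kers$S5)),
               tolerance = 1e-12)
})

test_that("Gabor bank is DC-free, offset-invariant, and orientation-tuned", {
  sc <- ImageScene(array(7, c(12, 12, 4)))
  gb <- computeGaborMaps(sc)
  expect_lt(max(vapply(gb, max, numeric(1))), 1e-10)

  d <- c(24L, 24L, 3L)
  grids <- expand.grid(x = 1:24, y = 1:24, z = 1:3)
  grating <- array(cos(2 * pi * grids$x / 4), d)
  g1 <- computeGaborMaps(ImageScene(grating))
  g2 <- computeGaborMaps(ImageScene(grating + 5))
  center <- vapply(g1, function(m) m[12, 12, 2], numeric(1))
  center2 <- vapply(g2, function(m) m[12, 12, 2], numeric(1))
  expect_equal(center, center2, tolerance = 1e-8)
  # the filter matched to the grating's orientation and wavelength wins
  expect_identical(names(which.max(center)), "gabor.th000.wl4")
})

test_that("CoLlAGe flags degenerate windows and tracks orientation structure", {
  sc <- ImageScene(array(2, c(10, 10, 3)))
  cl <- computeCollageMaps(sc)
  expect_length(cl, 13L)
  expect_true(all(vapply(cl, function(m) all(m == 0), logical(1))))
  expect_true(all(attr(cl, "degenerate")[, , 1]))

  # single ramp: one dominant orientation everywhere -> entropy 0
  d <- c(16L, 16L, 1L)
  grids <- expand.grid(x = 1:16, y = 1:16, z = 1)
  ramp <- array(grids$x * 1.0, d)
  cl2 <- computeCollageMaps(ImageScene(ramp))
  interior <- array(FALSE, d); interior[4:13, 4:13, 1] <- TRUE
  expect_true(all(abs(cl2$collage.entropy[interior]) < 1e-10))

  # composite image with two orthogonal gradients: boundary entropy higher
  comp <- array(0, d)
  comp[1:8, , 1] <- outer(1:8, rep(1, 16))        # x-gradient half
  comp[9:16, , 1] <- outer(rep(8, 8), 1:16) + 8   # y-gradient half
  cl3 <- computeCollageMaps(ImageScene(comp))
  boundary <- mean(cl3$collage.entropy[8:9, 6:11, 1])
  pure <- mean(cl3$collage.entropy[c(3, 14), 6:11, 1])
  expect_gt(boundary, pure)
})

test_that("texture summaries have length 1070 and match direct moments", {
  set.seed(24)
  sc <- ImageScene(array(rnorm(9^3), c(9, 9, 9)))
  mask <- array(FALSE, c(9, 9, 9)); mask[3:7, 3:7, 3:7] <- TRUE
  maps <- computeTextureMaps(sc, mask)
  ft <- summarizeTexture(maps, mask)
  expect_length(ft, 1070L)
  expect_false(anyDuplicated(names(ft)) > 0)

  constMap <- list(x = array(3, c(9, 9, 9)))
  expect_equal(unname(summarizeTexture(constMap, mask)), c(3, 3, 0, 0, 0))

  v <- rnorm(20)
  region <- array(FALSE, c(20, 1, 1)); region[1:20, 1, 1] <- TRUE
  st <- summarizeTexture(list(m = array(v, c(20, 1, 1))), region)
  m <- mean(v); m2 <- mean((v - m)^2)
  expect_equal(unname(st), c(m, median(v), sd(v), mean((v - m)^3) / m2^1.5,
                             mean((v - m)^4) / m2^2 - 3))
  expect_error(summarizeTexture(maps, array(FALSE, c(9, 9, 9))), "empty")
})

test_that("per-voxel maps are translation-equivariant in the interior", {
  set.seed(25)
  arr <- array(rnorm(10 * 9 * 8), c(10, 9, 8))
  shifted <- arr[c(2:10, 1), , ]   # shift content by one voxel along x
  m1 <- computeGradientMaps(ImageScene(arr))$gradient.magnitude
  m2 <- computeGradientMaps(ImageScene(shifted))$gradient.magnitude
  expect_equal(m2[3:7, 3:7, 3:6], m1[4:8, 3:7, 3:6], tolerance = 1e-12)
  l1 <- computeLawsMaps(ImageScene(arr))[["laws.E5S5W5"]]
  l2 <- computeLawsMaps(ImageScene(shifted))[["laws.E5S5W5"]]
  expect_equal(l2[4:6, 4:6, 4:5], l1[5:7, 4:6, 4:5], tolerance = 1e-10)
})
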