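# Synthetic oocyte-scene generator: geometry, determinism, defocus locality.

baseParams <- function(...) {
  args <- utils::modifyList(
    list(cellCenter = c(128, 128), cellRadius = 96, zonaThickness = 16,
         pbCenterAngle = pi, pbSemiAxes = c(8, 8), seed = 7L),
    list(...))
  do.call(sceneParams, args)
}

test_that("the mask is the rasterized polar-body ellipse at the scene position", {
  # cell center (128,128), radius 96, zona 16 -> pb centre at
  # radius 88 toward angle pi = (128, 40)
  p <- baseParams()
  expect_equal(pbCenter(p), c(128, 40))
  sc <- renderScene(p, size = c(256, 256))
  m <- sc$mask@.Data
  px <- which(m == 1, arr.ind = TRUE)
  expect_gt(nrow(px), 0)
  expect_equal(unname(colMeans(px)), c(128, 40), tolerance = 1)
  # analytic ellipse: every foreground pixel within the circle radius 8 (+.5)
  d <- sqrt((px[, 1] - 128)^2 + (px[, 2] - 40)^2)
  expect_lte(max(d), 8.5)
  # area close to pi * 8^2
  expect_equal(nrow(px), pi * 64, tolerance = 0.06)
})

test_that("scenes without a polar body have all-zero masks", {
  sc <- renderScene(baseParams(polarBodyPresent = FALSE), c(256, 256))
  expect_true(all(sc$mask@.Data == 0))
  expect_s4_class(sc$image, "Micrograph")
})

test_that("rendering is deterministic and defocus changes only the image near the polar body", {
  p0 <- baseParams(pbDefocusSigma = 0)
  p5 <- baseParams(pbDefocusSigma = 5)
  a <- renderScene(p0, c(256, 256))
  a2 <- renderScene(p0, c(256, 256))
  b <- renderScene(p5, c(256, 256))
  expect_identical(a$image@.Data, a2$image@.Data)
  expect_identical(a$mask@.Data, b$mask@.Data)
  diff <- abs(a$image@.Data - b$image@.Data) > 1e-9
  px <- which(diff, arr.ind = TRUE)
  expect_gt(nrow(px), 0)
  # all changed pixels lie within the pb ellipse dilated by the separable
  # PSF extent (a Chebyshev ball of radius 4 sigma around each pb pixel)
  d <- pmax(abs(px[, 1] - 128), abs(px[, 2] - 40))
  expect_lte(max(d), 8.5 + 4 * 5 + 1)
})

test_that("generated images satisfy the intensity and shape invariants", {
  for (s in 1:3) {
    p <- sampleSceneParams("mixed", seed = s, size = c(128, 128))
    sc <- renderScene(p, c(128, 128))
    expect_true(validObject(sc$image))
    expect_true(all(sc$mask@.Data %in% c(0, 1)))
  }
})

test_that("parameter sampling is deterministic and respects difficulty axes", {
  a <- sampleSceneParams("clear", seed = 1)
  b <- sampleSceneParams("clear", seed = 1)
  expect_identical(a, b)
  expect_equal(a$pbDefocusSigma, 0)
  expect_null(a$deformation)
  for (s in 1:5) {
    d <- sampleSceneParams("defocused", seed = s)
    expect_gte(d$pbDefocusSigma, 2)
    expect_lte(d$pbDefocusSigma, 6)
    f <- sampleSceneParams("deformed", seed = s)
    expect_gte(f$deformation$alpha, 4)
    expect_lte(f$deformation$alpha, 10)
  }
  expect_error(sampleSceneParams("impossible", seed = 1), "difficulty")
})

test_that("mixed-difficulty draws span the stated polar-body size range", {
  axes <- unlist(lapply(1:400, function(s)
    sampleSceneParams("mixed", seed = s)$pbSemiAxes))
  expect_lte(min(axes), 5)
  expect_gte(max(axes), 15)
})

test_that("scene parameter validation rejects out-of-range geometry", {
  expect_error(baseParams(pbSemiAxes = c(1, 8)), ">= 2")
  expect_error(baseParams(pbSemiAxes = c(40, 8)), "cellRadius / 3")
  expect_error(baseParams(brightness = 0.1), "brightness")
  expect_error(renderScene(baseParams(), c(100, 128)), "divisible")
})

test_that("generateDataset writes the requested composition deterministically", {
  d1 <- file.path(tempdir(), "gen_a")
  d2 <- file.path(tempdir(), "gen_b")
  m1 <- generateDataset(3, 2, "clear", d1, seed = 5, size = c(64, 64))
  m2 <- generateDataset(3, 2, "clear", d2, seed = 5, size = c(64, 64))
  expect_equal(nrow(m1), 5)
  expect_equal(sum(m1$label == "negative"), 2)
  for (i in seq_len(5)) {
    msk <- readLabelMask(m1$mask[i])@.Data
    if (m1$label[i] == "positive") expect_gt(sum(msk), 0)
    else expect_equal(sum(msk), 0)
    # byte-identical across reruns with the same seed
    expect_identical(readBin(m1$image[i], "raw", 1e6),
                     readBin(m2$image[i], "raw", 1e6))
  }
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
  # zero-positive edge case
  m0 <- generateDataset(0, 4, "clear", file.path(tempdir(), "gen_c"),
                        seed = 2, size = c(64, 64))
  expect_equal(nrow(m0), 4)
  expect_true(all(vapply(m0$mask, function(p)
    sum(readLabelMask(p)@.Data), numeric(1)) == 0))
})
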