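# Paired geometric transforms: identities, index oracles, field bounds,
# area preservation, and the fourfold expansion policy.

test_that("rotation by 0 degrees is an exact identity", {
  img <- tinyImage(32, 1)
  mask <- diskMask(32, 10, 12, 4)
  out <- rotatePair(img, mask, 0)
  expect_identical(out$image, img)
  expect_identical(out$mask, mask)
})

test_that("rotation by 90 degrees matches the exact index permutation", {
  img <- tinyImage(32, 2)
  mask <- diskMask(32, 8, 20, 3)
  out <- rotatePair(img, mask, 90)
  # the inverse map at +90 degrees reads out(r, c) = in(n + 1 - c, r),
  # i.e. reverse the rows then transpose
  perm <- t(img[nrow(img):1, ])
  permM <- t(mask[nrow(mask):1, ])
  expect_equal(out$image, perm, tolerance = 1e-9)
  expect_equal(out$mask, permM)
  expect_true(all(out$mask %in% c(0, 1)))
})

test_that("rotated masks remain binary at arbitrary angles", {
  mask <- diskMask(32, 16, 16, 6)
  for (ang in c(-77.3, -45, 13.7, 61)) {
    out <- rotatePair(tinyImage(32), mask, ang)
    expect_true(all(out$mask %in% c(0, 1)))
    expect_true(all(out$image >= 0 & out$image <= 1))
  }
  expect_error(rotatePair(tinyImage(32), mask, 91), "\\[-90, 90\\]")
})

test_that("rigid transforms move the mask centroid with the geometric map", {
  mask <- diskMask(64, 20, 44, 5)
  img <- tinyImage(64, 4)
  ctr <- colMeans(which(mask == 1, arr.ind = TRUE))
  for (ang in c(-60, 30, 85)) {
    out <- rotatePair(img, mask, ang)
    outCtr <- colMeans(which(out$mask == 1, arr.ind = TRUE))
    th <- ang * pi / 180; cc <- (64 + 1) / 2
    # forward map of the source centroid
    expCtr <- c(cc + cos(th) * (ctr[1] - cc) + sin(th) * (ctr[2] - cc),
                cc - sin(th) * (ctr[1] - cc) + cos(th) * (ctr[2] - cc))
    expect_lt(sqrt(sum((outCtr - expCtr)^2)), 1)
  }
})

test_that("flips are exact index reversals and involutions", {
  img <- tinyImage(32, 5)
  mask <- matrix(0, 32, 32)
  mask[11, 21] <- 1
  h <- flipPair(img, mask, "horizontal")
  expect_equal(which(h$mask == 1, arr.ind = TRUE)[1, ],
               c(row = 11, col = 32 + 1 - 21))
  expect_identical(flipPair(h$image, h$mask, "horizontal")$image, img)
  v <- flipPair(img, mask, "vertical")
  expect_equal(which(v$mask == 1, arr.ind = TRUE)[1, ],
               c(row = 32 + 1 - 11, col = 21))
  expect_equal(sum(h$mask), sum(mask))
  expect_error(flipPair(img, mask, "diagonal"))
})

test_that("single-pixel flip on a wide mask follows c -> W + 1 - c", {
  mask <- matrix(0, 16, 256)
  mask[10, 21] <- 1  # 0-based (10, 20) in a width-256 canvas
  img <- matrix(0.5, 16, 256)
  out <- flipPair(img, mask, "horizontal")
  expect_equal(unname(which(out$mask == 1, arr.ind = TRUE)[1, ]),
               c(10, 236))  # 0-based column 235
})

test_that("displacement fields are bounded by alpha and seeded deterministically", {
  for (alpha in c(0, 3, 7)) {
    f <- makeDisplacement(c(40, 48), elasticParams(alpha, 6, seed = 9))
    expect_lte(max(abs(f$drow)), alpha)
    expect_lte(max(abs(f$dcol)), alpha)
  }
  f1 <- makeDisplacement(c(32, 32), elasticParams(5, 8, seed = 4))
  f2 <- makeDisplacement(c(32, 32), elasticParams(5, 8, seed = 4))
  expect_identical(f1, f2)
  expect_true(all(makeDisplacement(c(16, 16),
                                   elasticParams(0, 4))$drow == 0))
})

test_that("elastic transform with alpha = 0 is an identity", {
  img <- tinyImage(32, 6)
  mask <- diskMask(32, 16, 16, 5)
  out <- elasticPair(img, mask, elasticParams(0, 8, seed = 1))
  expect_equal(out$image, img)
  expect_identical(out$mask, mask)
})

test_that("a constant injected field shifts content by the sampling rule", {
  mask <- matrix(0, 16, 16)
  mask[8, 10] <- 1
  img <- matrix(0, 16, 16); img[8, 10] <- 1
  field <- list(drow = matrix(0, 16, 16), dcol = matrix(3, 16, 16))
  out <- elasticPair(img, mask, field = field)
  # out(r, c) = in(r, c + 3): the pixel lands 3 columns to the left
  expect_equal(which(out$mask == 1, arr.ind = TRUE)[1, ],
               c(row = 8, col = 7))
})

test_that("smooth elastic fields approximately preserve foreground area", {
  mask <- diskMask(64, 32, 32, 16)
  img <- matrix(0.5, 64, 64)
  area0 <- sum(mask)
  for (s in 1:100) {
    p <- elasticParams(alpha = runif(1, 0, 6), sigma = runif(1, 8, 12),
                       seed = s)
    out <- elasticPair(img, mask, p)
    expect_lte(abs(sum(out$mask) - area0) / area0, 0.2)
  }
})

test_that("augmenting a manifest yields exactly four pairs per original", {
  src <- file.path(tempdir(), "aug_src")
  man <- generateDataset(2, 1, "clear", src, seed = 11, size = c(64, 64))
  out <- augmentManifest(man, file.path(tempdir(), "aug_out"), seed = 3)
  expect_equal(nrow(out), 4 * nrow(man))
  expect_equal(sum(out$label == "negative"), 4)
  for (i in seq_len(nrow(out))) {
    m <- readLabelMask(out$mask[i])@.Data
    expect_true(all(m %in% c(0, 1)))
    if (out$label[i] == "negative") expect_equal(sum(m), 0)
  }
  # determinism of the expansion
  out2 <- augmentManifest(man, file.path(tempdir(), "aug_out2"), seed = 3)
  for (i in seq_len(nrow(out)))
    expect_identical(readBin(out$image[i], "raw", 1e6),
                     readBin(out2$image[i], "raw", 1e6))
})
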