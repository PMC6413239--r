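# Detection stage: region formation, non-maximum suppression, centroid
# rule, and exhaustive agreement with a flood-fill oracle.

test_that("region formation follows the support threshold and connectivity", {
  cfg <- nmsConfig(minArea = 1)
  expect_equal(findRegions(matrix(0, 16, 16), cfg), list())
  # one block below the support threshold disappears
  low <- matrix(0, 16, 16); low[4:6, 4:6] <- 0.05
  expect_equal(findRegions(low, cfg), list())
  # two disjoint 5x5 blocks of 0.9
  p <- matrix(0, 20, 20)
  p[2:6, 2:6] <- 0.9; p[12:16, 12:16] <- 0.9
  regs <- findRegions(p, cfg)
  expect_length(regs, 2)
  expect_equal(sort(vapply(regs, `[[`, numeric(1), "area")), c(25, 25))
  expect_equal(vapply(regs, `[[`, numeric(1), "maxProb"), c(0.9, 0.9))
  # diagonal touching merges under 8- but not 4-connectivity
  d <- matrix(0, 8, 8); d[2, 2] <- 0.8; d[3, 3] <- 0.8
  expect_length(findRegions(d, nmsConfig(minArea = 1, connectivity = 8)), 1)
  expect_length(findRegions(d, nmsConfig(minArea = 1, connectivity = 4)), 2)
})

test_that("labeling agrees with EBImage's component labeling at 4-connectivity", {
  ns <- asNamespace("polarseg")
  set.seed(42)
  for (i in 1:20) {
    bin <- matrix(runif(24 * 24) < 0.35, 24, 24)
    ours <- ns$labelComponents(bin, 4L)
    ebs <- EBImage::bwlabel(bin * 1)
    expect_equal(max(ours), max(ebs))
    # same partition: every pair of labels maps one-to-one
    expect_equal(length(unique(paste(ours[bin], ebs[bin]))), max(ours))
  }
})

test_that("suppression applies both constraints and the deterministic tie-break", {
  cfg <- nmsConfig(minArea = 10)
  mk <- function(maxp, area, centroid)
    list(maxProb = maxp, area = area, centroid = centroid,
         pixels = matrix(0, area, 2))
  # the 0.45 region is ignored even though it is larger
  win <- nonmaxSuppress(list(mk(0.7, 50, c(5, 5)), mk(0.45, 400, c(9, 9))),
                        cfg)
  expect_equal(win$maxProb, 0.7)
  # area below the minimum disqualifies
  expect_null(nonmaxSuppress(list(mk(0.8, 9, c(1, 1))), cfg))
  expect_null(nonmaxSuppress(list(), cfg))
  # ties: probability first, then area, then topmost-leftmost
  win <- nonmaxSuppress(list(mk(0.8, 20, c(9, 9)), mk(0.8, 30, c(5, 5))),
                        cfg)
  expect_equal(win$area, 30)
  win <- nonmaxSuppress(list(mk(0.8, 20, c(9, 2)), mk(0.8, 20, c(5, 5))),
                        cfg)
  expect_equal(win$centroid, c(5, 5))
})

test_that("the centroid is the mean of member pixel locations", {
  one <- list(pixels = matrix(c(10, 20), 1, 2))
  expect_equal(regionCentroid(one), c(10, 20))
  block <- list(pixels = as.matrix(expand.grid(10:11, 20:21)))
  expect_equal(regionCentroid(block), c(10.5, 20.5))
  set.seed(5)
  px <- unique(cbind(sample(30, 40, TRUE), sample(30, 40, TRUE)))[1:37, ]
  reg <- list(pixels = px)
  expect_equal(regionCentroid(reg), unname(colMeans(px)))
  expect_error(regionCentroid(list(pixels = matrix(0, 0, 2))), "empty")
})

test_that("map-level detection matches the stub examples", {
  cfg <- nmsConfig()
  expect_false(detectFromMap(matrix(0, 128, 128), cfg)@present)
  disk <- diskMask(128, 100, 60, 8) * 0.9
  det <- detectFromMap(disk, cfg)
  expect_true(det@present)
  expect_lt(sqrt(sum((det@centroid - c(100, 60))^2)), 0.5)
  expect_equal(det@confidence, 0.9)
  # two blobs: the more confident one wins even if smaller
  two <- matrix(0, 128, 128)
  two[20:29, 20:29] <- 0.55
  two[80:87, 80:87] <- 0.9
  det2 <- detectFromMap(two, cfg)
  expect_equal(det2@centroid, c(83.5, 83.5))
})

test_that("raising the probability threshold never creates a detection", {
  set.seed(8)
  for (i in 1:25) {
    p <- randomProbMap(24, 24)
    was <- detectFromMap(p, nmsConfig(probThreshold = 0.3,
                                      supportThreshold = 0.1,
                                      minArea = 2))@present
    now <- detectFromMap(p, nmsConfig(probThreshold = 0.6,
                                      supportThreshold = 0.1,
                                      minArea = 2))@present
    expect_true(!now || was)
  }
})

test_that("detection equals the exhaustive flood-fill oracle on random maps", {
  set.seed(99)
  for (i in 1:60) {
    H <- sample(8:32, 1); W <- sample(8:32, 1)
    p <- randomProbMap(H, W, nBlobs = sample(1:4, 1))
    cfg <- nmsConfig(probThreshold = 0.5, supportThreshold = 0.1,
                     minArea = sample(c(1L, 4L, 12L), 1),
                     connectivity = sample(c(4L, 8L), 1))
    got <- detectFromMap(p, cfg)
    want <- oracleDetect(p, cfg)
    expect_equal(got@present, want$present)
    if (want$present) {
      expect_equal(got@centroid, want$centroid)
      expect_equal(got@area, want$area)
      expect_equal(got@confidence, want$maxp)
    }
  }
})

test_that("configuration invariants are enforced", {
  expect_error(nmsConfig(probThreshold = 0.5, supportThreshold = 0.6),
               "supportThreshold")
  expect_error(nmsConfig(minArea = 0), "minArea")
  expect_error(nmsConfig(connectivity = 6), "connectivity")
})
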