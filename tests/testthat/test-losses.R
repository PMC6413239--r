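# Loss functions: closed-form identities, set-counting oracle, symmetry,
# monotonicity, and gradient correctness.

test_that("dice loss matches direct set counting on binary masks", {
  pred <- matrix(0, 8, 8); targ <- matrix(0, 8, 8)
  pred[1:2, 1:5] <- 1          # |pred| = 10
  targ[2:3, 1:5] <- 1          # |targ| = 10, overlap = 5
  expect_equal(diceLoss(pred, targ), 1 - 5 / 15, tolerance = 1e-6)
  expect_equal(diceLoss(targ, targ), 0, tolerance = 1e-5)
  disj <- matrix(0, 8, 8); disj[7:8, ] <- 1
  expect_equal(diceLoss(pred, disj), 1, tolerance = 1e-5)
  # empty vs empty counts as a correct rejection
  z <- matrix(0, 8, 8)
  expect_equal(diceLoss(z, z), 0)
  expect_error(diceLoss(matrix(0, 4, 4), matrix(0, 8, 8)), "shapes")
})

test_that("dice loss is symmetric on binary inputs and monotone in overlap", {
  set.seed(1)
  for (i in 1:5) {
    a <- matrix(rbinom(64, 1, 0.3), 8, 8)
    b <- matrix(rbinom(64, 1, 0.3), 8, 8)
    expect_equal(diceLoss(a, b), diceLoss(b, a))
  }
  targ <- matrix(0, 10, 10); targ[3:7, 3:7] <- 1
  outside <- which(row(targ) %in% c(1, 2, 9))   # disjoint from the target
  losses <- sapply(0:5, function(k) {
    pred <- matrix(0, 10, 10)
    if (k > 0) pred[3:7, 3:(2 + k)] <- 1        # 5k overlapping pixels
    rest <- 25 - 5 * k                          # keep |pred| fixed at 25
    if (rest > 0) pred[outside[seq_len(rest)]] <- 1
    diceLoss(pred, targ)
  })
  expect_true(all(diff(losses) < 0))
})

test_that("cross-entropy matches its closed forms", {
  targ <- matrix(rbinom(64, 1, 0.4), 8, 8)
  expect_equal(cateLoss(matrix(0.5, 8, 8), targ), log(2), tolerance = 1e-12)
  expect_equal(cateLoss(targ, targ), 0, tolerance = 1e-6)
  ones <- matrix(1, 8, 8)
  expect_equal(cateLoss(matrix(0, 8, 8), ones), -log(1e-7),
               tolerance = 1e-3)
  expect_error(cateLoss(matrix(0.5, 4, 4), matrix(0, 8, 8)), "shapes")
})

test_that("the combined loss is the beta-weighted sum of its components", {
  set.seed(2)
  pred <- matrix(runif(64), 8, 8)
  targ <- matrix(rbinom(64, 1, 0.3), 8, 8)
  tl <- totalLoss(pred, targ, beta = 0.5)
  expect_equal(tl$value, tl$dice + 0.5 * tl$cate)
  expect_equal(totalLoss(pred, targ, beta = 0)$value, diceLoss(pred, targ))
  same <- matrix(0, 8, 8); same[2:4, 2:4] <- 1
  expect_lt(totalLoss(same, same, beta = 1)$value, 1e-4)
  expect_error(totalLoss(pred, targ, beta = -1), "nonnegative")
})

test_that("analytic loss gradients match numerical differentiation", {
  ns <- asNamespace("polarseg")
  set.seed(3)
  p <- matrix(runif(64, 0.05, 0.95), 8, 8)
  t <- matrix(rbinom(64, 1, 0.3), 8, 8)
  h <- 1e-6
  # dice gradient w.r.t. predictions
  gd <- ns$diceGrad(p, t)
  for (i in sample(64, 8)) {
    pp <- p; pp[i] <- pp[i] + h
    pm <- p; pm[i] <- pm[i] - h
    num <- (diceLoss(pp, t) - diceLoss(pm, t)) / (2 * h)
    expect_equal(gd[i], num, tolerance = 1e-4)
  }
  # combined gradient w.r.t. logits (through the sigmoid)
  z <- qlogis(p)
  gz <- ns$lossGradLogits(p, t, beta = 0.5)
  for (i in sample(64, 8)) {
    zp <- z; zp[i] <- zp[i] + h
    zm <- z; zm[i] <- zm[i] - h
    lp <- totalLoss(matrix(plogis(zp), 8, 8), t, 0.5)$value
    lm <- totalLoss(matrix(plogis(zm), 8, 8), t, 0.5)$value
    expect_equal(gz[i], (lp - lm) / (2 * h), tolerance = 1e-4)
  }
})
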