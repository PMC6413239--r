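# The segmentation network: a contraction-expansion (U-net style)
# architecture of nine inception-style modules I1..I9. Each module splits
# its input into four parallel branches -- (a) 1x1 conv; (b) 1x1 then 3x3;
# (c) 1x1 then 1x3 then 3x1; (d) 3x3 same-padded max-pool then 1x1 -- and
# concatenates the branch outputs along channels, so several receptive-field
# scales coexist at every level. I1-I4 are each followed by 2x2 max-pooling,
# I5 is the bottleneck, and I6-I9 are each preceded by a 2x upconvolution
# whose output is concatenated with the symmetric encoder module's output
# (skip connection). A 1x1 convolution with sigmoid produces the per-pixel
# polar-body probability. Every convolution is followed by batch
# normalization and ReLU except the head.

#' Configuration of one inception module
#'
#' @param inChannels number of input channels (>= 1).
#' @param branchChannels integer 4-tuple: output channels of the three
#'   convolutional branches (1x1; 1x1-3x3; 1x1-1x3-3x1) and the pooling
#'   branch. The module's output width is their sum.
#' @return validated list.
#' @export
inceptionConfig <- function(inChannels, branchChannels) {
  if (length(branchChannels) != 4L || any(branchChannels < 1))
    stop("branchChannels must be 4 counts >= 1", call. = FALSE)
  if (inChannels < 1) stop("inChannels must be >= 1", call. = FALSE)
  list(inChannels = as.integer(inChannels),
       branchChannels = as.integer(branchChannels),
       outChannels = as.integer(sum(branchChannels)))
}

heUniform <- function(nr, nc, fanIn) {
  lim <- sqrt(6 / fanIn)
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# Parameters for one inception module under `prefix`, written into list `P`
# (trainable) and `S` (BN running moments). Internal reduction widths equal
# the branch's output width.
initInception <- function(P, S, prefix, cfg) {
  bc <- cfg$branchChannels
  Cin <- cfg$inChannels
  addConv <- function(P, key, Cin, Cout, k) {
    P[[paste0(key, ".w")]] <- heUniform(Cin * k, Cout, Cin * k)
    P
  }
  addBN <- function(P, S, key, C) {
    P[[paste0(key, ".gamma")]] <- rep(1, C)
    P[[paste0(key, ".beta")]] <- rep(0, C)
    S[[paste0(key, ".rm")]] <- rep(0, C)
    S[[paste0(key, ".rv")]] <- rep(1, C)
    list(P = P, S = S)
  }
  specs <- list(
    list(key = paste0(prefix, ".a"),      cin = Cin,   cout = bc[1], k = 1L),
    list(key = paste0(prefix, ".b.red"),  cin = Cin,   cout = bc[2], k = 1L),
    list(key = paste0(prefix, ".b.conv"), cin = bc[2], cout = bc[2], k = 9L),
    list(key = paste0(prefix, ".c.red"),  cin = Cin,   cout = bc[3], k = 1L),
    list(key = paste0(prefix, ".c.h"),    cin = bc[3], cout = bc[3], k = 3L),
    list(key = paste0(prefix, ".c.v"),    cin = bc[3], cout = bc[3], k = 3L),
    list(key = paste0(prefix, ".d"),      cin = Cin,   cout = bc[4], k = 1L)
  )
  for (s in specs) {
    P <- addConv(P, s$key, s$cin, s$cout, s$k)
    ps <- addBN(P, S, paste0(s$key, ".bn"), s$cout)
    P <- ps$P; S <- ps$S
  }
  list(P = P, S = S)
}

# Forward pass of one inception module on the tape.
inceptionForwardT <- function(tp, P, S, prefix, t, training, momentum, eps) {
  cbr <- function(t, key, kh, kw) {
    opBNRelu(tp, opConv(tp, t, key, P, kh, kw), paste0(key, ".bn"),
             P, S, training, momentum, eps)
  }
  a <- cbr(t, paste0(prefix, ".a"), 1L, 1L)
  b <- cbr(cbr(t, paste0(prefix, ".b.red"), 1L, 1L),
           paste0(prefix, ".b.conv"), 3L, 3L)
  cc <- cbr(cbr(cbr(t, paste0(prefix, ".c.red"), 1L, 1L),
                paste0(prefix, ".c.h"), 1L, 3L),
            paste0(prefix, ".c.v"), 3L, 1L)
  d <- cbr(opMaxPool3(tp, t), paste0(prefix, ".d"), 1L, 1L)
  opConcat(tp, list(a, b, cc, d))
}

#' Build a standalone inception module
#'
#' Mostly useful for inspecting the multi-branch block in isolation; the
#' full network assembles the same blocks internally.
#'
#' @param cfg an [inceptionConfig()].
#' @param seed seed for He-uniform weight initialization.
#' @return an object with `params`, `state` and `cfg`, usable with
#'   [inceptionForward()].
#' @export
buildInceptionModule <- function(cfg, seed = 1L) {
  ps <- withSeed(seed, initInception(list(), list(), "m", cfg))
  structure(list(params = ps$P, state = ps$S, cfg = cfg),
            class = "InceptionModule")
}

#' Apply an inception module to an image stack
#'
#' Spatial dimensions are preserved; output channels are the sum of the
#' four branch widths. Inference-mode batch normalization is used, so the
#' result is deterministic for fixed weights.
#'
#' @param module from [buildInceptionModule()].
#' @param x numeric H x W matrix (1 input channel) or H x W x C array.
#' @return H x W x outChannels array.
#' @export
inceptionForward <- function(module, x) {
  if (is.matrix(x)) x <- array(x, c(nrow(x), ncol(x), 1L))
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  if (C != module$cfg$inChannels)
    stop("input has ", C, " channels, module expects ",
         module$cfg$inChannels, call. = FALSE)
  X <- matrix(aperm(x, c(2, 1, 3)), nrow = H * W, ncol = C)
  tp <- tapeNew()
  t0 <- tten(tp, f_d2f(as.vector(X)), C, H, W, 1L)
  out <- inceptionForwardT(tp, module$params, module$state, "m", t0,
                           training = FALSE, momentum = 0.9, eps = 1e-5)
  y <- matrix(f_f2d(out$x), nrow = H * W, ncol = out$C)
  aperm(array(y, c(W, H, out$C)), c(2, 1, 3))
}

#' Network architecture configuration
#'
#' The channel schedule follows the standard U-net convention: module I1
#' emits `baseChannels`, widths double at each of the four poolings (16x at
#' the bottleneck I5) and halve back up the decoder. `baseChannels` must be
#' divisible by 4 (four equal-width branches per module).
#'
#' @param baseChannels output width of module I1 (default 32).
#' @param inChannels input image channels (1 for grayscale).
#' @param upsample "transposed" (stride-2 transposed convolution, default)
#'   or "nearest" (nearest-neighbour upsampling followed by a 1x1
#'   convolution).
#' @param bnMomentum running-moment momentum of batch normalization.
#' @param bnEps batch-normalization variance floor.
#' @param seed weight-initialization seed.
#' @return validated list.
#' @export
networkConfig <- function(baseChannels = 32L, inChannels = 1L,
                          upsample = c("transposed", "nearest"),
                          bnMomentum = 0.9, bnEps = 1e-5, seed = 42L) {
  upsample <- match.arg(upsample)
  if (baseChannels < 4 || baseChannels %% 4L != 0L)
    stop("baseChannels must be a positive multiple of 4", call. = FALSE)
  list(baseChannels = as.integer(baseChannels),
       inChannels = as.integer(inChannels), upsample = upsample,
       bnMomentum = bnMomentum, bnEps = bnEps, seed = as.integer(seed))
}

# Channel schedule of the nine modules given the base width.
channelSchedule <- function(bc) {
  list(
    enc = c(I1 = bc, I2 = 2L * bc, I3 = 4L * bc, I4 = 8L * bc,
            I5 = 16L * bc),
    dec = c(I6 = 8L * bc, I7 = 4L * bc, I8 = 2L * bc, I9 = bc)
  )
}

#' Build the nine-module segmentation network
#'
#' @param config a [networkConfig()].
#' @return a [SegmentationNetwork-class] with freshly initialized weights
#'   (He-uniform, deterministic under `config$seed`).
#' @export
buildNetwork <- function(config = networkConfig()) {
  bc <- config$baseChannels
  sch <- channelSchedule(bc)
  withSeed(config$seed, {
    P <- list(); S <- list()
    cins <- c(config$inChannels, sch$enc[1:4])
    for (i in 1:5) {
      cfg <- inceptionConfig(cins[i], rep(sch$enc[i] %/% 4L, 4L))
      ps <- initInception(P, S, paste0("I", i), cfg)
      P <- ps$P; S <- ps$S
    }
    upIn <- c(sch$enc[5], sch$dec[1:3])
    for (j in 1:4) {
      upOut <- sch$dec[j]
      key <- paste0("U", j)
      if (config$upsample == "transposed") {
        P[[paste0(key, ".w")]] <- heUniform(4L * upIn[j], upOut, upIn[j])
      } else {
        P[[paste0(key, ".w")]] <- heUniform(upIn[j], upOut, upIn[j])
      }
      P[[paste0(key, ".bn.gamma")]] <- rep(1, upOut)
      P[[paste0(key, ".bn.beta")]] <- rep(0, upOut)
      S[[paste0(key, ".bn.rm")]] <- rep(0, upOut)
      S[[paste0(key, ".bn.rv")]] <- rep(1, upOut)
      skip <- sch$enc[5L - j]
      cfg <- inceptionConfig(upOut + skip, rep(sch$dec[j] %/% 4L, 4L))
      ps <- initInception(P, S, paste0("I", 5L + j), cfg)
      P <- ps$P; S <- ps$S
    }
    P[["head.w"]] <- heUniform(bc, 1L, bc)
    P[["head.b"]] <- 0
    new("SegmentationNetwork", params = P, state = S, config = config)
  })
}

# Full forward pass to pre-sigmoid logits. `P`/`S` may be lists (read-only)
# or environments (training updates BN running moments in place).
netForward <- function(P, S, X, H, W, B, cfg, training = FALSE) {
  if (H %% 16L != 0L || W %% 16L != 0L)
    stop("input size ", H, "x", W, " is not divisible by 16", call. = FALSE)
  mom <- cfg$bnMomentum; eps <- cfg$bnEps
  tp <- tapeNew()
  t0 <- tten(tp, f_d2f(as.vector(X)), cfg$inChannels, H, W, B)
  inc <- function(prefix, t) inceptionForwardT(tp, P, S, prefix, t,
                                               training, mom, eps)
  e1 <- inc("I1", t0)
  e2 <- inc("I2", opMaxPool2(tp, e1))
  e3 <- inc("I3", opMaxPool2(tp, e2))
  e4 <- inc("I4", opMaxPool2(tp, e3))
  bott <- inc("I5", opMaxPool2(tp, e4))
  up <- function(key, t) {
    u <- if (cfg$upsample == "transposed") opUpconv2(tp, t, key, P)
         else opConv(tp, opUpsampleNearest(tp, t), key, P, 1L, 1L)
    opBNRelu(tp, u, paste0(key, ".bn"), P, S, training, mom, eps)
  }
  d4 <- inc("I6", opConcat(tp, list(up("U1", bott), e4)))
  d3 <- inc("I7", opConcat(tp, list(up("U2", d4), e3)))
  d2 <- inc("I8", opConcat(tp, list(up("U3", d3), e2)))
  d1 <- inc("I9", opConcat(tp, list(up("U4", d2), e1)))
  z <- opConv(tp, d1, "head", P, 1L, 1L, bias = TRUE)
  list(logits = z, tape = tp)
}

#' Predict the polar-body probability map for a micrograph
#'
#' Runs the network in inference mode (batch normalization uses running
#' moments), so repeated calls with fixed weights are bit-identical.
#'
#' @param net a [SegmentationNetwork-class].
#' @param img a [Micrograph-class] or numeric matrix in \[0, 1\] with
#'   dimensions divisible by 16.
#' @return a [ProbabilityMap-class] of the same spatial shape.
#' @export
predictMap <- function(net, img) {
  m <- asPixels(img)
  H <- nrow(m); W <- ncol(m)
  X <- matrix(as.vector(t(m)), ncol = 1L)
  fw <- netForward(net@params, net@state, X, H, W, 1L, net@config,
                   training = FALSE)
  ProbabilityMap(fromRowMajor(f_sigmoid(fw$logits$x), H, W))
}

#' Total number of trainable parameters
#'
#' @param net a [SegmentationNetwork-class].
#' @return integer count over all weight arrays.
#' @export
parameterCount <- function(net) {
  sum(vapply(net@params, length, integer(1)))
}
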