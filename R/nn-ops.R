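# Reverse-mode engine driving the float32 kernels in src/ops.cpp.
#
# Activations are raw vectors of IEEE float32 (one column per channel, rows
# row-major over batch/row/col); master weights stay double on the R side,
# so Adam and checkpoints are plain numeric. A small tape records the op
# sequence during the forward pass; tapeBackward walks it in reverse and
# returns double parameter gradients. Everything is single-threaded and
# sequenced, hence bit-reproducible for a fixed seed.

# ---- tape ------------------------------------------------------------------

tapeNew <- function() {
  tp <- new.env(parent = emptyenv())
  tp$recs <- vector("list", 128L)
  tp$nrec <- 0L
  tp$nid <- 0L
  tp
}

tapeId <- function(tp) {
  tp$nid <- tp$nid + 1L
  tp$nid
}

tapeRec <- function(tp, r) {
  tp$nrec <- tp$nrec + 1L
  if (tp$nrec > length(tp$recs)) length(tp$recs) <- 2L * length(tp$recs)
  tp$recs[[tp$nrec]] <- r
}

# A "tensor" on the tape: raw float32 buffer plus channel count and spatial
# shape. N = H*W*B rows.
tten <- function(tp, x, C, H, W, B) {
  list(id = tapeId(tp), x = x, C = C, H = H, W = W, B = B)
}

tN <- function(t) t$H * t$W * t$B

# ---- ops -------------------------------------------------------------------

# Convolution with an odd (kh x kw) same-padded kernel. Weight layout:
# (Cin*kh*kw) x Cout, one Cin-row block per kernel offset (di outer, dj
# inner). 1x1 kernels go through sgemm, spatial kernels through the direct
# loops.
opConv <- function(tp, t, key, P, kh = 1L, kw = 1L, bias = FALSE) {
  W <- P[[paste0(key, ".w")]]
  b <- if (bias) P[[paste0(key, ".b")]] else numeric(0)
  if (kh == 1L && kw == 1L) {
    path <- "gemm"
    xcol <- NULL
    y <- f_gemm_fwd(t$x, tN(t), t$C, W, b)
  } else if (t$W >= 64L) {
    # shallow levels: big canvas, few channels -- direct loops win
    path <- "direct"
    xcol <- NULL
    y <- f_conv_fwd(t$x, t$H, t$W, t$B, t$C, W, kh, kw)
  } else {
    # deep levels: small canvas, many channels -- im2col + sgemm wins
    path <- "im2col"
    xcol <- f_im2col(t$x, t$H, t$W, t$B, t$C, kh, kw)
    y <- f_gemm_fwd(xcol, tN(t), t$C * kh * kw, W, b)
  }
  out <- tten(tp, y, ncol(W), t$H, t$W, t$B)
  tapeRec(tp, list(op = "conv", out = out$id, inp = t$id, key = key,
                   kh = kh, kw = kw, bias = bias, x = t$x, xcol = xcol,
                   path = path, C = t$C, Cout = ncol(W),
                   H = t$H, W = t$W, B = t$B))
  out
}

convBackward <- function(r, g, P, addG, addP) {
  W <- P[[paste0(r$key, ".w")]]
  N <- r$H * r$W * r$B
  if (r$path == "gemm") {
    addP(paste0(r$key, ".w"), f_gemm_dw(r$x, N, r$C, g, r$Cout))
    addG(r$inp, f_gemm_dx(g, N, r$Cout, W))
  } else if (r$path == "direct") {
    addP(paste0(r$key, ".w"),
         f_conv_dw(r$x, g, r$H, r$W, r$B, r$C, r$Cout, r$kh, r$kw))
    addG(r$inp, f_conv_dx(g, r$H, r$W, r$B, r$C, W, r$kh, r$kw))
  } else {
    addP(paste0(r$key, ".w"),
         f_gemm_dw(r$xcol, N, r$C * r$kh * r$kw, g, r$Cout))
    dcol <- f_gemm_dx(g, N, r$Cout, W)
    addG(r$inp, f_col2im(dcol, r$H, r$W, r$B, r$C, r$kh, r$kw))
  }
  if (r$bias) addP(paste0(r$key, ".b"), f_colsum(g, N, r$Cout))
}

# Fused batch normalization + ReLU. Training mode uses batch moments
# (biased variance) and updates the running moments in the state
# environment; inference uses the running moments and keeps nothing.
opBNRelu <- function(tp, t, key, P, S, training, momentum = 0.9,
                     eps = 1e-5) {
  gamma <- P[[paste0(key, ".gamma")]]
  beta <- P[[paste0(key, ".beta")]]
  N <- tN(t)
  if (training) {
    fw <- f_bnrelu_train(t$x, N, t$C, gamma, beta, eps)
    S[[paste0(key, ".rm")]] <- momentum * S[[paste0(key, ".rm")]] +
      (1 - momentum) * fw$mu
    S[[paste0(key, ".rv")]] <- momentum * S[[paste0(key, ".rv")]] +
      (1 - momentum) * fw$var
    out <- tten(tp, fw$y, t$C, t$H, t$W, t$B)
    tapeRec(tp, list(op = "bnrelu", out = out$id, inp = t$id, key = key,
                     x = t$x, y = fw$y, mu = fw$mu, invstd = fw$invstd,
                     C = t$C, N = N))
  } else {
    y <- f_bnrelu_eval(t$x, N, t$C, gamma, beta,
                       S[[paste0(key, ".rm")]], S[[paste0(key, ".rv")]],
                       eps)
    out <- tten(tp, y, t$C, t$H, t$W, t$B)
  }
  out
}

bnreluBackward <- function(r, g, P, addG, addP) {
  bw <- f_bnrelu_bwd(g, r$x, r$y, r$N, r$C,
                     P[[paste0(r$key, ".gamma")]], r$mu, r$invstd)
  addP(paste0(r$key, ".gamma"), bw$dgamma)
  addP(paste0(r$key, ".beta"), bw$dbeta)
  addG(r$inp, bw$dx)
}

opMaxPool2 <- function(tp, t) {
  mp <- f_maxpool2(t$x, t$H, t$W, t$B, t$C)
  out <- tten(tp, mp$y, t$C, t$H %/% 2L, t$W %/% 2L, t$B)
  tapeRec(tp, list(op = "mp2", out = out$id, inp = t$id, wh = mp$wh,
                   C = t$C, H = t$H, W = t$W, B = t$B))
  out
}

opMaxPool3 <- function(tp, t) {
  mp <- f_maxpool3(t$x, t$H, t$W, t$B, t$C)
  out <- tten(tp, mp$y, t$C, t$H, t$W, t$B)
  tapeRec(tp, list(op = "mp3", out = out$id, inp = t$id, wh = mp$wh,
                   C = t$C, H = t$H, W = t$W, B = t$B))
  out
}

# 2x2 stride-2 transposed convolution; weight (Cin*4) x Cout blocked per
# output sub-position.
opUpconv2 <- function(tp, t, key, P) {
  W <- P[[paste0(key, ".w")]]
  y <- f_up2_fwd(t$x, t$H, t$W, t$B, t$C, W)
  out <- tten(tp, y, ncol(W), 2L * t$H, 2L * t$W, t$B)
  tapeRec(tp, list(op = "up2", out = out$id, inp = t$id, key = key,
                   x = t$x, C = t$C, H = t$H, W = t$W, B = t$B))
  out
}

opUpsampleNearest <- function(tp, t) {
  y <- f_upnn_fwd(t$x, t$H, t$W, t$B, t$C)
  out <- tten(tp, y, t$C, 2L * t$H, 2L * t$W, t$B)
  tapeRec(tp, list(op = "upnn", out = out$id, inp = t$id,
                   C = t$C, H = t$H, W = t$W, B = t$B))
  out
}

opConcat <- function(tp, ts) {
  N <- tN(ts[[1]])
  y <- if (length(ts) == 2L) {
    f_concat2(ts[[1]]$x, ts[[1]]$C, ts[[2]]$x, ts[[2]]$C, N)
  } else {
    f_concat4(ts[[1]]$x, ts[[1]]$C, ts[[2]]$x, ts[[2]]$C,
              ts[[3]]$x, ts[[3]]$C, ts[[4]]$x, ts[[4]]$C, N)
  }
  widths <- vapply(ts, `[[`, integer(1), "C")
  out <- tten(tp, y, sum(widths), ts[[1]]$H, ts[[1]]$W, ts[[1]]$B)
  tapeRec(tp, list(op = "concat", out = out$id,
                   inps = vapply(ts, `[[`, integer(1), "id"),
                   widths = widths, N = N))
  out
}

# ---- backward driver -------------------------------------------------------

tapeBackward <- function(tp, outTensor, dOut, P) {
  grads <- new.env(parent = emptyenv())
  pgrads <- new.env(parent = emptyenv())
  assign(as.character(outTensor$id), dOut, envir = grads)
  addG <- function(id, g) {
    k <- as.character(id)
    cur <- grads[[k]]
    if (is.null(cur)) grads[[k]] <- g else f_add_inplace(cur, g)
  }
  addP <- function(key, g) {
    cur <- pgrads[[key]]
    pgrads[[key]] <- if (is.null(cur)) g else cur + g
  }
  for (i in rev(seq_len(tp$nrec))) {
    r <- tp$recs[[i]]
    k <- as.character(r$out)
    g <- grads[[k]]
    if (is.null(g)) next
    rm(list = k, envir = grads)
    switch(r$op,
      conv = convBackward(r, g, P, addG, addP),
      bnrelu = bnreluBackward(r, g, P, addG, addP),
      mp2 = addG(r$inp, f_maxpool2_bwd(g, r$wh, r$H, r$W, r$B, r$C)),
      mp3 = addG(r$inp, f_maxpool3_bwd(g, r$wh, r$H, r$W, r$B, r$C)),
      up2 = {
        bw <- f_up2_bwd(r$x, g, r$H, r$W, r$B, r$C,
                        P[[paste0(r$key, ".w")]])
        addP(paste0(r$key, ".w"), bw$dw)
        addG(r$inp, bw$dx)
      },
      upnn = addG(r$inp, f_upnn_bwd(g, r$H, r$W, r$B, r$C)),
      concat = {
        off <- 0L
        for (j in seq_along(r$inps)) {
          addG(r$inps[j], f_colslice(g, r$N, off + 1L, r$widths[j]))
          off <- off + r$widths[j]
        }
      },
      stop("unknown op on tape: ", r$op)
    )
  }
  pgrads
}
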