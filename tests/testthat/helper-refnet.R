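# Independent double-precision reference implementation of the network
# forward/backward, written with plain R matrix operations (offset-shifted
# GEMMs, colMeans batch norm, pmax pooling). Used to cross-check the
# package's float32 engine on small inputs: both implement the same
# architecture but share no code path. Tensors here are double matrices
# (B*H*W rows, row-major over batch/row/col; one column per channel).

refPadIdx <- function(H, W, B, ph, pw) {
  Hp <- H + 2L * ph; Wp <- W + 2L * pw
  bb <- rep(seq_len(B) - 1L, each = H * W)
  rr <- rep(rep(seq_len(H), each = W), times = B)
  cc <- rep(seq_len(W), times = H * B)
  list(inner = (bb * Hp + (rr + ph - 1L)) * Wp + (cc + pw), Hp = Hp, Wp = Wp)
}

refConvFwd <- function(X, Wt, H, W, B, kh, kw) {
  Cin <- ncol(X)
  if (kh == 1L && kw == 1L) return(X %*% Wt)
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  pd <- refPadIdx(H, W, B, ph, pw)
  Xp <- matrix(0, B * pd$Hp * pd$Wp, Cin)
  Xp[pd$inner, ] <- X
  Y <- matrix(0, nrow(X), ncol(Wt))
  o <- 0L
  for (di in -ph:ph) for (dj in -pw:pw) {
    o <- o + 1L
    rows <- ((o - 1L) * Cin + 1L):(o * Cin)
    Y <- Y + Xp[pd$inner + (di * pd$Wp + dj), , drop = FALSE] %*%
      Wt[rows, , drop = FALSE]
  }
  Y
}

refConvBwd <- function(X, Wt, G, H, W, B, kh, kw) {
  Cin <- ncol(X)
  if (kh == 1L && kw == 1L)
    return(list(dx = G %*% t(Wt), dw = crossprod(X, G)))
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  pd <- refPadIdx(H, W, B, ph, pw)
  Xp <- matrix(0, B * pd$Hp * pd$Wp, Cin)
  Xp[pd$inner, ] <- X
  dW <- matrix(0, nrow(Wt), ncol(Wt))
  dXp <- matrix(0, nrow(Xp), Cin)
  o <- 0L
  for (di in -ph:ph) for (dj in -pw:pw) {
    o <- o + 1L
    rows <- ((o - 1L) * Cin + 1L):(o * Cin)
    sh <- pd$inner + (di * pd$Wp + dj)
    dW[rows, ] <- crossprod(Xp[sh, , drop = FALSE], G)
    dXp[sh, ] <- dXp[sh, , drop = FALSE] + G %*% t(Wt[rows, , drop = FALSE])
  }
  list(dx = dXp[pd$inner, , drop = FALSE], dw = dW)
}

refBNReluFwd <- function(X, gamma, beta, eps = 1e-5) {
  n <- nrow(X)
  mu <- colMeans(X)
  v <- pmax(colMeans(X^2) - mu^2, 0)
  invstd <- 1 / sqrt(v + eps)
  xhat <- (X - rep(mu, each = n)) * rep(invstd, each = n)
  y <- pmax(xhat * rep(gamma, each = n) + rep(beta, each = n), 0)
  list(y = y, xhat = xhat, invstd = invstd, mu = mu, v = v)
}

refBNReluBwd <- function(fw, G, gamma) {
  n <- nrow(G)
  G <- G * (fw$y > 0)
  dgamma <- colSums(G * fw$xhat)
  dbeta <- colSums(G)
  dxhat <- G * rep(gamma, each = n)
  s1 <- colSums(dxhat); s2 <- colSums(dxhat * fw$xhat)
  dx <- (dxhat - rep(s1 / n, each = n) - fw$xhat * rep(s2 / n, each = n)) *
    rep(fw$invstd, each = n)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

refPool2Base <- function(H, W, B) {
  Ho <- H %/% 2L; Wo <- W %/% 2L
  bb <- rep(seq_len(B) - 1L, each = Ho * Wo)
  rr <- rep(rep(seq_len(Ho), each = Wo), times = B)
  cc <- rep(seq_len(Wo), times = Ho * B)
  (bb * H + (2L * rr - 2L)) * W + (2L * cc - 1L)
}

refMaxPool2Fwd <- function(X, H, W, B) {
  base <- refPool2Base(H, W, B)
  y <- NULL; wh <- NULL; o <- 0L
  for (di in 0:1) for (dj in 0:1) {
    o <- o + 1L
    xo <- X[base + (di * W + dj), , drop = FALSE]
    if (is.null(y)) { y <- xo; wh <- matrix(1L, nrow(xo), ncol(xo)) }
    else { upd <- xo > y; y[upd] <- xo[upd]; wh[upd] <- o }
  }
  list(y = y, wh = wh)
}

refMaxPool2Bwd <- function(fw, G, H, W, B) {
  base <- refPool2Base(H, W, B)
  dx <- matrix(0, H * W * B, ncol(G))
  o <- 0L
  for (di in 0:1) for (dj in 0:1) {
    o <- o + 1L
    go <- G; go[fw$wh != o] <- 0
    idx <- base + (di * W + dj)
    dx[idx, ] <- dx[idx, , drop = FALSE] + go
  }
  dx
}

refMaxPool3Fwd <- function(X, H, W, B) {
  pd <- refPadIdx(H, W, B, 1L, 1L)
  Xp <- matrix(-Inf, B * pd$Hp * pd$Wp, ncol(X))
  Xp[pd$inner, ] <- X
  y <- NULL; wh <- NULL; o <- 0L
  for (di in -1:1) for (dj in -1:1) {
    o <- o + 1L
    xo <- Xp[pd$inner + (di * pd$Wp + dj), , drop = FALSE]
    if (is.null(y)) { y <- xo; wh <- matrix(1L, nrow(xo), ncol(xo)) }
    else { upd <- xo > y; y[upd] <- xo[upd]; wh[upd] <- o }
  }
  list(y = y, wh = wh)
}

refMaxPool3Bwd <- function(fw, G, H, W, B) {
  pd <- refPadIdx(H, W, B, 1L, 1L)
  dXp <- matrix(0, B * pd$Hp * pd$Wp, ncol(G))
  o <- 0L
  for (di in -1:1) for (dj in -1:1) {
    o <- o + 1L
    go <- G; go[fw$wh != o] <- 0
    idx <- pd$inner + (di * pd$Wp + dj)
    dXp[idx, ] <- dXp[idx, , drop = FALSE] + go
  }
  dXp[pd$inner, , drop = FALSE]
}

refUp2Base <- function(H, W, B) {
  bb <- rep(seq_len(B) - 1L, each = H * W)
  rr <- rep(rep(seq_len(H), each = W), times = B)
  cc <- rep(seq_len(W), times = H * B)
  (bb * 2L * H + (2L * rr - 2L)) * 2L * W + (2L * cc - 1L)
}

refUp2Fwd <- function(X, Wt, H, W, B) {
  Cin <- ncol(X)
  base <- refUp2Base(H, W, B)
  y <- matrix(0, 4L * nrow(X), ncol(Wt))
  o <- 0L
  for (di in 0:1) for (dj in 0:1) {
    o <- o + 1L
    rows <- ((o - 1L) * Cin + 1L):(o * Cin)
    y[base + (di * 2L * W + dj), ] <- X %*% Wt[rows, , drop = FALSE]
  }
  y
}

refUp2Bwd <- function(X, Wt, G, H, W, B) {
  Cin <- ncol(X)
  base <- refUp2Base(H, W, B)
  dW <- matrix(0, nrow(Wt), ncol(Wt))
  dx <- matrix(0, nrow(X), Cin)
  o <- 0L
  for (di in 0:1) for (dj in 0:1) {
    o <- o + 1L
    rows <- ((o - 1L) * Cin + 1L):(o * Cin)
    go <- G[base + (di * 2L * W + dj), , drop = FALSE]
    dW[rows, ] <- crossprod(X, go)
    dx <- dx + go %*% t(Wt[rows, , drop = FALSE])
  }
  list(dx = dx, dw = dW)
}

# Reference forward + backward of the whole nine-module network in double
# precision (training-mode batch norm, batch moments; running stats are not
# tracked -- only the gradients and logits are compared).
refNetGrad <- function(params, X, dZ, H, W, B, baseChannels) {
  P <- params
  acts <- list()   # forward caches keyed by layer name
  cbrF <- function(x, key, kh, kw, H, W) {
    y <- refConvFwd(x, P[[paste0(key, ".w")]], H, W, B, kh, kw)
    fw <- refBNReluFwd(y, P[[paste0(key, ".bn.gamma")]],
                       P[[paste0(key, ".bn.beta")]])
    acts[[key]] <<- list(x = x, bn = fw, kh = kh, kw = kw, H = H, W = W)
    fw$y
  }
  incF <- function(prefix, x, H, W) {
    a <- cbrF(x, paste0(prefix, ".a"), 1L, 1L, H, W)
    b <- cbrF(cbrF(x, paste0(prefix, ".b.red"), 1L, 1L, H, W),
              paste0(prefix, ".b.conv"), 3L, 3L, H, W)
    mp <- refMaxPool3Fwd(x, H, W, B)
    acts[[paste0(prefix, ".mp3")]] <<- mp
    d <- cbrF(mp$y, paste0(prefix, ".d"), 1L, 1L, H, W)
    cc <- cbrF(cbrF(cbrF(x, paste0(prefix, ".c.red"), 1L, 1L, H, W),
                    paste0(prefix, ".c.h"), 1L, 3L, H, W),
               paste0(prefix, ".c.v"), 3L, 1L, H, W)
    cbind(a, b, cc, d)
  }
  upF <- function(key, x, H, W) {
    y <- refUp2Fwd(x, P[[paste0(key, ".w")]], H, W, B)
    fw <- refBNReluFwd(y, P[[paste0(key, ".bn.gamma")]],
                       P[[paste0(key, ".bn.beta")]])
    acts[[key]] <<- list(x = x, bn = fw, H = H, W = W)
    fw$y
  }
  e1 <- incF("I1", X, H, W)
  p1 <- refMaxPool2Fwd(e1, H, W, B); acts[["P1"]] <- p1
  e2 <- incF("I2", p1$y, H %/% 2L, W %/% 2L)
  p2 <- refMaxPool2Fwd(e2, H %/% 2L, W %/% 2L, B); acts[["P2"]] <- p2
  e3 <- incF("I3", p2$y, H %/% 4L, W %/% 4L)
  p3 <- refMaxPool2Fwd(e3, H %/% 4L, W %/% 4L, B); acts[["P3"]] <- p3
  e4 <- incF("I4", p3$y, H %/% 8L, W %/% 8L)
  p4 <- refMaxPool2Fwd(e4, H %/% 8L, W %/% 8L, B); acts[["P4"]] <- p4
  e5 <- incF("I5", p4$y, H %/% 16L, W %/% 16L)
  u1 <- upF("U1", e5, H %/% 16L, W %/% 16L)
  d4 <- incF("I6", cbind(u1, e4), H %/% 8L, W %/% 8L)
  u2 <- upF("U2", d4, H %/% 8L, W %/% 8L)
  d3 <- incF("I7", cbind(u2, e3), H %/% 4L, W %/% 4L)
  u3 <- upF("U3", d3, H %/% 4L, W %/% 4L)
  d2 <- incF("I8", cbind(u3, e2), H %/% 2L, W %/% 2L)
  u4 <- upF("U4", d2, H %/% 2L, W %/% 2L)
  d1 <- incF("I9", cbind(u4, e1), H, W)
  acts[["d1"]] <- d1
  logits <- d1 %*% P[["head.w"]] + rep(P[["head.b"]], nrow(d1))

  # ---- backward ----
  pg <- list()
  cbrB <- function(g, key) {
    a <- acts[[key]]
    bw <- refBNReluBwd(a$bn, g, P[[paste0(key, ".bn.gamma")]])
    pg[[paste0(key, ".bn.gamma")]] <<- bw$dgamma
    pg[[paste0(key, ".bn.beta")]] <<- bw$dbeta
    cb <- refConvBwd(a$x, P[[paste0(key, ".w")]], bw$dx, a$H, a$W, B,
                     a$kh, a$kw)
    pg[[paste0(key, ".w")]] <<- cb$dw
    cb$dx
  }
  incB <- function(prefix, g, H, W) {
    C4 <- ncol(g) %/% 4L
    ga <- g[, 1:C4, drop = FALSE]
    gb <- g[, (C4 + 1):(2 * C4), drop = FALSE]
    gc <- g[, (2 * C4 + 1):(3 * C4), drop = FALSE]
    gd <- g[, (3 * C4 + 1):(4 * C4), drop = FALSE]
    dx <- cbrB(ga, paste0(prefix, ".a"))
    dx <- dx + cbrB(cbrB(gb, paste0(prefix, ".b.conv")),
                    paste0(prefix, ".b.red"))
    dx <- dx + cbrB(cbrB(cbrB(gc, paste0(prefix, ".c.v")),
                         paste0(prefix, ".c.h")), paste0(prefix, ".c.red"))
    dmp <- cbrB(gd, paste0(prefix, ".d"))
    dx + refMaxPool3Bwd(acts[[paste0(prefix, ".mp3")]], dmp, H, W, B)
  }
  upB <- function(key, g) {
    a <- acts[[key]]
    bw <- refBNReluBwd(a$bn, g, P[[paste0(key, ".bn.gamma")]])
    pg[[paste0(key, ".bn.gamma")]] <<- bw$dgamma
    pg[[paste0(key, ".bn.beta")]] <<- bw$dbeta
    ub <- refUp2Bwd(a$x, P[[paste0(key, ".w")]], bw$dx, a$H, a$W, B)
    pg[[paste0(key, ".w")]] <<- ub$dw
    ub$dx
  }
  pg[["head.w"]] <- crossprod(acts[["d1"]], dZ)
  pg[["head.b"]] <- sum(dZ)
  g <- dZ %*% t(P[["head.w"]])
  g <- incB("I9", g, H, W)
  cu <- ncol(g) %/% 2L
  gU4 <- g[, 1:cu, drop = FALSE]; ge1 <- g[, (cu + 1):ncol(g), drop = FALSE]
  g <- upB("U4", gU4)
  g <- incB("I8", g, H %/% 2L, W %/% 2L)
  cu <- ncol(g) %/% 2L
  gU3 <- g[, 1:cu, drop = FALSE]; ge2 <- g[, (cu + 1):ncol(g), drop = FALSE]
  g <- upB("U3", gU3)
  g <- incB("I7", g, H %/% 4L, W %/% 4L)
  cu <- ncol(g) %/% 2L
  gU2 <- g[, 1:cu, drop = FALSE]; ge3 <- g[, (cu + 1):ncol(g), drop = FALSE]
  g <- upB("U2", gU2)
  g <- incB("I6", g, H %/% 8L, W %/% 8L)
  cu <- ncol(g) %/% 2L
  gU1 <- g[, 1:cu, drop = FALSE]; ge4 <- g[, (cu + 1):ncol(g), drop = FALSE]
  g <- upB("U1", gU1)
  gE5 <- incB("I5", g, H %/% 16L, W %/% 16L)
  gP4 <- refMaxPool2Bwd(acts[["P4"]], gE5, H %/% 8L, W %/% 8L, B) + ge4
  gE4 <- incB("I4", gP4, H %/% 8L, W %/% 8L)
  gP3 <- refMaxPool2Bwd(acts[["P3"]], gE4, H %/% 4L, W %/% 4L, B) + ge3
  gE3 <- incB("I3", gP3, H %/% 4L, W %/% 4L)
  gP2 <- refMaxPool2Bwd(acts[["P2"]], gE3, H %/% 2L, W %/% 2L, B) + ge2
  gE2 <- incB("I2", gP2, H %/% 2L, W %/% 2L)
  gP1 <- refMaxPool2Bwd(acts[["P1"]], gE2, H, W, B) + ge1
  gE1 <- incB("I1", gP1, H, W)
  list(logits = logits, grads = pg, dX = gE1)
}
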