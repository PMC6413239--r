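# Internal numerical utilities shared by the synthesis, augmentation and
# network code. Nothing here is exported.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Unit-sum 1-D Gaussian kernel truncated at `truncate` standard deviations.
gaussianKernel1d <- function(sigma, truncate = 4) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma > 0)
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# n x n banded convolution matrix for the 1-D Gaussian above, with replicate
# (clamp-to-edge) boundary folding so every row still sums to one.
blurMatrix1d <- function(n, sigma, truncate = 4) {
  k <- gaussianKernel1d(sigma, truncate)
  r <- (length(k) - 1L) %/% 2L
  K <- matrix(0, n, n)
  i <- seq_len(n)
  for (off in -r:r) {
    j <- pmin(pmax(i + off, 1L), n)
    idx <- cbind(i, j)
    K[idx] <- K[idx] + k[off + r + 1L]
  }
  K
}

# Separable Gaussian blur of a matrix: rows then columns, replicate boundary.
gaussBlur2d <- function(x, sigma, truncate = 4) {
  if (sigma <= 0) return(x)
  Kr <- blurMatrix1d(nrow(x), sigma, truncate)
  Kc <- blurMatrix1d(ncol(x), sigma, truncate)
  Kr %*% x %*% t(Kc)
}

# Reflect an integer index into [1, n] (mirror about the edges, period 2n-2).
reflectIndex <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n - 2L
  i <- (i - 1L) %% p
  i <- ifelse(i < 0L, i + p, i)
  as.integer(ifelse(i >= n, p - i, i) + 1L)
}

clampIndex <- function(i, n) pmin(pmax(i, 1L), n)

# Bilinear sampling of `img` at fractional (row, col) source coordinates.
# border = "reflect" mirrors out-of-canvas coordinates; "constant" uses `fill`.
bilinearSample <- function(img, sr, sc, border = c("reflect", "constant"),
                           fill = 0) {
  border <- match.arg(border)
  H <- nrow(img); W <- ncol(img)
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  ri <- as.integer(r0); ci <- as.integer(c0)
  pick <- function(rr, cc) {
    if (border == "reflect") {
      img[cbind(reflectIndex(rr, H), reflectIndex(cc, W))]
    } else {
      ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
      v <- rep(fill, length(rr))
      if (any(ok)) v[ok] <- img[cbind(rr[ok], cc[ok])]
      v
    }
  }
  v00 <- pick(ri,      ci)
  v01 <- pick(ri,      ci + 1L)
  v10 <- pick(ri + 1L, ci)
  v11 <- pick(ri + 1L, ci + 1L)
  v00 * (1 - fr) * (1 - fc) + v01 * (1 - fr) * fc +
    v10 * fr * (1 - fc) + v11 * fr * fc
}

# Nearest-neighbour sampling (used for masks so values stay binary).
nearestSample <- function(img, sr, sc, border = c("reflect", "constant"),
                          fill = 0) {
  border <- match.arg(border)
  H <- nrow(img); W <- ncol(img)
  rr <- as.integer(round(sr)); cc <- as.integer(round(sc))
  if (border == "reflect") {
    img[cbind(reflectIndex(rr, H), reflectIndex(cc, W))]
  } else {
    ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
    v <- rep(fill, length(rr))
    if (any(ok)) v[ok] <- img[cbind(rr[ok], cc[ok])]
    v
  }
}

# Output-pixel grid of an H x W canvas as (row, col) vectors, row-major.
canvasGrid <- function(H, W) {
  list(r = rep(seq_len(H), each = W), c = rep(seq_len(W), times = H))
}

# Rebuild a row-major sample vector into an H x W matrix.
fromRowMajor <- function(v, H, W) matrix(v, H, W, byrow = TRUE)

# Derive a stream of independent sub-seeds from one master seed (< 2^31).
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}
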