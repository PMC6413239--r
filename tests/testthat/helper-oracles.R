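# Brute-force oracles used to validate the detection stage, plus small
# fixture builders. The oracles deliberately share no code with the
# implementation: flood-fill labeling by explicit queue, selection by
# exhaustive filtering.

# Flood-fill connected-component labeling (queue-based), 4- or 8-adjacency.
oracleLabel <- function(bin, connectivity = 8L) {
  H <- nrow(bin); W <- ncol(bin)
  lab <- matrix(0L, H, W)
  cur <- 0L
  nbr <- if (connectivity == 8L)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  for (r0 in seq_len(H)) for (c0 in seq_len(W)) {
    if (!bin[r0, c0] || lab[r0, c0] > 0L) next
    cur <- cur + 1L
    queue <- matrix(c(r0, c0), ncol = 2)
    lab[r0, c0] <- cur
    while (nrow(queue) > 0) {
      p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(nbr))) {
        rr <- p[1] + nbr[k, 1]; cc <- p[2] + nbr[k, 2]
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W &&
            bin[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- cur
          queue <- rbind(queue, c(rr, cc))
        }
      }
    }
  }
  lab
}

# Exhaustive reference implementation of the whole detection rule:
# threshold at the support level, flood-fill, filter by max-probability and
# area, pick by (max prob, area, topmost-leftmost centroid).
oracleDetect <- function(pmap, cfg) {
  lab <- oracleLabel(pmap >= cfg$supportThreshold, cfg$connectivity)
  n <- max(lab)
  if (n == 0L) return(list(present = FALSE, centroid = NULL))
  best <- NULL
  for (l in seq_len(n)) {
    px <- which(lab == l, arr.ind = TRUE)
    maxp <- max(pmap[lab == l])
    area <- nrow(px)
    if (maxp < cfg$probThreshold || area < cfg$minArea) next
    cand <- list(maxp = maxp, area = area, centroid = colMeans(px))
    if (is.null(best)) best <- cand
    else {
      better <- cand$maxp > best$maxp ||
        (cand$maxp == best$maxp && cand$area > best$area) ||
        (cand$maxp == best$maxp && cand$area == best$area &&
           (cand$centroid[1] < best$centroid[1] ||
              (cand$centroid[1] == best$centroid[1] &&
                 cand$centroid[2] < best$centroid[2])))
      if (better) best <- cand
    }
  }
  if (is.null(best)) list(present = FALSE, centroid = NULL)
  else list(present = TRUE, centroid = unname(best$centroid),
            maxp = best$maxp, area = best$area)
}

# Random blobby probability map: a few rectangular plateaus over noise, so
# regions of varying max-probability and area arise.
randomProbMap <- function(H, W, nBlobs = 3L) {
  p <- matrix(stats::runif(H * W, 0, 0.08), H, W)
  for (i in seq_len(nBlobs)) {
    h <- sample(1:6, 1); w <- sample(1:6, 1)
    r <- sample(seq_len(max(H - h, 1)), 1)
    c <- sample(seq_len(max(W - w, 1)), 1)
    p[r:(r + h - 1), c:(c + w - 1)] <- stats::runif(1, 0.2, 0.98)
  }
  p
}

# A tiny all-white-noise micrograph matrix of a valid size.
tinyImage <- function(n = 32L, seed = 1L) {
  set.seed(seed)
  matrix(stats::runif(n * n), n, n)
}

# A disk mask centered at (cr, cc).
diskMask <- function(n, cr, cc, radius) {
  g <- expand.grid(r = seq_len(n), c = seq_len(n))
  m <- matrix(0, n, n)
  inside <- (g$r - cr)^2 + (g$c - cc)^2 <= radius^2
  m[cbind(g$r[inside], g$c[inside])] <- 1
  m
}
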