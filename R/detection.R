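# Prediction stage: threshold the probability map into candidate connected
# regions, suppress non-maximal regions under two constraints (region max
# probability >= 0.5 and a minimum pixel area), and report the winning
# region's pixel-location mean as the polar-body centre -- or "no polar
# body" when no region survives. Two thresholds are used: a low support
# threshold (0.1) forms the candidate components, and the 0.5 constraint is
# then applied to each region's maximum, so regions peaking below 0.5 exist
# as candidates but are rejected, keeping both constraints meaningful.

#' Non-maximum-suppression configuration
#'
#' @param probThreshold acceptance threshold on a region's maximum
#'   probability (default 0.5).
#' @param supportThreshold threshold at which pixels join candidate
#'   regions; must satisfy 0 < supportThreshold <= probThreshold < 1.
#' @param minArea minimum region area in pixels (default 50, sized so the
#'   smallest plausible polar body at the nominal 16 px / 10 um scale
#'   survives).
#' @param connectivity pixel adjacency for component formation: 4 or 8.
#' @return validated list.
#' @export
nmsConfig <- function(probThreshold = 0.5, supportThreshold = 0.1,
                      minArea = 50L, connectivity = 8L) {
  if (!(supportThreshold > 0 && supportThreshold <= probThreshold &&
        probThreshold < 1))
    stop("need 0 < supportThreshold <= probThreshold < 1", call. = FALSE)
  if (minArea < 1) stop("minArea must be >= 1", call. = FALSE)
  if (!connectivity %in% c(4L, 8L))
    stop("connectivity must be 4 or 8", call. = FALSE)
  list(probThreshold = probThreshold, supportThreshold = supportThreshold,
       minArea = as.integer(minArea), connectivity = as.integer(connectivity))
}

# Connected-component labeling of a logical matrix by union-find over the
# foreground pixels (one pass in column-major order, then root resolution).
labelComponents <- function(bin, connectivity = 8L) {
  H <- nrow(bin); W <- ncol(bin)
  lab <- matrix(0L, H, W)
  fg <- which(bin)
  if (length(fg) == 0) return(lab)
  parent <- integer(length(fg))
  nlab <- 0L
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(fg)) {
    idx <- fg[k]
    r <- ((idx - 1L) %% H) + 1L
    cc <- ((idx - 1L) %/% H) + 1L
    # Neighbours already visited in column-major order.
    nb <- integer(0)
    if (r > 1L && bin[r - 1L, cc]) nb <- c(nb, idx - 1L)
    if (cc > 1L) {
      if (bin[r, cc - 1L]) nb <- c(nb, idx - H)
      if (connectivity == 8L) {
        if (r > 1L && bin[r - 1L, cc - 1L]) nb <- c(nb, idx - H - 1L)
        if (r < H && bin[r + 1L, cc - 1L]) nb <- c(nb, idx - H + 1L)
      }
    }
    if (length(nb) == 0) {
      nlab <- nlab + 1L
      lab[idx] <- nlab
      parent[nlab] <- nlab
    } else {
      roots <- unique(vapply(lab[nb], find, integer(1)))
      keep <- min(roots)
      lab[idx] <- keep
      for (rt in roots[roots != keep]) parent[rt] <- keep
    }
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  remap <- integer(nlab)
  remap[sort(unique(roots))] <- seq_along(unique(roots))
  lab[fg] <- remap[roots[lab[fg]]]
  lab
}

#' Find candidate polar-body regions in a probability map
#'
#' Connected components of the pixels at or above `supportThreshold`, each
#' annotated with its maximum probability, area and centroid.
#'
#' @param pmap a [ProbabilityMap-class] or numeric matrix in \[0, 1\].
#' @param cfg an [nmsConfig()].
#' @return list of regions, each a list with `pixels` (n x 2 matrix of
#'   (row, col)), `area`, `maxProb`, `centroid`.
#' @export
findRegions <- function(pmap, cfg = nmsConfig()) {
  p <- asPixels(pmap)
  lab <- labelComponents(p >= cfg$supportThreshold, cfg$connectivity)
  nl <- max(lab)
  if (nl == 0L) return(list())
  lapply(seq_len(nl), function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    colnames(idx) <- c("row", "col")
    list(pixels = idx, area = nrow(idx),
         maxProb = max(p[lab == l]),
         centroid = unname(colMeans(idx)))
  })
}

#' Suppress non-maximal regions
#'
#' Discards regions whose maximum probability is below `probThreshold` or
#' whose area is below `minArea`; among the survivors returns the region
#' with the highest maximum probability, ties broken by larger area, then
#' by topmost-leftmost centroid. NULL when nothing survives.
#'
#' @param regions list from [findRegions()].
#' @param cfg an [nmsConfig()].
#' @return a single region (list) or NULL.
#' @export
nonmaxSuppress <- function(regions, cfg = nmsConfig()) {
  keep <- Filter(function(r) r$maxProb >= cfg$probThreshold &&
                   r$area >= cfg$minArea, regions)
  if (length(keep) == 0) return(NULL)
  ord <- order(-vapply(keep, `[[`, numeric(1), "maxProb"),
               -vapply(keep, `[[`, numeric(1), "area"),
               vapply(keep, function(r) r$centroid[1], numeric(1)),
               vapply(keep, function(r) r$centroid[2], numeric(1)))
  keep[[ord[1]]]
}

#' Centroid of a region
#'
#' The arithmetic mean of the member pixels' (row, col) coordinates -- the
#' polar-body centre reported to the micromanipulation system.
#'
#' @param region a region from [findRegions()].
#' @return numeric (row, col).
#' @export
regionCentroid <- function(region) {
  if (is.null(region) || nrow(region$pixels) == 0)
    stop("region is empty", call. = FALSE)
  unname(colMeans(region$pixels))
}

#' Decide polar-body presence from a probability map
#'
#' Thresholding, region non-maximum suppression and the centroid rule in
#' one step; useful when the map comes from elsewhere than [predictMap()].
#'
#' @inheritParams findRegions
#' @return a [DetectionResult-class].
#' @export
detectFromMap <- function(pmap, cfg = nmsConfig()) {
  win <- nonmaxSuppress(findRegions(pmap, cfg), cfg)
  if (is.null(win)) return(DetectionResult(FALSE))
  DetectionResult(TRUE, centroid = regionCentroid(win),
                  confidence = win$maxProb, area = win$area)
}

#' Detect the polar body in a micrograph
#'
#' Composition of the trained network's forward pass, candidate-region
#' formation, non-maximum suppression and the centroid rule. A pure
#' function of (weights, image, cfg): repeated calls are identical.
#'
#' @param net a trained [SegmentationNetwork-class].
#' @param img a [Micrograph-class] or numeric matrix.
#' @param cfg an [nmsConfig()].
#' @return a [DetectionResult-class].
#' @export
detectPolarBody <- function(net, img, cfg = nmsConfig()) {
  detectFromMap(predictMap(net, img), cfg)
}
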