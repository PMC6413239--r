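# Raster I/O for micrographs and masks, plus the dataset manifest that pairs
# them. PNG is read/written through the png package and TIFF through the tiff
# package; both return intensities already rescaled to [0, 1] by the format's
# maximum value. RGB inputs are collapsed to Rec. 709 luminance because the
# method is grayscale while cameras may deliver 3 channels.

readRaster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format '", ext, "' for ", path, call. = FALSE)
  )
  if (length(dim(a)) == 3L) {
    if (dim(a)[3] >= 3L) {
      a <- 0.2126 * a[, , 1] + 0.7152 * a[, , 2] + 0.0722 * a[, , 3]
    } else {
      a <- a[, , 1]
    }
  }
  a
}

checkDims <- function(m, path) {
  h <- nrow(m); w <- ncol(m)
  if (h %% 16L != 0L)
    stop("image height ", h, " is not divisible by 16 (", path, ")",
         call. = FALSE)
  if (w %% 16L != 0L)
    stop("image width ", w, " is not divisible by 16 (", path, ")",
         call. = FALSE)
  invisible(m)
}

#' Read a micrograph from a PNG or TIFF file
#'
#' Intensities are rescaled to \[0, 1\] by the format's maximum value
#' (255 for 8-bit, 65535 for 16-bit); RGB images are converted to luminance.
#' Dimensions must be divisible by 16 (four 2x poolings in the encoder).
#'
#' @param path path to an 8- or 16-bit grayscale (or RGB) PNG/TIFF file.
#' @param pixelsPer10um physical scale, pixels per 10 um (default 16).
#' @return a [Micrograph-class].
#' @export
readMicrograph <- function(path, pixelsPer10um = 16) {
  m <- readRaster(path)
  checkDims(m, path)
  Micrograph(pmin(pmax(m, 0), 1), pixelsPer10um = pixelsPer10um)
}

#' Read a binary annotation mask
#'
#' Pixels brighter than half of the format maximum become 1 (polar body),
#' the rest 0 (background), matching the white-on-black mask convention.
#'
#' @param path path to a grayscale PNG/TIFF mask.
#' @return a [LabelMask-class].
#' @export
readLabelMask <- function(path) {
  m <- readRaster(path)
  checkDims(m, path)
  LabelMask((m > 0.5) * 1)
}

#' Write a micrograph as an 8-bit grayscale PNG or TIFF
#'
#' Round-tripping through [readMicrograph()] reproduces the image within the
#' 8-bit quantization bound of 1/255 per pixel.
#'
#' @param m a [Micrograph-class] or numeric matrix in \[0, 1\].
#' @param path destination path; format chosen by extension (.png/.tif/.tiff).
#' @export
writeMicrograph <- function(m, path) {
  m <- asPixels(m)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(m, path),
    tif  = ,
    tiff = tiff::writeTIFF(m, path, bits.per.sample = 8L),
    stop("unsupported raster format '", ext, "'", call. = FALSE)
  )
  invisible(path)
}

#' Write a label mask as an 8-bit PNG (0 = background, 255 = polar body)
#'
#' The encoding is lossless: round-tripping through [readLabelMask()] is
#' exact.
#'
#' @param l a [LabelMask-class] or 0/1 matrix.
#' @param path destination path (.png/.tif/.tiff).
#' @export
writeLabelMask <- function(l, path) {
  writeMicrograph(asPixels(l), path)
}

#' Read a dataset manifest
#'
#' A manifest is a CSV with columns `image`, `mask`, `label` pairing each
#' micrograph with its annotation mask; `label` is "positive" or "negative"
#' and a negative entry's mask may be empty (no file). Relative paths are
#' resolved against the manifest's directory.
#'
#' @param path manifest CSV path.
#' @param check if TRUE (default), verify every referenced file exists.
#' @return data.frame with columns image, mask, label.
#' @export
readManifest <- function(path, check = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image", "mask", "label")
  if (!all(need %in% names(m)))
    stop("manifest must have columns image, mask, label", call. = FALSE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(is.na(p) | p == "", NA_character_,
           ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p)))
  }
  m$image <- resolve(m$image)
  m$mask <- resolve(m$mask)
  if (!all(m$label %in% c("positive", "negative")))
    stop("manifest labels must be 'positive' or 'negative'", call. = FALSE)
  if (check) {
    missing <- c(m$image[!file.exists(m$image)],
                 stats::na.omit(m$mask)[!file.exists(stats::na.omit(m$mask))])
    if (length(missing) > 0)
      stop("manifest references missing files: ",
           paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  m
}

#' Write a dataset manifest
#'
#' @param manifest data.frame with columns image, mask, label.
#' @param path destination CSV path.
#' @param relativeTo optional directory; paths under it are stored relative.
#' @export
writeManifest <- function(manifest, path, relativeTo = NULL) {
  m <- manifest[, c("image", "mask", "label")]
  if (!is.null(relativeTo)) {
    base <- paste0(normalizePath(relativeTo), "/")
    strip <- function(p) {
      full <- ifelse(is.na(p), NA_character_,
                     suppressWarnings(normalizePath(p, mustWork = FALSE)))
      ifelse(!is.na(full) & startsWith(full, base),
             substring(full, nchar(base) + 1L), p)
    }
    m$image <- strip(m$image)
    m$mask <- strip(m$mask)
  }
  m$mask[is.na(m$mask)] <- ""
  utils::write.csv(m, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
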