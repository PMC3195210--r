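# Hue-based segmentation of a single pre-cropped seedling image.
#
# Images are plain integer arrays H x W x 3 with channels 0-255, row-major
# (pixel [i, j] is row i from the top, column j from the left). All
# coordinates are 0-based in the user-facing crop API, half-open intervals.

.checkRgb <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    .gerr("badImage", "image must be an H x W x 3 array")
  if (any(image < 0) || any(image > 255))
    .gerr("badImage", "channel values must lie in [0, 255]")
  invisible(image)
}

## grayscale intensity weights (ITU-R BT.601 luma); rounding is half away
## from zero (values are nonnegative so floor(x + 0.5) implements it).
.GRAY_W <- c(0.2989, 0.5870, 0.1140)

.grayIntensity <- function(image, round. = TRUE) {
  g <- .GRAY_W[1] * image[, , 1] + .GRAY_W[2] * image[, , 2] +
       .GRAY_W[3] * image[, , 3]
  if (round.) matrix(as.integer(floor(g + 0.5)), nrow(g), ncol(g)) else g
}

#' Segmentation configuration
#'
#' Parameters of the hue-window segmentation. Green foliage occupies hue
#' 54-154 degrees on the HSV circle; pixels below the saturation floor are
#' treated as achromatic background noise and zeroed out before
#' thresholding. Connected components smaller than `minRegionPx` are
#' removed to suppress salt noise (set to 0 to keep every component).
#'
#' @param hueLowDeg,hueHighDeg hue window bounds in degrees, 0-360.
#' @param saturationMin minimum HSV saturation (fraction, 0-1) for a pixel
#'   to count as plant.
#' @param minRegionPx smallest connected component (8-connectivity) kept.
#' @param contrastStretch if `TRUE`, apply a global linear min-max stretch
#'   to the image before hue conversion. Cosmetic: hue is invariant to a
#'   common linear scaling of the channels, so this only affects display.
#' @return a named list of class `segmentationConfig`.
#' @export
segmentationConfig <- function(hueLowDeg = 54, hueHighDeg = 154,
                               saturationMin = 0.15, minRegionPx = 25,
                               contrastStretch = FALSE) {
  if (!(hueLowDeg >= 0 && hueLowDeg < hueHighDeg && hueHighDeg <= 360))
    .gerr("badConfig", "need 0 <= hueLowDeg < hueHighDeg <= 360")
  if (saturationMin < 0 || saturationMin > 1)
    .gerr("badConfig", "saturationMin must lie in [0, 1]")
  structure(list(hueLowDeg = hueLowDeg, hueHighDeg = hueHighDeg,
                 saturationMin = saturationMin, minRegionPx = minRegionPx,
                 contrastStretch = contrastStretch),
            class = "segmentationConfig")
}

#' Per-pixel hue and saturation
#'
#' Converts an RGB image to per-pixel HSV hue (degrees, 0-360) and
#' saturation (fraction, 0-1). Achromatic pixels (R = G = B) have
#' saturation 0 and their hue is reported as 0.
#'
#' @param image integer array H x W x 3, channels 0-255.
#' @return list with matrices `hue` (degrees) and `saturation`.
#' @examples
#' hs <- rgbToHueSaturation(array(c(0, 255, 0), c(1, 1, 3)))
#' hs$hue  # 120: primary green
#' @export
rgbToHueSaturation <- function(image) {
  .checkRgb(image)
  d <- dim(image)[1:2]
  hsv <- grDevices::rgb2hsv(r = as.vector(image[, , 1]),
                            g = as.vector(image[, , 2]),
                            b = as.vector(image[, , 3]),
                            maxColorValue = 255)
  list(hue = matrix(hsv[1, ] * 360, d[1], d[2]),
       saturation = matrix(hsv[2, ], d[1], d[2]))
}

## drop 8-connected components smaller than minPx (EBImage works in x,y
## order, hence the transposes)
.removeSmallComponents <- function(mask, minPx) {
  if (minPx <= 1L || !any(mask == 1L)) return(mask)
  lab <- EBImage::bwlabel(EBImage::Image(t(mask)))
  lab <- t(EBImage::imageData(lab))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= minPx)
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[lab %in% keep] <- 1L
  out
}

#' Segment the plant region of a seedling image
#'
#' Implements the hue-window segmentation: low-saturation pixels are zeroed
#' out, the hue image is binarised against the foliage window
#' (`hueLowDeg`-`hueHighDeg`, default 54-154 degrees), small connected
#' components are removed, and the mask is combined with the true-colour
#' image to give the colour-segmented plant region and its grayscale image.
#'
#' @param image integer array H x W x 3, channels 0-255.
#' @param config a [segmentationConfig()].
#' @return a [PlantRegion-class].
#' @examples
#' img <- array(0L, c(8, 8, 3)); img[, , 2] <- 255L
#' region <- segmentPlant(img, segmentationConfig(minRegionPx = 0))
#' regionArea(region)  # 64: the whole uniform-green frame
#' @export
segmentPlant <- function(image, config = segmentationConfig()) {
  .checkRgb(image)
  img <- image
  if (isTRUE(config$contrastStretch)) {
    rng <- range(img)
    if (rng[2] > rng[1])
      img <- (img - rng[1]) / (rng[2] - rng[1]) * 255
  }
  hs <- rgbToHueSaturation(img)
  mask <- matrix(0L, nrow(hs$hue), ncol(hs$hue))
  mask[hs$saturation >= config$saturationMin &
       hs$hue >= config$hueLowDeg & hs$hue <= config$hueHighDeg] <- 1L
  mask <- .removeSmallComponents(mask, config$minRegionPx)
  if (!any(mask == 1L))
    .gerr("emptySegmentation", "no plant pixels found after segmentation")
  colour <- array(0L, dim(image))
  for (ch in 1:3) {
    plane <- matrix(0L, nrow(mask), ncol(mask))
    plane[mask == 1L] <- as.integer(image[, , ch][mask == 1L])
    colour[, , ch] <- plane
  }
  gray <- .grayIntensity(image)
  gray[mask == 0L] <- 0L
  new("PlantRegion", mask = mask, colour = colour, gray = gray)
}

#' Crop a rectangle out of an image
#'
#' 0-based, row-major, half-open: the crop covers rows
#' `top .. top + height - 1` and columns `left .. left + width - 1`.
#'
#' @param image integer array H x W x 3.
#' @param top,left 0-based offsets of the top-left corner.
#' @param height,width extent of the crop in pixels.
#' @return the sub-image as an H x W x 3 array.
#' @export
cropRectangle <- function(image, top, left, height, width) {
  .checkRgb(image)
  d <- dim(image)
  if (top < 0 || left < 0 || height < 1 || width < 1 ||
      top + height > d[1] || left + width > d[2])
    .gerr("outOfBounds", "crop rectangle exceeds image extent")
  image[(top + 1):(top + height), (left + 1):(left + width), , drop = FALSE]
}

#' Ground resolution of a top-view camera set-up
#'
#' From the field of view (mm) and the sensor resolution (pixels): the
#' ground area covered by one pixel and the linear resolution (square root
#' of the area). For a 980 x 720 mm field of view at 3648 x 2736 pixels
#' this gives 0.07 mm^2/pixel and 0.266 mm/pixel.
#'
#' @param fovWidthMm,fovHeightMm field of view in mm.
#' @param imgWidthPx,imgHeightPx image size in pixels.
#' @return list with `areaPerPx` (mm^2/pixel) and `linearRes` (mm/pixel).
#' @export
groundResolution <- function(fovWidthMm, fovHeightMm, imgWidthPx, imgHeightPx) {
  vals <- c(fovWidthMm, fovHeightMm, imgWidthPx, imgHeightPx)
  if (any(!is.finite(vals)) || any(vals <= 0))
    .gerr("invalidGeometry", "all geometry inputs must be positive")
  area <- (fovWidthMm * fovHeightMm) / (imgWidthPx * imgHeightPx)
  list(areaPerPx = area, linearRes = sqrt(area))
}

#' Read / write images
#'
#' `readRgbImage` reads an 8-bit PNG/JPEG/TIFF image into the H x W x 3
#' integer array used throughout; `writeMaskPng` writes a binary mask as a
#' 0/255 grayscale PNG; `writeRegionPng` writes the colour-segmented plant
#' region of a [PlantRegion-class] as PNG.
#'
#' @param path file path.
#' @param image,mask,region the object to write.
#' @return `readRgbImage`: an integer H x W x 3 array.
#' @export
readRgbImage <- function(path) {
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 2L) dat <- array(rep(dat, 3L), c(dim(dat), 3L))
  if (dim(dat)[3] > 3L) dat <- dat[, , 1:3, drop = FALSE]  # drop alpha
  out <- aperm(dat, c(2, 1, 3))  # EBImage is x,y; we are row,col
  array(as.integer(floor(out * 255 + 0.5)), dim(out))
}

#' @rdname readRgbImage
#' @export
writeRgbImage <- function(image, path) {
  .checkRgb(image)
  png::writePNG(image / 255, target = path)
  invisible(path)
}

#' @rdname readRgbImage
#' @export
writeMaskPng <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)),
                target = path)
  invisible(path)
}

#' @rdname readRgbImage
#' @export
writeRegionPng <- function(region, path) {
  stopifnot(is(region, "PlantRegion"))
  writeRgbImage(region@colour, path)
}
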