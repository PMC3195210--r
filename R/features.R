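# The eleven per-plant visual features: normalized colour factors and
# excess-colour indices, erosion-based width W, Waddle Disk Ratio, and the
# histogram texture statistics uniformity and entropy.

#' Names of the plant features, in canonical order
#' @export
featureNames <- function() {
  c("r_i", "g_i", "b_i", "RBI", "ERI", "EGI", "EBI", "W", "WDR", "U_t", "E_t")
}

#' Per-pixel normalized colour factors and colour indices
#'
#' For channel intensities R, G, B (0-255) the grayscale intensity is
#' I = 0.2989 R + 0.5870 G + 0.1140 B (unrounded) and the normalized
#' colour factors are r_i = R/I, g_i = G/I, b_i = B/I. Normalizing by the
#' pixel's own intensity removes a common illumination factor. The derived
#' contrast indices are RBI = (r_i - b_i)/(r_i + b_i) and the excess
#' red/green/blue indices ERI = (r_i - g_i)(r_i - b_i),
#' EGI = (g_i - r_i)(g_i - b_i), EBI = (b_i - g_i)(b_i - r_i).
#'
#' Black pixels (I = 0) have no defined factors and are flagged
#' (`flagZeroIntensity`); pure-green-side pixels with r_i + b_i = 0 have no
#' defined RBI, which is returned as 0 and flagged (`flagRBI`). Flagged
#' pixels are skipped by the per-plant aggregation.
#'
#' @param R,G,B numeric vectors of channel intensities in 0-255 (recycled
#'   to a common length).
#' @return data.frame with columns r_i, g_i, b_i, RBI, ERI, EGI, EBI,
#'   flagZeroIntensity, flagRBI.
#' @examples
#' pixelColourIndices(60, 120, 40)  # RBI = 0.2, EGI ~ 0.556
#' @export
pixelColourIndices <- function(R, G, B) {
  n <- max(length(R), length(G), length(B))
  R <- rep_len(as.numeric(R), n); G <- rep_len(as.numeric(G), n)
  B <- rep_len(as.numeric(B), n)
  I <- .GRAY_W[1] * R + .GRAY_W[2] * G + .GRAY_W[3] * B
  zero <- I == 0
  Isafe <- ifelse(zero, 1, I)
  r <- ifelse(zero, NA_real_, R / Isafe)
  g <- ifelse(zero, NA_real_, G / Isafe)
  b <- ifelse(zero, NA_real_, B / Isafe)
  rbDen <- r + b
  flagRBI <- !zero & rbDen == 0
  RBI <- ifelse(zero | flagRBI, 0, (r - b) / ifelse(rbDen == 0, 1, rbDen))
  data.frame(r_i = r, g_i = g, b_i = b, RBI = RBI,
             ERI = (r - g) * (r - b), EGI = (g - r) * (g - b),
             EBI = (b - g) * (b - r),
             flagZeroIntensity = zero, flagRBI = flagRBI)
}

#' Per-plant colour features of a segmented region
#'
#' Aggregates the per-pixel colour indices over the plant mask as
#' arithmetic means, skipping flagged pixels (black pixels for every
#' feature; RBI-singular pixels for RBI only).
#'
#' @param region a [PlantRegion-class].
#' @return named numeric vector r_i, g_i, b_i, RBI, ERI, EGI, EBI.
#' @export
regionColourFeatures <- function(region) {
  stopifnot(is(region, "PlantRegion"))
  on <- region@mask == 1L
  if (!any(on)) .gerr("emptySegmentation", "region mask is empty")
  px <- pixelColourIndices(region@colour[, , 1][on],
                           region@colour[, , 2][on],
                           region@colour[, , 3][on])
  ok <- !px$flagZeroIntensity
  if (!any(ok)) .gerr("emptySegmentation", "all region pixels are black")
  out <- vapply(c("r_i", "g_i", "b_i", "ERI", "EGI", "EBI"),
                function(f) mean(px[[f]][ok]), numeric(1))
  okRBI <- ok & !px$flagRBI
  rbi <- if (any(okRBI)) mean(px$RBI[okRBI]) else 0
  c(out[c("r_i", "g_i", "b_i")], RBI = rbi, out[c("ERI", "EGI", "EBI")])
}

## one 3x3-square erosion with background outside the image: pad with a
## zero ring so EBImage's out-of-range-as-foreground convention cannot
## protect border pixels.
.erodeOnce <- function(mask) {
  pad <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  pad[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  er <- EBImage::erode(EBImage::Image(t(pad)), EBImage::makeBrush(3, "box"))
  out <- t(EBImage::imageData(er))[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L),
                                   drop = FALSE]
  matrix(as.integer(out), nrow(mask), ncol(mask))
}

#' Erosion-based plant width
#'
#' The plant region is eroded from the border pixels inwards with a 3 x 3
#' square kernel, removing a one-pixel layer per iteration, until the whole
#' region disappears. The width is twice the number of iterations needed —
#' a leaf-width proxy that is robust to leaf curvature and orientation.
#'
#' @param mask integer 0/1 matrix (or a [PlantRegion-class]).
#' @return even integer width W in pixels.
#' @examples
#' bar <- matrix(0L, 20, 50); bar[8:13, 6:45] <- 1L
#' erosionWidth(bar)  # 6: a 6-pixel-wide bar needs 3 erosions
#' @export
erosionWidth <- function(mask) {
  if (is(mask, "PlantRegion")) mask <- mask@mask
  mask <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  if (!any(mask == 1L)) .gerr("emptySegmentation", "mask is empty")
  iters <- 0L
  while (any(mask == 1L)) {
    mask <- .erodeOnce(mask)
    iters <- iters + 1L
  }
  2L * iters
}

#' Waddle Disk Ratio
#'
#' The Waddle disk of a region is the circle with the same pixel area; its
#' diameter is 2 sqrt(A / pi). The Waddle Disk Ratio is the erosion width
#' divided by that diameter — a dimensionless measure of roundness versus
#' linearity of the leaf area (near 1 for a disk, small for a long thin
#' leaf).
#'
#' @param mask integer 0/1 matrix (or a [PlantRegion-class]).
#' @param W erosion width in pixels; computed from `mask` if missing.
#' @return the ratio W / (2 sqrt(A / pi)).
#' @export
waddleDiskRatio <- function(mask, W = NULL) {
  if (is(mask, "PlantRegion")) mask <- mask@mask
  A <- sum(mask != 0)
  if (A == 0) .gerr("emptySegmentation", "mask is empty")
  if (is.null(W)) W <- erosionWidth(mask)
  W / (2 * sqrt(A / pi))
}

#' Histogram texture statistics of the plant region
#'
#' From the histogram of grayscale intensities over the plant mask
#' (L = 256 levels), with p(z) the proportion of region pixels at level z:
#' uniformity U_t = sum p(z)^2 (maximal, 1, when all gray levels are equal)
#' and entropy E_t = -sum p(z) log2 p(z) (maximal, 8 bits, for a flat
#' histogram). Both are surrogates for leaf-surface texture.
#'
#' @param gray integer matrix of grayscale intensities 0-255 (or a
#'   [PlantRegion-class]).
#' @param mask optional 0/1 matrix restricting the histogram; defaults to
#'   `gray != 0` when `gray` is a bare matrix.
#' @return list with `uniformity`, `entropy` (bits) and the length-256
#'   `proportions` vector.
#' @export
textureFeatures <- function(gray, mask = NULL) {
  if (is(gray, "PlantRegion")) {
    mask <- gray@mask
    gray <- gray@gray
  }
  if (is.null(mask)) mask <- gray != 0
  vals <- gray[mask == 1]
  if (!length(vals)) .gerr("emptySegmentation", "no region pixels")
  counts <- tabulate(as.integer(vals) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  nz <- p[p > 0]
  list(uniformity = sum(p^2), entropy = -sum(nz * log2(nz)), proportions = p)
}

#' Extract the full feature vector of a segmented plant
#'
#' Assembles all eleven features from a [PlantRegion-class]: the seven
#' aggregated colour features, the erosion width W, the Waddle Disk Ratio,
#' and the texture statistics U_t and E_t.
#'
#' @param region a [PlantRegion-class].
#' @return named numeric vector in [featureNames()] order.
#' @export
extractFeatures <- function(region) {
  stopifnot(is(region, "PlantRegion"))
  col <- regionColourFeatures(region)
  W <- erosionWidth(region@mask)
  wdr <- waddleDiskRatio(region@mask, W)
  tex <- textureFeatures(region)
  c(col, W = W, WDR = wdr, U_t = tex$uniformity, E_t = tex$entropy)
}

#' Build a per-plant feature table
#'
#' Applies [extractFeatures()] to a list of segmented regions (or
#' [SyntheticPlant-class] objects, which are segmented first) and returns
#' the feature table used by the selection, PCA and discrimination stages.
#'
#' @param regions list of `PlantRegion` or `SyntheticPlant` objects.
#' @param species character vector of labels (taken from the objects when
#'   they are `SyntheticPlant`s).
#' @param ids plant identifiers; defaults to `plant_1 ...`.
#' @param config segmentation configuration used for `SyntheticPlant`
#'   inputs.
#' @return data.frame with columns plant_id, species and the eleven
#'   features.
#' @export
extractFeatureTable <- function(regions, species = NULL, ids = NULL,
                                config = segmentationConfig()) {
  if (is(regions, "PlantRegion") || is(regions, "SyntheticPlant"))
    regions <- list(regions)
  n <- length(regions)
  if (is.null(ids)) ids <- paste0("plant_", seq_len(n))
  if (is.null(species))
    species <- vapply(regions, function(r)
      if (is(r, "SyntheticPlant")) r@species else NA_character_, character(1))
  feats <- t(vapply(regions, function(r) {
    if (is(r, "SyntheticPlant")) r <- segmentPlant(r@image, config)
    extractFeatures(r)
  }, numeric(11)))
  colnames(feats) <- featureNames()
  cbind(data.frame(plant_id = ids, species = species,
                   stringsAsFactors = FALSE),
        as.data.frame(feats))
}

#' Read / write a feature table CSV
#'
#' The CSV carries columns plant_id, species and the eleven features in
#' [featureNames()] order.
#'
#' @param table a feature table data.frame.
#' @param path file path.
#' @return `readFeatureTable`: the data.frame.
#' @export
writeFeatureTable <- function(table, path) {
  ## full 17-significant-digit formatting so a write/read round trip is
  ## lossless and the CSV path reproduces the in-memory path bit for bit
  out <- table
  for (col in names(out))
    if (is.double(out[[col]]))
      out[[col]] <- formatC(out[[col]], digits = 17, format = "g")
  .writeAtomic(path, function(p)
    utils::write.csv(out, p, row.names = FALSE, quote = FALSE))
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(featureNames(), names(tab))
  if (length(miss))
    .gerr("missingFeature", paste("feature table lacks columns:",
                                  paste(miss, collapse = ", ")))
  tab
}

## write via a temp file in the same directory, then rename: outputs are
## atomic even if the process dies mid-write.
.writeAtomic <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}
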