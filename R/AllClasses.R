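#' @import methods
NULL

## condition constructor used throughout: signals a classed error so callers
## (and tests) can catch specific failure modes by class.
.gerr <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(paste0("grassID_", class), "grassID_error")))
}

#' PlantRegion: a segmented seedling
#'
#' Holds the binary plant mask of one segmented seedling together with the
#' masked true-colour pixels and the masked grayscale intensity image.
#' Background pixels (mask 0) are zero in both the colour and gray slots.
#'
#' @slot mask integer matrix of 0/1, plant support.
#' @slot colour integer array H x W x 3, channels 0-255, zero off-mask.
#' @slot gray integer matrix, grayscale intensity 0-255
#'   (0.2989 R + 0.5870 G + 0.1140 B, rounded half away from zero), zero
#'   off-mask.
#'
#' @seealso [segmentPlant()], [extractFeatures()]
#' @export
setClass("PlantRegion",
  representation(mask = "matrix", colour = "array", gray = "matrix"),
  validity = function(object) {
    m <- object@mask
    if (!all(m %in% c(0L, 1L))) return("mask values must be 0 or 1")
    if (!identical(dim(object@colour), c(dim(m), 3L)) &&
        !identical(dim(object@colour), as.integer(c(dim(m), 3L))))
      return("colour array must be H x W x 3 matching mask")
    if (!identical(dim(object@gray), dim(m)))
      return("gray matrix must match mask dimensions")
    off <- m == 0L
    if (any(object@gray[off] != 0)) return("gray must be zero off-mask")
    for (ch in 1:3)
      if (any(object@colour[, , ch][off] != 0))
        return("colour must be zero off-mask")
    TRUE
  })

#' SeedlingPCA: a fitted Varimax-rotated principal component model
#'
#' Principal component analysis of the sample correlation matrix of the
#' selected plant features, with the retained components Varimax-rotated
#' (Kaiser row-normalization) and regression-method component score
#' coefficients. Scores of the fitting set are standardized (mean 0,
#' variance 1 per component).
#'
#' @slot featureNames character, ordered features entering the model.
#' @slot means,sds numeric, per-feature standardization parameters
#'   (sample SD, n-1 denominator).
#' @slot eigenvalues numeric, all eigenvalues of the correlation matrix in
#'   decreasing order (they sum to the number of features).
#' @slot retainedK integer, number of retained components.
#' @slot loadings matrix features x retainedK, Varimax-rotated loadings.
#' @slot rotation matrix retainedK x retainedK, orthogonal rotation applied
#'   to the unrotated loadings.
#' @slot coefficients matrix features x retainedK, component score
#'   coefficients (inverse correlation matrix times rotated loadings).
#' @slot explainedPct numeric, percent of total standardized variance per
#'   (unrotated) component.
#'
#' @seealso [fitSeedlingPCA()], [scoreSamples()]
#' @export
setClass("SeedlingPCA",
  representation(featureNames = "character", means = "numeric",
    sds = "numeric", eigenvalues = "numeric", retainedK = "integer",
    loadings = "matrix", rotation = "matrix", coefficients = "matrix",
    explainedPct = "numeric"),
  validity = function(object) {
    p <- length(object@featureNames)
    k <- object@retainedK
    ev <- object@eigenvalues
    if (length(object@means) != p || length(object@sds) != p)
      return("means/sds length must match featureNames")
    if (length(ev) != p) return("one eigenvalue per feature expected")
    if (is.unsorted(rev(ev))) return("eigenvalues must be decreasing")
    if (any(ev < -1e-8)) return("eigenvalues must be nonnegative")
    if (abs(sum(ev) - p) > 1e-8)
      return("eigenvalues of a correlation matrix must sum to the feature count")
    if (k < 1L || k > p) return("retainedK out of range")
    if (!identical(dim(object@loadings), c(p, as.integer(k))))
      return("loadings must be features x retainedK")
    if (!identical(dim(object@coefficients), c(p, as.integer(k))))
      return("coefficients must be features x retainedK")
    rtr <- crossprod(object@rotation)
    if (max(abs(rtr - diag(k))) > 1e-8) return("rotation must be orthogonal")
    TRUE
  })

#' ThresholdSet: CI-derived pairwise discrimination thresholds
#'
#' One row per species pair: the retained component used to separate the
#' pair, the threshold (midpoint of the gap between the two group
#' confidence intervals), and which species lies on the high side.
#'
#' @slot thresholds data.frame with columns component, speciesHigh,
#'   speciesLow, threshold, boundLow (upper CI bound of the low group) and
#'   boundHigh (lower CI bound of the high group).
#' @slot confidence numeric, the confidence level of the intervals.
#'
#' @seealso [deriveThresholds()], [classifyPairwise()]
#' @export
setClass("ThresholdSet",
  representation(thresholds = "data.frame", confidence = "numeric"),
  validity = function(object) {
    th <- object@thresholds
    need <- c("component", "speciesHigh", "speciesLow", "threshold",
              "boundLow", "boundHigh")
    if (!all(need %in% names(th))) return("missing threshold columns")
    if (nrow(th) && !all(th$threshold > th$boundLow & th$threshold < th$boundHigh))
      return("each threshold must lie strictly between the defining CI bounds")
    TRUE
  })

#' SpeciesParams: generative parameters for synthetic seedlings
#'
#' Parameters of the synthetic seedling image generator. Leaves are drawn
#' as tapered, curved strokes radiating from a common base over a soil
#' coloured background; colour runs as a linear base-to-tip gradient with
#' an additive red boost near the base, an additive blue tint, and
#' multiplicative grayscale speckle.
#'
#' @slot species character label.
#' @slot nLeavesRange integer length-2, inclusive range of leaf count.
#' @slot leafLength,leafWidth,curvature numeric length-2 (mean, sd); length
#'   and width in pixels, curvature in radians per unit arc length.
#' @slot baseRgb,tipRgb numeric length-3 mean colours (0-255) at leaf base
#'   and tip.
#' @slot baseRedBoost additive red shift at the leaf base, decaying tipward.
#' @slot blueTint additive blue channel shift over the whole leaf.
#' @slot textureNoiseSd sd of the multiplicative grayscale speckle
#'   (fraction of intensity).
#' @slot colourJitterSd sd of the per-plant additive colour shift applied
#'   to the base and tip colours (within-species colour variability).
#' @slot backgroundRgb numeric length-3 soil colour.
#'
#' @seealso [speciesPreset()], [drawPlant()]
#' @export
setClass("SpeciesParams",
  representation(species = "character", nLeavesRange = "integer",
    leafLength = "numeric", leafWidth = "numeric", curvature = "numeric",
    baseRgb = "numeric", tipRgb = "numeric", baseRedBoost = "numeric",
    blueTint = "numeric", textureNoiseSd = "numeric",
    colourJitterSd = "numeric", backgroundRgb = "numeric"),
  validity = function(object) {
    if (length(object@nLeavesRange) != 2L ||
        object@nLeavesRange[1] < 1L ||
        object@nLeavesRange[2] < object@nLeavesRange[1])
      return("nLeavesRange must be an increasing positive integer pair")
    if (object@leafWidth[1] < 1) return("mean leaf width must be >= 1 px")
    for (s in list(object@baseRgb, object@tipRgb, object@backgroundRgb))
      if (length(s) != 3L || any(s < 0) || any(s > 255))
        return("colours must be RGB triples in [0,255]")
    if (object@textureNoiseSd < 0) return("textureNoiseSd must be >= 0")
    TRUE
  })

#' SyntheticPlant: one generated seedling image with ground truth
#'
#' @slot image integer array H x W x 3 (0-255) top-view image.
#' @slot truthMask integer 0/1 matrix, the rasterized union of drawn leaves.
#' @slot species character label.
#' @slot seed integer seed the draw was made under.
#' @slot paramsUsed list, realized parameter draw (leaf count, per-leaf
#'   length/width/curvature/angle).
#'
#' @seealso [drawPlant()], [makeDataset()]
#' @export
setClass("SyntheticPlant",
  representation(image = "array", truthMask = "matrix",
    species = "character", seed = "integer", paramsUsed = "list"),
  validity = function(object) {
    if (!identical(dim(object@image)[1:2], dim(object@truthMask)))
      return("truthMask must match image dimensions")
    if (!all(object@truthMask %in% c(0L, 1L)))
      return("truthMask values must be 0 or 1")
    TRUE
  })

setMethod("show", "PlantRegion", function(object) {
  cat(sprintf("PlantRegion: %d x %d px, %d plant pixels (%.1f%%)\n",
    nrow(object@mask), ncol(object@mask), sum(object@mask),
    100 * mean(object@mask)))
})

setMethod("show", "SeedlingPCA", function(object) {
  cat(sprintf("SeedlingPCA: %d features, %d retained components\n",
    length(object@featureNames), object@retainedK))
  cat("  features:", paste(object@featureNames, collapse = ", "), "\n")
  cat(sprintf("  eigenvalues: %s\n",
    paste(sprintf("%.2f", object@eigenvalues), collapse = ", ")))
  cat(sprintf("  variance explained by retained components: %.1f%%\n",
    sum(object@explainedPct[seq_len(object@retainedK)])))
})

setMethod("show", "ThresholdSet", function(object) {
  cat(sprintf("ThresholdSet (%.0f%% CIs), %d pairwise rules:\n",
    100 * object@confidence, nrow(object@thresholds)))
  print(object@thresholds, row.names = FALSE)
})

setMethod("show", "SpeciesParams", function(object) {
  cat(sprintf("SpeciesParams '%s': %d-%d leaves, width %.1f±%.1f px, redBoost %.0f, blueTint %.0f, speckle sd %.2f\n",
    object@species, object@nLeavesRange[1], object@nLeavesRange[2],
    object@leafWidth[1], object@leafWidth[2], object@baseRedBoost,
    object@blueTint, object@textureNoiseSd))
})

setMethod("show", "SyntheticPlant", function(object) {
  cat(sprintf("SyntheticPlant '%s': %d x %d px, %d plant pixels, seed %d\n",
    object@species, dim(object@image)[1], dim(object@image)[2],
    sum(object@truthMask), object@seed))
})

#' Accessors for segmented regions and synthetic plants
#'
#' `plantMask` returns the binary mask of a [PlantRegion] (or the ground
#' truth mask of a [SyntheticPlant]); `grayPixels` the masked grayscale
#' image; `colourPixels` the masked colour array; `regionArea` the plant
#' pixel count.
#'
#' @param x a `PlantRegion` or `SyntheticPlant`.
#' @return `plantMask`/`grayPixels`: an integer matrix; `colourPixels`: an
#'   integer H x W x 3 array; `regionArea`: a count.
#' @export
setGeneric("plantMask", function(x) standardGeneric("plantMask"))
#' @rdname plantMask
#' @export
setGeneric("grayPixels", function(x) standardGeneric("grayPixels"))
#' @rdname plantMask
#' @export
setGeneric("colourPixels", function(x) standardGeneric("colourPixels"))
#' @rdname plantMask
#' @export
setGeneric("regionArea", function(x) standardGeneric("regionArea"))

#' @rdname plantMask
setMethod("plantMask", "PlantRegion", function(x) x@mask)
#' @rdname plantMask
setMethod("plantMask", "SyntheticPlant", function(x) x@truthMask)
#' @rdname plantMask
setMethod("grayPixels", "PlantRegion", function(x) x@gray)
#' @rdname plantMask
setMethod("colourPixels", "PlantRegion", function(x) x@colour)
#' @rdname plantMask
setMethod("colourPixels", "SyntheticPlant", function(x) x@image)
#' @rdname plantMask
setMethod("regionArea", "PlantRegion", function(x) sum(x@mask))
#' @rdname plantMask
setMethod("regionArea", "SyntheticPlant", function(x) sum(x@truthMask))

#' Model accessors
#'
#' Accessors for fitted [SeedlingPCA] models: the number of retained
#' components, the eigenvalue spectrum, rotated loadings and component
#' score coefficients, and the per-component percent of explained variance.
#'
#' @param x a `SeedlingPCA`.
#' @return `nComponents`: integer; `eigenvalues`/`explainedVariance`:
#'   numeric; `rotatedLoadings`/`scoreCoefficients`: features x k matrices.
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))
#' @rdname nComponents
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))
#' @rdname nComponents
#' @export
setGeneric("rotatedLoadings", function(x) standardGeneric("rotatedLoadings"))
#' @rdname nComponents
#' @export
setGeneric("scoreCoefficients", function(x) standardGeneric("scoreCoefficients"))
#' @rdname nComponents
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))

#' @rdname nComponents
setMethod("nComponents", "SeedlingPCA", function(x) x@retainedK)
#' @rdname nComponents
setMethod("eigenvalues", "SeedlingPCA", function(x) x@eigenvalues)
#' @rdname nComponents
setMethod("rotatedLoadings", "SeedlingPCA", function(x) x@loadings)
#' @rdname nComponents
setMethod("scoreCoefficients", "SeedlingPCA", function(x) x@coefficients)
#' @rdname nComponents
setMethod("explainedVariance", "SeedlingPCA", function(x) x@explainedPct)

#' @rdname deriveThresholds
#' @param x a `ThresholdSet`.
#' @export
setGeneric("thresholdTable", function(x) standardGeneric("thresholdTable"))
#' @rdname deriveThresholds
setMethod("thresholdTable", "ThresholdSet", function(x) x@thresholds)
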