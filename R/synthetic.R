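# Synthetic top-view seedling images with ground-truth masks. Leaves are
# quadratically curved, linearly tapered strokes radiating from a common
# base over a soil-coloured background; colour is a base-to-tip gradient
# plus a basal red boost, a blue tint, and multiplicative grayscale
# speckle. Deliberately not botanically accurate: it exists to inject
# known, controllable colour/shape/texture differences.

.hueOf <- function(rgb) {
  h <- grDevices::rgb2hsv(rgb[1], rgb[2], rgb[3], maxColorValue = 255)[1, 1]
  h * 360
}

## pull a jittered foliage colour back inside the hue window: too blue ->
## shed blue, too yellow/red -> shed red
.clampHueWindow <- function(col, lo = 58, hi = 150) {
  while (col[3] > 0 && .hueOf(col) > hi) col[3] <- col[3] - 1
  while (col[1] > 0 && .hueOf(col) < lo) col[1] <- col[1] - 1
  col
}

#' Construct synthetic species parameters
#'
#' See [SpeciesParams-class] for the meaning of each parameter. Foliage
#' colours must keep their hue inside the 54-154 degree segmentation
#' window so the generator's ground truth stays recoverable.
#'
#' @param species label.
#' @param nLeavesRange inclusive integer range of leaf count.
#' @param leafLength,leafWidth,curvature numeric (mean, sd); pixels and
#'   radians per pixel of arc.
#' @param baseRgb,tipRgb,backgroundRgb RGB triples in 0-255.
#' @param baseRedBoost,blueTint additive channel shifts (per-plant means;
#'   each plant draws its own value with a relative sd of 40%).
#' @param textureNoiseSd sd of multiplicative grayscale speckle (per-plant
#'   mean, same 40% relative spread).
#' @param colourJitterSd sd of the per-plant additive shift applied jointly
#'   to base and tip colours, modelling within-species colour variability.
#' @return a [SpeciesParams-class].
#' @export
speciesParams <- function(species, nLeavesRange = c(2L, 4L),
                          leafLength = c(55, 6), leafWidth = c(8, 0.8),
                          curvature = c(0.004, 0.002),
                          baseRgb = c(55, 125, 45), tipRgb = c(70, 140, 55),
                          baseRedBoost = 0, blueTint = 0,
                          textureNoiseSd = 0.05, colourJitterSd = 8,
                          backgroundRgb = c(120, 85, 60)) {
  p <- new("SpeciesParams", species = species,
           nLeavesRange = as.integer(nLeavesRange),
           leafLength = leafLength, leafWidth = leafWidth,
           curvature = curvature, baseRgb = baseRgb, tipRgb = tipRgb,
           baseRedBoost = baseRedBoost, blueTint = blueTint,
           textureNoiseSd = textureNoiseSd,
           colourJitterSd = colourJitterSd, backgroundRgb = backgroundRgb)
  for (col in list(baseRgb, tipRgb)) {
    h <- .hueOf(col)
    if (h < 54 || h > 154)
      .gerr("badParams", sprintf(
        "foliage hue %.0f outside the 54-154 segmentation window", h))
  }
  p
}

#' Species presets of the synthetic generator
#'
#' Three parameter sets encoding the visual contrasts a weed expert uses
#' at the 1-4 leaf stage: wheat has the widest, plainly green, hairless
#' leaves; brome grass has narrower bluish-green leaves with a reddish
#' base and a hairy (high-speckle) surface; ryegrass has the narrowest
#' leaves with the strongest reddish base and a smooth shiny surface.
#'
#' @param species one of "wheat", "brome", "ryegrass".
#' @return a [SpeciesParams-class].
#' @export
speciesPreset <- function(species = c("wheat", "brome", "ryegrass")) {
  species <- match.arg(species)
  switch(species,
    wheat = speciesParams("wheat",
      leafLength = c(55, 6), leafWidth = c(10, 1.0),
      baseRgb = c(55, 125, 45), tipRgb = c(70, 140, 55),
      baseRedBoost = 5, blueTint = 0, textureNoiseSd = 0.04),
    brome = speciesParams("brome",
      leafLength = c(60, 6), leafWidth = c(6, 0.8),
      baseRgb = c(62, 115, 68), tipRgb = c(74, 128, 80),
      baseRedBoost = 25, blueTint = 18, textureNoiseSd = 0.14),
    ryegrass = speciesParams("ryegrass",
      leafLength = c(65, 6), leafWidth = c(3.5, 0.6),
      baseRgb = c(58, 122, 40), tipRgb = c(68, 135, 48),
      baseRedBoost = 45, blueTint = 0, textureNoiseSd = 0.03))
}

#' Draw one synthetic seedling
#'
#' Renders 1-4 leaves as tapered curved strokes from a common base point,
#' applies the colour model (base-to-tip gradient, basal red boost, blue
#' tint, multiplicative grayscale speckle) and records the exact rasterized
#' leaf union as the ground-truth mask. Deterministic under `seed`.
#'
#' @param params a [SpeciesParams-class].
#' @param seed integer seed.
#' @param canvas c(height, width) in pixels.
#' @return a [SyntheticPlant-class].
#' @export
drawPlant <- function(params, seed = 1L, canvas = c(200L, 200L)) {
  stopifnot(is(params, "SpeciesParams"))
  set.seed(seed)
  H <- canvas[1]; W <- canvas[2]
  base <- c(H / 2 + stats::runif(1, -4, 4), W / 2 + stats::runif(1, -4, 4))
  nl <- sample(seq(params@nLeavesRange[1], params@nLeavesRange[2]), 1L)
  ## per-plant realization of the colour model: within-species variability
  jit <- stats::rnorm(3, 0, params@colourJitterSd)
  baseCol <- .clampHueWindow(pmin(255, pmax(0, params@baseRgb + jit)))
  tipCol <- .clampHueWindow(pmin(255, pmax(0, params@tipRgb + jit)))
  ## relative 40% spread: a zero mean parameter stays exactly zero, so the
  ## noise-free limit is really noise-free
  redBoost <- max(0, stats::rnorm(1, params@baseRedBoost,
                                  0.4 * params@baseRedBoost))
  blueTint <- max(0, stats::rnorm(1, params@blueTint,
                                  0.4 * params@blueTint))
  ## keep whole-leaf hue inside the foliage window: strong blue tints would
  ## otherwise push bluish-green leaves past 154 degrees
  while (blueTint > 0 &&
         (.hueOf(pmin(255, baseCol + c(0, 0, blueTint))) > 150 ||
          .hueOf(pmin(255, tipCol + c(0, 0, blueTint))) > 150))
    blueTint <- blueTint - 1
  noiseSd <- max(0, stats::rnorm(1, params@textureNoiseSd,
                                 0.4 * params@textureNoiseSd))
  mask <- matrix(0L, H, W)
  tMap <- matrix(Inf, H, W)  # along-leaf position of each plant pixel
  realized <- list()
  for (leaf in seq_len(nl)) {
    ang <- 2 * pi * (leaf - 1) / nl + stats::runif(1, -0.4, 0.4)
    len <- max(12, min(params@leafLength[1] + 3 * params@leafLength[2],
                       stats::rnorm(1, params@leafLength[1], params@leafLength[2])))
    wid <- max(1.5, stats::rnorm(1, params@leafWidth[1], params@leafWidth[2]))
    cur <- stats::rnorm(1, params@curvature[1], params@curvature[2]) *
           sample(c(-1, 1), 1)
    realized[[leaf]] <- list(angle = ang, length = len, width = wid,
                             curvature = cur)
    nStep <- ceiling(len * 2)
    pos <- base; theta <- ang
    for (s in seq_len(nStep)) {
      tFrac <- s / nStep
      step <- len / nStep
      theta <- theta + cur * step
      pos <- pos + step * c(sin(theta), cos(theta))
      r <- max(0.5, (wid * (1 - tFrac) + 1 * tFrac) / 2)
      if (pos[1] - r < 1 || pos[1] + r > H || pos[2] - r < 1 || pos[2] + r > W)
        .gerr("canvasTooSmall", "leaf stroke exceeds the canvas")
      rows <- max(1L, floor(pos[1] - r)):min(H, ceiling(pos[1] + r))
      cols <- max(1L, floor(pos[2] - r)):min(W, ceiling(pos[2] + r))
      for (i in rows) for (j in cols) {
        if ((i - pos[1])^2 + (j - pos[2])^2 <= r^2) {
          mask[i, j] <- 1L
          if (tFrac < tMap[i, j]) tMap[i, j] <- tFrac
        }
      }
    }
  }
  ## background with mild sensor noise (hue stays in the soil range)
  img <- array(0, c(H, W, 3))
  npx <- H * W
  for (ch in 1:3)
    img[, , ch] <- params@backgroundRgb[ch] + stats::rnorm(npx, 0, 2)
  ## foliage colour model
  on <- mask == 1L
  tv <- tMap[on]
  speckle <- pmax(0.2, 1 + stats::rnorm(sum(on), 0, noiseSd))
  shade <- c(redBoost * exp(-4 * tv), rep(0, sum(on)),
             rep(blueTint, sum(on)))
  dim(shade) <- c(sum(on), 3)
  for (ch in 1:3) {
    plane <- img[, , ch]
    grad <- baseCol[ch] + (tipCol[ch] - baseCol[ch]) * tv
    plane[on] <- (grad + shade[, ch]) * speckle
    img[, , ch] <- plane
  }
  img <- array(as.integer(pmin(255, pmax(0, floor(img + 0.5)))), dim(img))
  new("SyntheticPlant", image = img, truthMask = mask,
      species = params@species, seed = as.integer(seed),
      paramsUsed = list(nLeaves = nl, base = base, colourJitter = jit,
                        baseRedBoost = redBoost, blueTint = blueTint,
                        textureNoiseSd = noiseSd, leaves = realized))
}

#' Generate a labelled synthetic dataset
#'
#' Draws `nPerSpecies` plants for each parameter set (recycled as needed)
#' with per-plant seeds derived deterministically from `seed`, and builds a
#' manifest of realized parameters.
#'
#' @param paramsList list of [SpeciesParams-class] (default: the three
#'   presets).
#' @param nPerSpecies integer, plants per species (recycled); use
#'   `c(118, 122, 46)` for the imbalanced wheat/brome/ryegrass profile of
#'   the original greenhouse study.
#' @param seed integer master seed.
#' @param canvas canvas size passed to [drawPlant()].
#' @return list with `plants` (list of [SyntheticPlant-class]) and
#'   `manifest` (data.frame id, species, seed, nLeaves).
#' @export
makeDataset <- function(paramsList = list(speciesPreset("wheat"),
                                          speciesPreset("brome"),
                                          speciesPreset("ryegrass")),
                        nPerSpecies = 20L, seed = 1L,
                        canvas = c(200L, 200L)) {
  ns <- rep_len(as.integer(nPerSpecies), length(paramsList))
  total <- sum(ns)
  set.seed(seed)
  plantSeeds <- sample.int(.Machine$integer.max - 1L, total)
  plants <- vector("list", total)
  manifest <- vector("list", total)
  idx <- 0L
  for (s in seq_along(paramsList)) {
    for (i in seq_len(ns[s])) {
      idx <- idx + 1L
      p <- drawPlant(paramsList[[s]], seed = plantSeeds[idx], canvas = canvas)
      plants[[idx]] <- p
      manifest[[idx]] <- data.frame(
        id = sprintf("%s_%03d", p@species, i), species = p@species,
        seed = plantSeeds[idx], nLeaves = p@paramsUsed$nLeaves,
        stringsAsFactors = FALSE)
    }
  }
  list(plants = plants, manifest = do.call(rbind, manifest))
}

#' Write a synthetic dataset to disk
#'
#' Writes per-plant image and ground-truth mask PNGs plus the manifest CSV
#' and the parameter sets as JSON.
#'
#' @param dataset result of [makeDataset()].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- dataset$manifest
  man$file <- paste0(man$id, ".png")
  man$maskFile <- paste0(man$id, "_mask.png")
  for (i in seq_along(dataset$plants)) {
    writeRgbImage(dataset$plants[[i]]@image, file.path(dir, man$file[i]))
    writeMaskPng(dataset$plants[[i]]@truthMask, file.path(dir, man$maskFile[i]))
  }
  .writeAtomic(file.path(dir, "manifest.csv"), function(p)
    utils::write.csv(man, p, row.names = FALSE))
  invisible(dir)
}
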