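# Varimax-rotated principal component model on the correlation matrix of
# the selected features, with SPSS-convention regression score
# coefficients so fitted scores are standardized.

#' Standardize feature columns
#'
#' Column-wise z-scores with sample standard deviations (n - 1
#' denominator). PCA on the correlation matrix is PCA of these z-scores.
#'
#' @param table feature table data.frame or numeric matrix.
#' @param features columns to use (defaults to all numeric columns given).
#' @return list with matrix `z` and vectors `means`, `sds`.
#' @export
standardizeFeatures <- function(table, features = NULL) {
  X <- if (is.data.frame(table)) {
    if (is.null(features)) features <- names(table)[vapply(table, is.numeric, TRUE)]
    as.matrix(table[, features, drop = FALSE])
  } else as.matrix(table)
  means <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    .gerr("degenerateColumn", "cannot standardize a zero-variance feature")
  z <- sweep(sweep(X, 2, means), 2, sds, "/")
  list(z = z, means = means, sds = sds)
}

#' Eigen-decomposition of the sample correlation matrix
#'
#' Eigenvalues in decreasing order and unrotated loadings (eigenvectors
#' scaled by the square root of their eigenvalue). Sign convention: the
#' largest-magnitude entry of each loading column is positive.
#'
#' @param z standardized matrix (rows = plants) or a raw matrix/data.frame
#'   (only correlations are used, so standardization does not change the
#'   result).
#' @return list with `eigenvalues`, `loadings` and the correlation matrix
#'   `corr`.
#' @export
fitPca <- function(z) {
  z <- as.matrix(z)
  if (nrow(z) <= ncol(z))
    .gerr("badInput", "need more rows than features")
  R <- stats::cor(z)
  if (any(!is.finite(R))) .gerr("singularInput", "correlation matrix not computable")
  eig <- eigen(R, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  L <- eig$vectors %*% diag(sqrt(vals), length(vals))
  L <- .fixSigns(L)
  dimnames(L) <- list(colnames(R), paste0("PC", seq_len(ncol(L))))
  list(eigenvalues = vals, loadings = L, corr = R)
}

## flip each column so its largest-|.| entry is positive
.fixSigns <- function(L) {
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  L
}

#' Number of components to retain (Kaiser criterion with tolerance)
#'
#' Retains components with eigenvalue >= 1 - `kaiserTolerance`. The
#' tolerance admits components sitting marginally below the Kaiser line,
#' the scree-plot-guided borderline case; with the default 0.05 an
#' eigenvalue printed as 1.00 is retained.
#'
#' @param eigenvalues numeric, decreasing.
#' @param kaiserTolerance slack below 1 still admitted.
#' @return integer count of retained components.
#' @examples
#' retainComponents(c(2.50, 1.51, 1.00, 0.4, 0.3, 0.29))  # 3
#' @export
retainComponents <- function(eigenvalues, kaiserTolerance = 0.05) {
  if (is.unsorted(rev(eigenvalues))) .gerr("badInput", "eigenvalues must be decreasing")
  k <- sum(eigenvalues >= 1 - kaiserTolerance)
  if (k == 0L) .gerr("noComponents", "no component reaches the retention criterion")
  as.integer(k)
}

## varimax criterion (raw, unnormalized): variance of squared loadings
## within each column, summed
.varimaxCriterion <- function(L) {
  sum(apply(L^2, 2, function(x) mean(x^2) - mean(x)^2))
}

#' Varimax rotation of retained loadings
#'
#' Orthogonal Varimax rotation with Kaiser row-normalization (rows scaled
#' to unit communality during rotation, SPSS default), maximizing the
#' dispersion of squared loadings within components. Convention: rotated
#' columns are ordered by decreasing sum of squared loadings and the
#' dominant entry of each column is positive. Communalities are preserved.
#'
#' @param loadings features x k unrotated loadings.
#' @param rowNormalize apply Kaiser row-normalization (default TRUE).
#' @param eps convergence tolerance on the relative criterion gain.
#' @return list with `loadings` (rotated) and the orthogonal `rotation`
#'   such that `loadings == unrotated %*% rotation` (up to the sign/order
#'   convention).
#' @export
varimaxRotate <- function(loadings, rowNormalize = TRUE, eps = 1e-8) {
  L <- as.matrix(loadings)
  k <- ncol(L)
  if (k < 1L) .gerr("badInput", "need at least one component")
  if (k == 1L)
    return(list(loadings = L, rotation = matrix(1, 1, 1)))
  v <- stats::varimax(L, normalize = rowNormalize, eps = eps)
  Lr <- unclass(v$loadings)
  Tm <- v$rotmat
  ## order columns by decreasing explained sum of squares, dominant sign +
  ord <- order(colSums(Lr^2), decreasing = TRUE)
  Lr <- Lr[, ord, drop = FALSE]
  Tm <- Tm[, ord, drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(Lr[, j]))
    if (Lr[i, j] < 0) {
      Lr[, j] <- -Lr[, j]
      Tm[, j] <- -Tm[, j]
    }
  }
  colnames(Lr) <- paste0("PC", seq_len(k))
  list(loadings = Lr, rotation = Tm)
}

#' Component score coefficient matrix (regression method)
#'
#' Coefficients B = R^{-1} L_rot, the SPSS "regression" method: applying B
#' to standardized features yields component scores with mean 0 and
#' variance 1 over the fitting set, uncorrelated across retained
#' components.
#'
#' @param corr feature correlation matrix.
#' @param rotatedLoadings features x k rotated loadings.
#' @return features x k coefficient matrix.
#' @export
scoreCoefficientMatrix <- function(corr, rotatedLoadings) {
  B <- tryCatch(solve(corr, rotatedLoadings),
                error = function(e) .gerr("singularInput",
                  "correlation matrix is singular"))
  dimnames(B) <- dimnames(rotatedLoadings)
  B
}

#' Fit the Varimax-rotated seedling component model
#'
#' Standardizes the selected features, eigen-decomposes their correlation
#' matrix, retains components by the tolerant Kaiser rule, Varimax-rotates
#' the retained loadings and derives regression score coefficients.
#'
#' @param table feature table data.frame.
#' @param features character, the features entering the model; default the
#'   kept set of [selectFeatures()] run on `table` with defaults.
#' @param kaiserTolerance see [retainComponents()].
#' @param rowNormalize see [varimaxRotate()].
#' @return a [SeedlingPCA-class] model.
#' @export
fitSeedlingPCA <- function(table, features = NULL, kaiserTolerance = 0.05,
                           rowNormalize = TRUE) {
  if (is.null(features)) {
    corr <- correlationMatrix(table)
    features <- selectFeatures(corr)$kept
  }
  std <- standardizeFeatures(table, features)
  fit <- fitPca(std$z)
  k <- retainComponents(fit$eigenvalues, kaiserTolerance)
  rot <- varimaxRotate(fit$loadings[, seq_len(k), drop = FALSE],
                       rowNormalize = rowNormalize)
  B <- scoreCoefficientMatrix(fit$corr, rot$loadings)
  new("SeedlingPCA", featureNames = features,
      means = as.numeric(std$means), sds = as.numeric(std$sds),
      eigenvalues = fit$eigenvalues, retainedK = k,
      loadings = rot$loadings, rotation = rot$rotation,
      coefficients = B,
      explainedPct = fit$eigenvalues / length(features) * 100)
}

#' Component scores of plants under a fitted model
#'
#' Standardizes the model features of `table` by the model's means and SDs
#' and multiplies by the component score coefficient matrix.
#'
#' @param model a [SeedlingPCA-class].
#' @param table feature table containing all model features.
#' @return matrix n x k of scores, columns PC1..PCk.
#' @export
scoreSamples <- function(model, table) {
  stopifnot(is(model, "SeedlingPCA"))
  miss <- setdiff(model@featureNames, names(table))
  if (length(miss))
    .gerr("missingFeature", paste("table lacks model features:",
                                  paste(miss, collapse = ", ")))
  X <- as.matrix(table[, model@featureNames, drop = FALSE])
  z <- sweep(sweep(X, 2, model@means), 2, model@sds, "/")
  S <- z %*% model@coefficients
  colnames(S) <- paste0("PC", seq_len(ncol(S)))
  S
}

#' Model (de)serialization
#'
#' A [SeedlingPCA-class] round-trips losslessly through a JSON file.
#'
#' @param model a `SeedlingPCA`.
#' @param path file path.
#' @return `readModel`: the restored `SeedlingPCA`.
#' @export
writeModel <- function(model, path) {
  stopifnot(is(model, "SeedlingPCA"))
  obj <- list(featureNames = model@featureNames, means = model@means,
              sds = model@sds, eigenvalues = model@eigenvalues,
              retainedK = model@retainedK,
              loadings = model@loadings, rotation = model@rotation,
              coefficients = model@coefficients,
              explainedPct = model@explainedPct)
  .writeAtomic(path, function(p)
    jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA,
                         matrix = "rowmajor"))
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  mkmat <- function(m) {
    m <- as.matrix(m)
    dimnames(m) <- list(o$featureNames[seq_len(min(nrow(m), length(o$featureNames)))],
                        paste0("PC", seq_len(ncol(m))))
    m
  }
  rot <- as.matrix(o$rotation)
  dimnames(rot) <- NULL
  new("SeedlingPCA", featureNames = o$featureNames,
      means = as.numeric(o$means), sds = as.numeric(o$sds),
      eigenvalues = as.numeric(o$eigenvalues),
      retainedK = as.integer(o$retainedK),
      loadings = mkmat(o$loadings), rotation = rot,
      coefficients = mkmat(o$coefficients),
      explainedPct = as.numeric(o$explainedPct))
}

#' Reference greenhouse calibration
#'
#' `referenceScoreCoefficients` returns the component score coefficient
#' matrix of the original greenhouse calibration of this method (229
#' wheat/brome/ryegrass training images; features r_i, RBI, EBI, W, WDR,
#' U_t; three retained components). Applied to a standardized feature row
#' it yields the calibrated component scores without refitting.
#' `referenceCorrelations` returns the corresponding eleven-feature
#' correlation matrix (reported to one decimal), and `referenceEigenvalues`
#' the retained eigenvalue spectrum of that calibration.
#'
#' @return a matrix (coefficients, correlations) or numeric vector
#'   (eigenvalues).
#' @export
referenceScoreCoefficients <- function() {
  m <- matrix(c(
     0.482,  0.127, -0.081,
     0.251, -0.515, -0.022,
     0.183,  0.602, -0.018,
    -0.470,  0.055,  0.114,
    -0.088, -0.020,  0.574,
    -0.180,  0.011,  0.651), nrow = 6, byrow = TRUE,
    dimnames = list(c("r_i", "RBI", "EBI", "W", "WDR", "U_t"),
                    c("PC1", "PC2", "PC3")))
  m
}

#' @rdname referenceScoreCoefficients
#' @export
referenceEigenvalues <- function() {
  c(PC1 = 2.50, PC2 = 1.51, PC3 = 1.00)
}

#' @rdname referenceScoreCoefficients
#' @export
referenceCorrelations <- function() {
  f <- featureNames()
  lower <- c(
     1.0,  NA,   NA,   NA,   NA,   NA,   NA,   NA,  NA,  NA,  NA,
    -0.7,  1.0,  NA,   NA,   NA,   NA,   NA,   NA,  NA,  NA,  NA,
    -0.3, -0.5,  1.0,  NA,   NA,   NA,   NA,   NA,  NA,  NA,  NA,
     0.4, -0.9,  0.6,  1.0,  NA,   NA,   NA,   NA,  NA,  NA,  NA,
    -0.7,  1.0, -0.4, -0.9,  1.0,  NA,   NA,   NA,  NA,  NA,  NA,
     0.4,  0.4, -1.0, -0.5,  0.3,  1.0,  NA,   NA,  NA,  NA,  NA,
     0.5,  0.3, -1.0, -0.5,  0.2,  1.0,  1.0,  NA,  NA,  NA,  NA,
    -0.6,  0.6,  0.0, -0.4,  0.6, -0.1, -0.2,  1.0, NA,  NA,  NA,
     0.4, -0.3, -0.1,  0.3, -0.3,  0.2,  0.2, -0.3, 1.0, NA,  NA,
     0.3, -0.2, -0.1,  0.2, -0.2,  0.1,  0.1, -0.2, 0.5, 1.0, NA,
    -0.4,  0.2,  0.2, -0.2,  0.3, -0.2, -0.2,  0.3, -0.5, -0.9, 1.0)
  m <- matrix(lower, nrow = 11, byrow = TRUE, dimnames = list(f, f))
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  m
}
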