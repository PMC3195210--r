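# Correlation-based redundancy filter: of any group of highly correlated
# features only one representative enters the PCA.

#' Pearson correlation matrix of a feature table
#'
#' @param table feature table data.frame (as from [extractFeatureTable()]).
#' @param features character, columns to correlate; defaults to the eleven
#'   plant features present in the table.
#' @return symmetric correlation matrix with feature names as dimnames.
#' @export
correlationMatrix <- function(table, features = NULL) {
  if (is.null(features)) features <- intersect(featureNames(), names(table))
  miss <- setdiff(features, names(table))
  if (length(miss))
    .gerr("missingFeature", paste("missing columns:", paste(miss, collapse = ", ")))
  X <- as.matrix(table[, features, drop = FALSE])
  if (nrow(X) < 3L) .gerr("badInput", "need at least 3 rows")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    .gerr("degenerateColumn",
          paste("zero-variance feature(s):",
                paste(features[sds == 0], collapse = ", ")))
  stats::cor(X)
}

#' Default feature priority for redundancy filtering
#'
#' The greedy filter keeps the first feature of each correlated group in
#' priority order. The default promotes the six features retained for the
#' component model (r_i, RBI, EBI, W, WDR, U_t) ahead of the rest in
#' canonical order, so the representative chosen from each high-correlation
#' group is reproducible.
#' @return character vector over all eleven features.
#' @export
defaultPriority <- function() {
  promoted <- c("r_i", "RBI", "EBI", "W", "WDR", "U_t")
  c(promoted, setdiff(featureNames(), promoted))
}

#' Select a low-correlation feature subset
#'
#' Greedy scan in priority order: a feature is kept iff its absolute
#' Pearson correlation with every already-kept feature is below the
#' threshold; otherwise it is absorbed into the first kept feature it is
#' highly correlated with. With the default priority and threshold 0.7 the
#' survivors of the eleven plant features are r_i, RBI, EBI, W, WDR, U_t.
#'
#' @param corr correlation matrix with dimnames (see [correlationMatrix()]).
#' @param threshold absolute-correlation cutoff; |r| >= threshold counts as
#'   redundant.
#' @param priority ordered character vector covering all features of
#'   `corr`.
#' @return list with `kept` (ordered names), `dropped` (data.frame feature
#'   / absorbedInto), `threshold`.
#' @export
selectFeatures <- function(corr, threshold = 0.7, priority = defaultPriority()) {
  feats <- colnames(corr)
  if (is.null(feats)) .gerr("badInput", "correlation matrix needs dimnames")
  priority <- intersect(priority, feats)
  if (!setequal(priority, feats))
    .gerr("badInput", "priority must cover all features in the matrix")
  kept <- character(0)
  dropped <- data.frame(feature = character(0), absorbedInto = character(0),
                        stringsAsFactors = FALSE)
  for (f in priority) {
    high <- kept[abs(corr[f, kept]) >= threshold]
    if (length(high) == 0L) {
      kept <- c(kept, f)
    } else {
      dropped <- rbind(dropped, data.frame(feature = f,
                                           absorbedInto = high[1],
                                           stringsAsFactors = FALSE))
    }
  }
  list(kept = kept, dropped = dropped, threshold = threshold)
}

#' Write selection artifacts
#'
#' The correlation matrix goes to CSV (features as row/column labels), the
#' selection result to JSON.
#' @param corr correlation matrix.
#' @param selection result of [selectFeatures()].
#' @param path output file.
#' @export
writeCorrelationMatrix <- function(corr, path) {
  .writeAtomic(path, function(p)
    utils::write.csv(as.data.frame(corr), p, row.names = TRUE))
}

#' @rdname writeCorrelationMatrix
#' @export
writeSelection <- function(selection, path) {
  .writeAtomic(path, function(p)
    jsonlite::write_json(selection, p, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows"))
}
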