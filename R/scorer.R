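## Random-forest window scorer behind a deterministic surface.

.LABEL_LEVELS <- c("insufficient", "sufficient")

#' Train the window scorer
#'
#' Fits a probability random forest (ranger backend, single thread, fixed
#' seed) on window feature rows; scores are the predicted probability of the
#' positive ("sufficient") class, in \[0, 1\], and are deterministic given the
#' seed.  Missing feature values are imputed with the per-feature training
#' medians, which are stored in the model and re-applied at scoring time.
#' Default hyperparameters: 100 trees, depth cap 10, minimum node size 10,
#' mtry = floor(sqrt(p)).
#'
#' @param x windows-by-features numeric matrix (canonical columns).
#' @param labels character/factor with both classes present
#'   ("sufficient" / "insufficient").
#' @param seed integer.
#' @param numTrees,maxDepth,minNodeSize,mtry forest hyperparameters.
#' @return A [ScorerModel-class].
#' @export
trainScorer <- function(x, labels, seed = 1L, numTrees = 100L,
                        maxDepth = 10L, minNodeSize = 10L,
                        mtry = NULL) {
  labels <- factor(as.character(labels), levels = .LABEL_LEVELS)
  if (any(is.na(labels)))
    stop("labels must be 'sufficient' or 'insufficient'")
  if (length(unique(labels)) < 2L)
    stop("training set must contain both classes")
  if (nrow(x) != length(labels)) stop("x and labels must align")
  med <- apply(x, 2, median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  xi <- .imputeWith(x, med)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  fit <- ranger::ranger(
    x = as.data.frame(xi), y = labels,
    num.trees = numTrees, mtry = mtry, min.node.size = minNodeSize,
    max.depth = maxDepth, probability = TRUE,
    num.threads = 1L, seed = seed, verbose = FALSE)
  new("ScorerModel", forest = fit, featureNames = colnames(x),
      imputeMedians = med, numTrees = as.integer(numTrees),
      maxDepth = as.integer(maxDepth), minNodeSize = as.integer(minNodeSize),
      mtry = as.integer(mtry), seed = as.integer(seed))
}

.imputeWith <- function(x, med) {
  bad <- which(is.na(x) | !is.finite(x), arr.ind = TRUE)
  if (nrow(bad)) x[bad] <- med[bad[, 2]]
  x
}

#' Score windows with a fitted scorer
#'
#' @param model a [ScorerModel-class].
#' @param x windows-by-features matrix with the model's feature columns.
#' @return Numeric scores in \[0, 1\] (probability of "sufficient").
#' @export
scoreWindows <- function(model, x) {
  if (!identical(colnames(x), model@featureNames))
    stop("feature columns do not match the fitted scorer")
  xi <- .imputeWith(x, model@imputeMedians)
  p <- predict(model@forest, data = as.data.frame(xi),
               num.threads = 1L, verbose = FALSE)$predictions
  unname(p[, "sufficient"])
}

setMethod("show", "ScorerModel", function(object) {
  cat("ScorerModel: probability forest,", object@numTrees, "trees, depth <=",
      object@maxDepth, ", seed", object@seed, "\n")
})
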