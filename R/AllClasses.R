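#' @title Gene-by-covariate feature matrix
#'
#' @description
#' `FeatureMatrix` holds the gene x 12 multi-omics covariate matrix together
#' with the mask of originally-missing cells and a processing-state flag.
#' The twelve columns, in fixed order, are: expression level, DNA replication
#' timing, chromatin compartment (HiC), gene length, missense constraint,
#' expression-network hubness, regulatory role, copy-number alteration,
#' methylation, total mutation count, deleterious mutation count, and the
#' standard deviation of per-patient FIS. The last three are computed from
#' the cohort MAF; the first nine come from a static covariate table.
#'
#' State moves `raw` -> `imputed` (`imputeMissing()`) -> `normalized`
#' (`normalizeFeatures()`). A normalized matrix has column mean 0 and sample
#' standard deviation 1, and carries the centers/scales used so values can be
#' mapped back to the original units.
#'
#' @slot values numeric matrix, genes in rows (rownames = gene symbols),
#'   covariates in columns.
#' @slot missingMask logical matrix, TRUE where the cell was missing on input.
#' @slot state one of "raw", "imputed", "normalized".
#' @slot centers,scales per-column centering/scaling constants (NA until
#'   normalized).
#'
#' @aliases FeatureMatrix-class
#' @export FeatureMatrix
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
  representation(values = "matrix", missingMask = "matrix",
                 state = "character", centers = "numeric",
                 scales = "numeric"))

FEATURE_COLUMNS <- c("expression", "replication_timing", "hic", "gene_length",
                     "constraint", "hubness", "regulatory_role", "cna",
                     "methylation", "total_mutations", "deleterious_mutations",
                     "fis_sd")
STATIC_COLUMNS <- FEATURE_COLUMNS[1:9]

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (!identical(dim(v), dim(object@missingMask)))
    msg <- c(msg, "values and missingMask dimensions differ")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    msg <- c(msg, "values must have unique gene rownames")
  if (length(object@state) != 1L ||
      !object@state %in% c("raw", "imputed", "normalized"))
    msg <- c(msg, "state must be one of raw/imputed/normalized")
  if (object@state %in% c("imputed", "normalized") && anyNA(v))
    msg <- c(msg, "imputed/normalized matrix must have no missing entries")
  if (identical(object@state, "normalized") && nrow(v) > 1L) {
    if (max(abs(colMeans(v))) > 1e-9 ||
        max(abs(apply(v, 2L, sd) - 1)) > 1e-9)
      msg <- c(msg, "normalized columns must have mean 0 and sample sd 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureMatrix
#'
#' @param values numeric matrix with gene rownames; NA marks missing cells.
#' @param state processing state; new matrices are "raw".
#' @return a [FeatureMatrix-class] object.
#' @export
FeatureMatrix <- function(values, state = "raw") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("FeatureMatrix", values = values, missingMask = is.na(values),
      state = state,
      centers = rep(NA_real_, ncol(values)),
      scales = rep(NA_real_, ncol(values)))
}

#' @describeIn FeatureMatrix the numeric covariate matrix.
#' @param x a `FeatureMatrix`.
#' @export
featureValues <- function(x) x@values

#' @describeIn FeatureMatrix logical mask of originally-missing cells.
#' @export
missingMask <- function(x) x@missingMask

#' @describeIn FeatureMatrix processing state ("raw"/"imputed"/"normalized").
#' @export
featureState <- function(x) x@state

#' @describeIn FeatureMatrix gene symbols (rownames).
#' @export
geneNames <- function(x) rownames(x@values)

#' @describeIn FeatureMatrix per-column centers and scales applied by
#'   [normalizeFeatures()] (list with elements `centers`, `scales`).
#' @export
normalizationStats <- function(x) list(centers = x@centers, scales = x@scales)

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d genes x %d covariates [%s]\n",
              nrow(object@values), ncol(object@values), object@state))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", sum(object@missingMask),
              100 * mean(object@missingMask)))
})

#' @title Single-hidden-layer FIS regression network
#'
#' @description
#' A feed-forward network with one ReLU hidden layer (default 100 units) and,
#' by default, a linear output unit, mapping the 12 normalized covariates to
#' a gene's expected (background) FIS. Weights are trained by
#' backpropagation (Adam) on mean squared error; the response is standardized
#' internally and predictions are returned on the original FIS scale.
#'
#' @slot W2 hidden-layer weights (hiddenUnits x p).
#' @slot b2 hidden-layer biases.
#' @slot W3 output weights (1 x hiddenUnits).
#' @slot b3 output bias (length 1).
#' @slot epochs,seed training configuration actually used.
#' @slot lossTrace per-epoch full-data MSE on the standardized response
#'   (length = epochs).
#' @slot outputActivation "linear" (default) or "relu".
#' @slot targetCenter,targetScale response standardization constants.
#' @slot featureNames covariate order expected by [predictFIS()].
#'
#' @aliases FISModel-class
#' @exportClass FISModel
setClass("FISModel",
  representation(W2 = "matrix", b2 = "numeric", W3 = "matrix", b3 = "numeric",
                 epochs = "integer", seed = "integer", lossTrace = "numeric",
                 outputActivation = "character", targetCenter = "numeric",
                 targetScale = "numeric", featureNames = "character"))

setValidity("FISModel", function(object) {
  msg <- character()
  h <- nrow(object@W2)
  if (length(object@b2) != h) msg <- c(msg, "b2 length must match hidden units")
  if (!identical(dim(object@W3), c(1L, h)))
    msg <- c(msg, "W3 must be 1 x hiddenUnits")
  if (length(object@b3) != 1L) msg <- c(msg, "b3 must be scalar")
  if (length(object@lossTrace) != object@epochs)
    msg <- c(msg, "lossTrace length must equal epochs")
  if (!object@outputActivation %in% c("linear", "relu"))
    msg <- c(msg, "outputActivation must be 'linear' or 'relu'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FISModel", function(object) {
  cat(sprintf(
    "FISModel: %d -> %d ReLU -> 1 (%s output), %d epochs, seed %d\n",
    ncol(object@W2), nrow(object@W2), object@outputActivation,
    object@epochs, object@seed))
  cat(sprintf("  final training MSE (standardized): %.4g\n",
              object@lossTrace[length(object@lossTrace)]))
})

#' @describeIn FISModel per-epoch training loss (MSE on the standardized
#'   response).
#' @param x a `FISModel`.
#' @export
lossTrace <- function(x) x@lossTrace

#' @describeIn FISModel raw weight arrays as a list (W2, b2, W3, b3).
#' @export
modelWeights <- function(x) list(W2 = x@W2, b2 = x@b2, W3 = x@W3, b3 = x@b3)

#' @title Clustered gamma background model
#'
#' @description
#' The background ("null") distribution of gene FIS: a Ward clustering of
#' genes in normalized covariate space plus, per cluster, a gamma distribution
#' fitted by maximum likelihood to the 5%-truncated estimated FISs (shifted
#' into the positive domain when necessary). `beta` follows the rate
#' convention: density proportional to beta^alpha x^(alpha-1) exp(-beta x).
#'
#' @slot assignment named integer vector, gene -> cluster id in 1..nClusters.
#' @slot nClusters number of flat clusters (ceiling(G / genesPerCluster)).
#' @slot genesPerCluster expected genes per cluster (N; default 3000).
#' @slot truncation fraction of smallest estimated FISs dropped per cluster.
#' @slot fits data.frame with one row per cluster: `cluster`, `alpha`, `beta`,
#'   `shift`, `n_used`, `usable` (FALSE when the gamma could not be fitted;
#'   such clusters yield NA p-values downstream).
#'
#' @aliases GammaBackground-class
#' @exportClass GammaBackground
setClass("GammaBackground",
  representation(assignment = "integer", nClusters = "integer",
                 genesPerCluster = "numeric", truncation = "numeric",
                 fits = "data.frame"))

setValidity("GammaBackground", function(object) {
  msg <- character()
  if (is.null(names(object@assignment)))
    msg <- c(msg, "assignment must be named by gene")
  if (length(object@assignment) &&
      !all(object@assignment %in% seq_len(object@nClusters)))
    msg <- c(msg, "cluster ids must lie in 1..nClusters")
  need <- c("cluster", "alpha", "beta", "shift", "n_used", "usable")
  if (!all(need %in% names(object@fits)))
    msg <- c(msg, "fits must have cluster/alpha/beta/shift/n_used/usable")
  ok <- object@fits$usable
  if (any(ok) && (any(object@fits$alpha[ok] <= 0) ||
                  any(object@fits$beta[ok] <= 0)))
    msg <- c(msg, "usable fits must have positive alpha and beta")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GammaBackground", function(object) {
  cat(sprintf("GammaBackground: %d genes in %d cluster(s) (N = %g, %g%% truncation)\n",
              length(object@assignment), object@nClusters,
              object@genesPerCluster, 100 * object@truncation))
  print(object@fits, row.names = FALSE)
})

#' @describeIn GammaBackground named integer vector gene -> cluster id.
#' @param x a `GammaBackground`.
#' @export
clusterAssignments <- function(x) x@assignment

#' @describeIn GammaBackground per-cluster gamma fit table.
#' @export
gammaFits <- function(x) x@fits
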