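## Ward clustering in covariate space + per-cluster truncated gamma null.

#' Cluster genes in normalized covariate space
#'
#' Agglomerative hierarchical clustering with the Ward minimum-variance
#' criterion on Euclidean distances (the squared-distance formulation, i.e.
#' `hclust(method = "ward.D2")`), cut into exactly
#' `ceiling(G / genesPerCluster)` flat clusters. With a single resulting
#' cluster the dendrogram is skipped and all genes get cluster 1. The
#' assignment is deterministic given the input order.
#'
#' @param features normalized [FeatureMatrix-class] (G >= 2 genes).
#' @param genesPerCluster expected genes per cluster N (default 3000).
#' @return named integer vector gene -> cluster id, with attribute
#'   `nClusters`.
#' @export
clusterGenes <- function(features, genesPerCluster = 3000) {
  stopifnot(is(features, "FeatureMatrix"))
  X <- features@values
  G <- nrow(X)
  if (G < 2L) stopf("clustering requires at least 2 genes")
  nc <- as.integer(ceiling(G / genesPerCluster))
  if (nc <= 1L) {
    assignment <- stats::setNames(rep(1L, G), rownames(X))
  } else {
    hc <- hclust(dist(X), method = "ward.D2")
    assignment <- stats::setNames(as.integer(cutree(hc, k = nc)), rownames(X))
  }
  attr(assignment, "nClusters") <- nc
  assignment
}

#' Truncate and shift estimated FISs within clusters
#'
#' Per cluster, the `floor(truncation * n)` smallest estimated FISs are
#' dropped (gamma is positively skewed; low outliers distort the fit). If
#' any remaining value is non-positive, all remaining values are shifted by
#' `-min + 0.01` so the minimum becomes exactly 0.01; the shift is recorded.
#' Clusters left with fewer than 20 values raise a warning; fewer than 3
#' makes the cluster unusable (gamma unfittable) — its genes receive NA
#' p-values downstream.
#'
#' @param estimated named numeric vector of estimated FIS (all genes).
#' @param clusters named integer vector from [clusterGenes()].
#' @param truncation fraction dropped from the low end (default 0.05).
#' @return list with one element per cluster id: `values` (post-truncation,
#'   post-shift), `shift`, `nUsed`, `usable`.
#' @export
truncateAndShift <- function(estimated, clusters, truncation = 0.05) {
  stopifnot(all(names(clusters) %in% names(estimated)))
  ids <- sort(unique(clusters))
  out <- vector("list", length(ids))
  names(out) <- as.character(ids)
  for (cid in ids) {
    v <- unname(estimated[names(clusters)[clusters == cid]])
    drop <- floor(truncation * length(v))
    if (drop > 0L) v <- v[order(v)][-seq_len(drop)]
    shift <- 0
    if (length(v) && min(v) <= 0) shift <- -min(v) + 0.01
    v <- v + shift
    usable <- length(v) >= 3L
    if (!usable)
      warnf("cluster %d: only %d value(s) after truncation; gamma unfittable, genes get NA p-values",
            cid, length(v))
    else if (length(v) < 20L)
      warnf("cluster %d: only %d values after truncation", cid, length(v))
    out[[as.character(cid)]] <- list(values = v, shift = shift,
                                     nUsed = length(v), usable = usable)
  }
  out
}

#' Maximum-likelihood gamma fit (shape/rate)
#'
#' Fits a gamma distribution with density proportional to
#' `beta^alpha x^(alpha-1) exp(-beta x)` (`beta` is the rate) by maximum
#' likelihood: Newton iteration on the profile shape equation
#' `log(alpha) - digamma(alpha) = log(mean(x)) - mean(log(x))` starting from
#' the method-of-moments estimate, then `beta = alpha / mean(x)`.
#'
#' @param values positive numeric vector, length >= 3, non-degenerate.
#' @param tol convergence tolerance on the shape equation (default 1e-8).
#' @param maxit Newton iteration cap (default 200).
#' @return list: `alpha`, `beta`, `logLik`, `iterations`, `converged`.
#' @export
fitGamma <- function(values, tol = 1e-8, maxit = 200L) {
  x <- as.numeric(values)
  if (length(x) < 3L) stopf("gamma fit requires at least 3 values")
  if (any(!is.finite(x)) || any(x <= 0))
    stopf("gamma fit requires finite, strictly positive values")
  if (var(x) == 0) stopf("gamma fit is degenerate: all values equal")
  mx <- mean(x)
  s <- log(mx) - mean(log(x))  # > 0 by Jensen unless degenerate
  if (s <= 0) stopf("gamma fit is degenerate: zero log-spread")
  alpha <- mx^2 / var(x)       # method-of-moments start
  it <- 0L
  repeat {
    it <- it + 1L
    g <- log(alpha) - digamma(alpha) - s
    gp <- 1 / alpha - trigamma(alpha)
    stepSize <- g / gp
    alphaNew <- alpha - stepSize
    if (!is.finite(alphaNew) || alphaNew <= 0) alphaNew <- alpha / 2
    done <- abs(log(alphaNew) - digamma(alphaNew) - s) < tol
    alpha <- alphaNew
    if (done) break
    if (it >= maxit)
      stopf("gamma MLE did not converge in %d iterations (alpha = %g, residual = %g)",
            maxit, alpha, abs(log(alpha) - digamma(alpha) - s))
  }
  beta <- alpha / mx
  list(alpha = alpha, beta = beta,
       logLik = sum(dgamma(x, shape = alpha, rate = beta, log = TRUE)),
       iterations = it, converged = TRUE)
}

#' Estimate the clustered gamma background
#'
#' Convenience wrapper: [truncateAndShift()] then [fitGamma()] per cluster,
#' collected into a [GammaBackground-class]. Unfittable clusters are kept
#' with `usable = FALSE` and NA parameters.
#'
#' @param estimated named numeric vector of estimated FIS.
#' @param clusters named integer vector from [clusterGenes()].
#' @param genesPerCluster the N used to form `clusters` (bookkeeping only).
#' @param truncation low-end truncation fraction (default 0.05).
#' @return a [GammaBackground-class].
#' @export
estimateBackground <- function(estimated, clusters, genesPerCluster = 3000,
                               truncation = 0.05) {
  pieces <- truncateAndShift(estimated, clusters, truncation)
  ids <- as.integer(names(pieces))
  fits <- data.frame(cluster = ids, alpha = NA_real_, beta = NA_real_,
                     shift = NA_real_, n_used = NA_integer_, usable = FALSE)
  for (i in seq_along(pieces)) {
    pc <- pieces[[i]]
    fits$shift[i] <- pc$shift
    fits$n_used[i] <- pc$nUsed
    if (!pc$usable) next
    fit <- tryCatch(fitGamma(pc$values), error = function(e) NULL)
    if (is.null(fit)) {
      warnf("cluster %d: gamma fit failed; genes get NA p-values", ids[i])
      next
    }
    fits$alpha[i] <- fit$alpha
    fits$beta[i] <- fit$beta
    fits$usable[i] <- TRUE
  }
  nc <- attr(clusters, "nClusters")
  if (is.null(nc)) nc <- max(clusters)
  new("GammaBackground",
      assignment = stats::setNames(as.integer(clusters), names(clusters)),
      nClusters = as.integer(nc),
      genesPerCluster = as.numeric(genesPerCluster),
      truncation = truncation, fits = fits)
}
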