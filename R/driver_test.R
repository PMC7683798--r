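## Gamma upper-tail p-values, BH correction, driver calls.

#' Upper-tail gamma p-value for an observed FIS
#'
#' `p = 1 - GammaCDF(observed; alpha, rate beta)`; an observed FIS of zero or
#' below is outside the gamma domain and gets `p = 1` (a significantly LOW
#' score is never evidence for driving). Vectorized over `observed`.
#'
#' @param observed numeric vector of observed FIS.
#' @param alpha,beta gamma shape and rate; NA parameters propagate NA.
#' @return numeric vector of p-values in [0, 1].
#' @export
genePValue <- function(observed, alpha, beta) {
  p <- rep(NA_real_, length(observed))
  if (length(alpha) == 1L) alpha <- rep(alpha, length(observed))
  if (length(beta) == 1L) beta <- rep(beta, length(observed))
  ok <- is.finite(alpha) & is.finite(beta)
  p[ok] <- pgamma(observed[ok], shape = alpha[ok], rate = beta[ok],
                  lower.tail = FALSE)
  p[ok & observed <= 0] <- 1
  p
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH adjustment (`stats::p.adjust(method = "BH")`): on sorted
#' p-values, `q_(i) = min_(j>=i) m p_(j) / j`, clipped at 1 and mapped back
#' to input order. NA p-values pass through as NA and are excluded from `m`;
#' p-values outside [0, 1] are a fatal error.
#'
#' @param pvalues numeric vector of p-values (NA allowed).
#' @return numeric vector of q-values in the input order.
#' @export
bhQValues <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stopf("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Call driver genes against the clustered gamma background
#'
#' Computes each tested gene's upper-tail gamma p-value against its
#' cluster's fit, applies Benjamini-Hochberg within each cluster
#' independently (default) or over all genes pooled, and flags genes with
#' q <= `alphaFdr` as drivers; the union over clusters is the reported
#' driver set. The observed FIS is compared to the fitted gamma as-is — the
#' cluster's truncation shift is NOT applied to it (set
#' `shiftObserved = TRUE` for sensitivity analysis). Genes in unfittable
#' clusters get NA p- and q-values and `is_driver = FALSE`.
#'
#' @param profiles gene FIS profiles from [geneFISProfiles()]; genes missing
#'   from `profiles` but present in the background are tested with observed
#'   FIS 0 (hence p = 1).
#' @param background a [GammaBackground-class].
#' @param estimated named numeric vector of estimated FIS (reported in the
#'   output table).
#' @param alphaFdr q-value threshold (default 0.05).
#' @param scope "per_cluster" (default) or "global" BH correction.
#' @param shiftObserved apply the cluster's domain shift to the observed FIS
#'   before testing (default FALSE).
#' @return data.frame sorted by (q, p, gene): `gene`, `cluster`,
#'   `observed_fis`, `estimated_fis`, `p_value`, `q_value`, `is_driver`.
#' @export
callDrivers <- function(profiles, background, estimated = NULL,
                        alphaFdr = 0.05, scope = c("per_cluster", "global"),
                        shiftObserved = FALSE) {
  scope <- match.arg(scope)
  stopifnot(is(background, "GammaBackground"))
  assignment <- clusterAssignments(background)
  fits <- gammaFits(background)
  genes <- names(assignment)
  obs <- stats::setNames(rep(0, length(genes)), genes)
  hit <- intersect(profiles$gene, genes)
  obs[hit] <- profiles$observed_fis[match(hit, profiles$gene)]
  row <- match(assignment, fits$cluster)
  alpha <- fits$alpha[row]
  beta <- fits$beta[row]
  shift <- ifelse(shiftObserved, fits$shift[row], 0)
  tab <- data.frame(
    gene = genes,
    cluster = as.integer(assignment),
    observed_fis = unname(obs),
    estimated_fis = if (is.null(estimated)) NA_real_
                    else unname(estimated[genes]),
    stringsAsFactors = FALSE)
  tab$p_value <- genePValue(tab$observed_fis + shift, alpha, beta)
  nNA <- sum(is.na(tab$p_value))
  if (nNA > 0L)
    message(sprintf("callDrivers: %d gene(s) in unfittable clusters (NA p-values)", nNA))
  if (scope == "global") {
    tab$q_value <- bhQValues(tab$p_value)
  } else {
    tab$q_value <- NA_real_
    for (cid in unique(tab$cluster)) {
      sel <- tab$cluster == cid
      tab$q_value[sel] <- bhQValues(tab$p_value[sel])
    }
  }
  tab$is_driver <- !is.na(tab$q_value) & tab$q_value <= alphaFdr
  tab <- tab[order(tab$q_value, tab$p_value, tab$gene,
                   na.last = TRUE, method = "radix"), ]
  rownames(tab) <- NULL
  tab
}

#' Write driver calls and the plain driver gene list
#'
#' @param calls data.frame from [callDrivers()].
#' @param path TSV path for the full table; the driver gene list (one symbol
#'   per line) is written next to it with suffix `_genes.txt` unless
#'   `listPath` is given.
#' @param listPath optional path for the plain gene list.
#' @return the TSV path, invisibly.
#' @export
writeDriverCalls <- function(calls, path, listPath = NULL) {
  writeTSV(calls, path)
  if (is.null(listPath))
    listPath <- sub("\\.tsv$", "", path)
  if (!grepl("_genes\\.txt$", listPath))
    listPath <- paste0(listPath, "_genes.txt")
  writeLines(calls$gene[calls$is_driver], listPath)
  invisible(path)
}
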