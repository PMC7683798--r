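## Evaluation metrics: patient coverage, deleterious ratio, overlap precision.

#' Patient coverage of a gene set
#'
#' Fraction of patients (distinct tumor sample barcodes in the MAF) carrying
#' at least one mutation in any gene of `geneSet`.
#'
#' @param geneSet character vector of gene symbols (may be empty -> 0).
#' @param mutations mutation data.frame from [readMAF()].
#' @return coverage in [0, 1].
#' @export
patientCoverage <- function(geneSet, mutations) {
  patients <- unique(mutations$sample)
  m <- length(patients)
  if (m == 0L) stopf("coverage is undefined for an empty MAF (no patients)")
  if (!length(geneSet)) return(0)
  covered <- unique(mutations$sample[mutations$gene %in% geneSet])
  length(covered) / m
}

#' Per-gene deleterious-mutation ratio
#'
#' Ratio of deleterious mutations (non-silent + null effects) to total
#' mutations for each requested gene; NA for genes without mutations.
#'
#' @param annotated mutation data.frame with an `effect` column
#'   ([readMAF()] or [annotateFIS()] output).
#' @param genes genes to report (default: all mutated genes).
#' @return named numeric vector of ratios in [0, 1] (NA where unmutated).
#' @export
deleteriousRatio <- function(annotated, genes = NULL) {
  del <- annotated$effect %in% c("non-silent", "null")
  tot <- table(annotated$gene)
  hit <- tapply(del, annotated$gene, sum)
  ratio <- as.numeric(hit) / as.numeric(tot[names(hit)])
  names(ratio) <- names(hit)
  if (is.null(genes)) return(ratio)
  out <- stats::setNames(rep(NA_real_, length(genes)), genes)
  common <- intersect(genes, names(ratio))
  out[common] <- ratio[common]
  out
}

#' Precision of a driver call set against a reference list
#'
#' `|called intersect reference| / |called|`, with the convention that a
#' method calling fewer than `minCalls` genes (default 3) scores 0.
#' Matching is exact string equality after whitespace stripping; no alias
#' resolution.
#'
#' @param called character vector of called driver genes.
#' @param reference character vector of reference genes (e.g. a curated
#'   driver catalog).
#' @param minCalls minimum call-set size for a non-zero precision.
#' @return precision in [0, 1].
#' @export
overlapPrecision <- function(called, reference, minCalls = 3L) {
  called <- unique(trimws(called))
  called <- called[nzchar(called)]
  if (length(called) < minCalls) return(0)
  reference <- unique(trimws(reference))
  length(intersect(called, reference)) / length(called)
}
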