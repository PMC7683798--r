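## Per-mutation FIS resolution and gene-level aggregation.

FIXED_FALLBACK <- c("silent" = 0, "non-coding" = 1,
                    "non-silent" = 2, "null" = 3)

#' Resolve a functional impact score for every mutation
#'
#' Each mutation is scored by a three-step cascade:
#' \enumerate{
#'   \item direct lookup in the FIS table (`fis_source = "lookup"`);
#'   \item if absent, the cohort-wide mean of looked-up scores for mutations
#'     of the same effect class (`"effect_mean"`);
#'   \item if that effect class has no looked-up score anywhere in the
#'     cohort, a fixed value reflecting increasing protein impact —
#'     silent 0, non-coding 1, non-silent 2, null 3 (`"fixed_fallback"`).
#' }
#' The cascade is idempotent: rerunning it on its own output changes nothing.
#'
#' @param mutations data.frame from [readMAF()] (effects attached).
#' @param table `FISTable` from [readFISTable()].
#' @return the input with numeric `fis` and character `fis_source` columns.
#' @export
annotateFIS <- function(mutations, table) {
  stopifnot(is.data.frame(mutations), "effect" %in% names(mutations))
  fis <- fisLookup(table, mutations$chrom, mutations$start,
                   mutations$ref, mutations$alt)
  src <- ifelse(is.na(fis), NA_character_, "lookup")
  found <- !is.na(fis)
  effectMeans <- tapply(fis[found], mutations$effect[found], mean)
  miss <- which(!found)
  for (i in miss) {
    eff <- mutations$effect[i]
    m <- effectMeans[eff]
    if (!is.na(m) && length(m)) {
      fis[i] <- m
      src[i] <- "effect_mean"
    } else {
      fis[i] <- FIXED_FALLBACK[[eff]]
      src[i] <- "fixed_fallback"
    }
  }
  mutations$fis <- as.numeric(fis)
  mutations$fis_source <- src
  mutations
}

#' Aggregate annotated mutations to gene-level FIS profiles
#'
#' The observed FIS of a gene is the sum of its mutations' FISs over the
#' whole cohort. Per-sample sums, mutation counts, deleterious counts
#' (non-silent + null effects) and the sample standard deviation of the
#' per-sample sums across mutated samples are also recorded; a gene mutated
#' in a single sample has `fis_sd = 0`.
#'
#' @param annotated data.frame from [annotateFIS()].
#' @return data.frame with one row per gene: `gene`, `observed_fis`,
#'   `n_mutations`, `n_deleterious`, `fis_sd`; the long per-sample table
#'   (`gene`, `sample`, `fis`) is kept in attribute `perSample`.
#' @export
geneFISProfiles <- function(annotated) {
  stopifnot(all(c("gene", "sample", "fis", "effect") %in% names(annotated)))
  perSample <- stats::aggregate(fis ~ gene + sample, data = annotated,
                                FUN = sum)
  sdOrZero <- function(v) if (length(v) > 1L) sd(v) else 0
  byGene <- split(annotated$fis, annotated$gene)
  genes <- names(byGene)
  deleterious <- annotated$effect %in% c("non-silent", "null")
  nDel <- tapply(deleterious, annotated$gene, sum)
  sdPerGene <- tapply(perSample$fis, perSample$gene, sdOrZero)
  out <- data.frame(
    gene = genes,
    observed_fis = vapply(byGene, sum, numeric(1)),
    n_mutations = lengths(byGene),
    n_deleterious = as.integer(nDel[genes]),
    fis_sd = as.numeric(sdPerGene[genes]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "perSample") <- perSample[order(perSample$gene, perSample$sample), ]
  out
}

#' MAF-derived covariates for the feature matrix
#'
#' Returns the three mutation-derived covariates — total mutation count,
#' deleterious mutation count, and the per-patient FIS standard deviation —
#' for an arbitrary gene universe. Genes absent from the MAF get (0, 0, 0).
#'
#' @param profiles data.frame from [geneFISProfiles()].
#' @param genes gene universe (default: the profiled genes).
#' @return numeric matrix, genes x 3, columns `total_mutations`,
#'   `deleterious_mutations`, `fis_sd`.
#' @export
mafDerivedFeatures <- function(profiles, genes = profiles$gene) {
  m <- matrix(0, nrow = length(genes), ncol = 3L,
              dimnames = list(genes, FEATURE_COLUMNS[10:12]))
  i <- match(profiles$gene, genes)
  keep <- !is.na(i)
  m[i[keep], 1L] <- profiles$n_mutations[keep]
  m[i[keep], 2L] <- profiles$n_deleterious[keep]
  m[i[keep], 3L] <- profiles$fis_sd[keep]
  m
}

#' Write / read the annotated-mutation audit table
#'
#' @param annotated data.frame from [annotateFIS()].
#' @param path TSV path.
#' @return `writeAnnotatedMutations`: the path, invisibly.
#'   `readAnnotatedMutations`: the data.frame.
#' @export
writeAnnotatedMutations <- function(annotated, path) {
  writeTSV(annotated, path)
}

#' @rdname writeAnnotatedMutations
#' @export
readAnnotatedMutations <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  for (col in c("chrom", "ref", "alt")) df[[col]] <- as.character(df[[col]])
  df
}
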