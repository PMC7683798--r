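## Covariate matrix assembly, KNN imputation, z-normalization.

#' Read the static nine-covariate gene table
#'
#' TSV with a header; first column gene symbol, then the nine static
#' covariates in order: expression, replication_timing, hic, gene_length,
#' constraint, hubness, regulatory_role, cna, methylation. Empty cells are
#' missing. Duplicate gene rows are a fatal error.
#'
#' @param path TSV file path.
#' @return data.frame with rownames = genes and the nine numeric columns.
#' @export
readStaticFeatures <- function(path) {
  if (!file.exists(path)) stopf("static feature table not found: %s", path)
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) != 10L)
    stopf("static feature table '%s' must have gene + 9 covariate columns",
          path)
  genes <- trimws(as.character(df[[1L]]))
  if (anyDuplicated(genes))
    stopf("duplicate gene row(s) in static feature table: %s",
          paste(unique(genes[duplicated(genes)]), collapse = ", "))
  vals <- as.matrix(df[, -1L])
  storage.mode(vals) <- "double"
  colnames(vals) <- STATIC_COLUMNS
  rownames(vals) <- genes
  as.data.frame(vals)
}

#' Assemble the gene x 12 covariate matrix
#'
#' The gene universe is the union of the static-table genes and the MAF
#' genes. Genes absent from the static table are missing in columns 1-9;
#' genes absent from the MAF get (0, 0, 0) in the three mutation-derived
#' columns. Column order is fixed and stable across runs.
#'
#' @param staticFeatures data.frame from [readStaticFeatures()] (or any
#'   data.frame with gene rownames and the nine static columns).
#' @param profiles gene FIS profiles from [geneFISProfiles()].
#' @return a raw-state [FeatureMatrix-class].
#' @export
assembleFeatures <- function(staticFeatures, profiles) {
  genes <- sort(unique(c(rownames(staticFeatures), profiles$gene)))
  m <- matrix(NA_real_, nrow = length(genes), ncol = 12L,
              dimnames = list(genes, FEATURE_COLUMNS))
  i <- match(rownames(staticFeatures), genes)
  m[i, STATIC_COLUMNS] <- as.matrix(staticFeatures[, STATIC_COLUMNS])
  m[, 10:12] <- mafDerivedFeatures(profiles, genes)
  FeatureMatrix(m, state = "raw")
}

## Pairwise squared-distance matrix over co-present features only (the sum
## runs over features present in both genes). Computed with dense matrix
## algebra: with X zero-filled at missing cells and M the presence mask,
##   D_ij = sum_l m_il m_jl (x_il - x_jl)^2
##        = (X^2 M')_ij + (M (X^2)')_ij - 2 (X X')_ij.
## Pairs sharing no feature get +Inf (an empty sum must not read as 0).
copresentDistances <- function(values) {
  M <- !is.na(values)
  X <- values
  X[!M] <- 0
  X2 <- X * X
  Mnum <- matrix(as.numeric(M), nrow = nrow(M))
  D <- X2 %*% t(Mnum) + Mnum %*% t(X2) - 2 * (X %*% t(X))
  D[D < 0] <- 0  # numerical noise
  shared <- Mnum %*% t(Mnum)
  D[shared == 0] <- Inf
  D
}

#' Impute missing covariates by K-nearest-neighbour means
#'
#' For each originally-missing cell (gene g, feature k), the imputed value is
#' the mean of feature k over the K genes nearest to g — by squared Euclidean
#' distance computed over features present in both genes — among genes with
#' feature k present. Neighbour sets are per-feature; ties at the K-th slot
#' are broken by gene order; genes sharing no co-present feature are at
#' infinite distance and never selected. Fewer than K candidates triggers a
#' warning and uses all available. Present values are never altered. A gene
#' with all features missing is a fatal error.
#'
#' @param fm raw-state [FeatureMatrix-class].
#' @param K neighbour count (default 100).
#' @return an imputed-state `FeatureMatrix`.
#' @export
imputeMissing <- function(fm, K = 100) {
  stopifnot(is(fm, "FeatureMatrix"))
  if (fm@state != "raw") stopf("imputeMissing expects a raw FeatureMatrix")
  v <- fm@values
  mask <- fm@missingMask
  allMissing <- rownames(v)[rowSums(!mask) == 0L]
  if (length(allMissing))
    stopf("gene(s) with all features missing: %s",
          paste(allMissing, collapse = ", "))
  out <- v
  if (any(mask)) {
    D <- copresentDistances(v)
    diag(D) <- Inf
    shortfall <- FALSE
    for (k in which(colSums(mask) > 0L)) {
      present <- which(!mask[, k])
      for (g in which(mask[, k])) {
        d <- D[g, present]
        finite <- is.finite(d)
        cand <- present[finite]
        d <- d[finite]
        if (!length(cand))
          stopf("gene '%s': no neighbour with feature '%s' present",
                rownames(v)[g], colnames(v)[k])
        if (length(cand) < K) shortfall <- TRUE
        ord <- order(d, cand)  # ties broken by gene order
        nn <- cand[ord[seq_len(min(K, length(cand)))]]
        out[g, k] <- mean(v[nn, k])
      }
    }
    if (shortfall)
      warnf("imputeMissing: fewer than K = %d candidate neighbours for some cells; used all available", K)
  }
  res <- fm
  res@values <- out
  res@state <- "imputed"
  validObject(res)
  res
}

#' Z-normalize the covariate columns
#'
#' Each column is centered by its mean and scaled by its sample standard
#' deviation (n - 1 denominator). A zero-variance column is a fatal error
#' (the z-score is undefined). Centers and scales are stored on the result
#' so values can be mapped back to original units.
#'
#' @param fm imputed-state [FeatureMatrix-class] (a raw matrix without
#'   missing values is also accepted).
#' @return a normalized-state `FeatureMatrix`.
#' @export
normalizeFeatures <- function(fm) {
  stopifnot(is(fm, "FeatureMatrix"))
  if (anyNA(fm@values))
    stopf("normalizeFeatures requires a fully observed (imputed) matrix")
  v <- fm@values
  centers <- colMeans(v)
  scales <- apply(v, 2L, sd)
  zero <- scales == 0 | !is.finite(scales)
  if (any(zero))
    stopf("zero-variance feature column(s): %s",
          paste(colnames(v)[zero], collapse = ", "))
  res <- fm
  res@values <- sweep(sweep(v, 2L, centers), 2L, scales, "/")
  res@centers <- centers
  res@scales <- scales
  res@state <- "normalized"
  validObject(res)
  res
}

#' Export a feature matrix as TSV
#'
#' @param fm a [FeatureMatrix-class].
#' @param path output path; the processing state is recorded in a leading
#'   comment line.
#' @return the path, invisibly.
#' @export
writeFeatureMatrix <- function(fm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# state: %s", fm@state), con)
  df <- data.frame(gene = geneNames(fm), fm@values, check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
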