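## Independent oracles used across tests. These deliberately avoid the code
## paths they check: straight loops and textbook formulas only.

## Benjamini-Hochberg by literal step-up enumeration on sorted p-values.
bhBrute <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  pv <- p[ok]
  m <- length(pv)
  if (m) {
    o <- order(pv)
    sorted <- pv[o]
    qs <- numeric(m)
    for (i in seq_len(m)) {
      js <- i:m
      qs[i] <- min(1, min(m * sorted[js] / js))
    }
    back <- numeric(m)
    back[o] <- qs
    q[ok] <- back
  }
  q
}

## Pairwise squared distance over co-present features, by explicit loops.
distBrute <- function(v) {
  G <- nrow(v)
  D <- matrix(Inf, G, G)
  for (i in seq_len(G)) for (j in seq_len(G)) {
    both <- !is.na(v[i, ]) & !is.na(v[j, ])
    if (any(both)) D[i, j] <- sum((v[i, both] - v[j, both])^2)
  }
  D
}

## KNN mean imputation by exhaustive neighbour search (ties by gene order).
knnImputeBrute <- function(v, K) {
  D <- distBrute(v)
  diag(D) <- Inf
  out <- v
  for (k in seq_len(ncol(v))) {
    present <- which(!is.na(v[, k]))
    for (g in which(is.na(v[, k]))) {
      cand <- present[is.finite(D[g, present])]
      ord <- cand[order(D[g, cand], cand)]
      nn <- ord[seq_len(min(K, length(ord)))]
      out[g, k] <- mean(v[nn, k])
    }
  }
  out
}

## Straight-line ReLU network forward pass, one sample at a time.
forwardBrute <- function(W2, b2, W3, b3, X, outputActivation = "linear") {
  n <- nrow(X)
  y <- numeric(n)
  for (i in seq_len(n)) {
    h <- pmax(as.numeric(W2 %*% X[i, ]) + b2, 0)
    yi <- sum(W3 * h) + b3
    if (outputActivation == "relu") yi <- max(yi, 0)
    y[i] <- yi
  }
  y
}

## Patient coverage by a patient-by-patient scan.
coverageBrute <- function(geneSet, mutations) {
  patients <- unique(mutations$sample)
  hit <- 0L
  for (p in patients) {
    genes <- mutations$gene[mutations$sample == p]
    if (any(genes %in% geneSet)) hit <- hit + 1L
  }
  hit / length(patients)
}

## Fixture writers -----------------------------------------------------------

writeToyMAF <- function(rows, path = tempfile(fileext = ".maf"),
                        columns = c("Hugo_Symbol", "Chromosome",
                                    "Start_Position", "End_Position",
                                    "Variant_Classification",
                                    "Reference_Allele", "Tumor_Seq_Allele",
                                    "Tumor_Sample_Barcode")) {
  df <- as.data.frame(rows, check.names = FALSE)
  names(df) <- columns[seq_along(df)]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

writeToyFISTable <- function(df, path = tempfile(fileext = ".tsv"),
                             header = TRUE) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = header)
  path
}

## A small fully-observed FeatureMatrix with deterministic content.
toyFeatureMatrix <- function(G = 50, p = 12, seed = 1, missing = 0) {
  set.seed(seed)
  v <- matrix(rnorm(G * p), G, p,
              dimnames = list(sprintf("g%04d", seq_len(G)),
                              paste0("f", seq_len(p))))
  if (missing > 0)
    v[matrix(runif(G * p) < missing, G, p)] <- NA_real_
  FeatureMatrix(v)
}
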