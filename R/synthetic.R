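## Seeded synthetic cohorts: MAF + FIS table + covariates + truth labels.

#' Specify a synthetic cohort
#'
#' Describes a seeded synthetic study: cluster-structured Gaussian
#' covariates, a smooth link from covariates to each gene's expected FIS,
#' additive Gaussian observation noise, and a configurable fraction of
#' spiked driver genes whose observed FIS is placed at `driverEffect` times
#' the 99.9th percentile of the null observed-FIS distribution. Mutation
#' counts per gene are drawn independently of driver status, so spiked
#' drivers carry their signal in per-mutation impact rather than mutation
#' frequency (the regime function-based callers target). Per-mutation scores
#' are random proportions of the gene total, so they sum exactly to the
#' intended observed FIS.
#'
#' The default noise standard deviation (1.1, against a gene-level signal
#' standard deviation of 3) leaves about 87% of FIS variance explainable
#' from the covariates, a realistic regime for these regressions on real
#' cohorts.
#'
#' @param nGenes,nPatients cohort dimensions (default 2000 genes, 100
#'   patients).
#' @param nClustersTrue number of Gaussian covariate clusters (default 2).
#' @param fisLink link from covariates to expected FIS: "linear",
#'   "quadratic", or "relu-mix".
#' @param noiseSd observation noise s.d. on the gene FIS scale.
#' @param driverFraction fraction of genes spiked as drivers (default 0).
#' @param driverEffect multiplier on the null 99.9th percentile (default 2).
#' @param missingFeatureRate fraction of static covariate cells masked.
#' @param missingFisRate fraction of mutations absent from the FIS table.
#' @param effectProbs sampling proportions for mutation effects.
#' @param meanMutations expected mutations per gene (min 1).
#' @param seed RNG seed; a fixed seed gives byte-identical output files.
#' @return validated spec (class `SyntheticCohortSpec`).
#' @export
syntheticCohortSpec <- function(nGenes = 2000L, nPatients = 100L,
                                nClustersTrue = 2L,
                                fisLink = c("linear", "quadratic", "relu-mix"),
                                noiseSd = 1.1, driverFraction = 0,
                                driverEffect = 2, missingFeatureRate = 0.05,
                                missingFisRate = 0,
                                effectProbs = c("non-silent" = 0.5,
                                                "silent" = 0.25,
                                                "null" = 0.15,
                                                "non-coding" = 0.1),
                                meanMutations = 3, seed = 1L) {
  fisLink <- match.arg(fisLink)
  stopifnot(nGenes >= nClustersTrue, nPatients >= 1,
            driverFraction >= 0, driverFraction <= 1,
            missingFeatureRate >= 0, missingFeatureRate <= 1,
            missingFisRate >= 0, missingFisRate <= 1,
            noiseSd >= 0, meanMutations >= 1,
            all(effectProbs >= 0), sum(effectProbs) > 0,
            setequal(names(effectProbs), EFFECT_LEVELS))
  if (driverFraction > 0 && driverEffect <= 1)
    warnf("driverEffect <= 1 with driverFraction > 0: spiked drivers will sit inside the null")
  structure(list(nGenes = as.integer(nGenes),
                 nPatients = as.integer(nPatients),
                 nClustersTrue = as.integer(nClustersTrue),
                 fisLink = fisLink, noiseSd = noiseSd,
                 driverFraction = driverFraction,
                 driverEffect = driverEffect,
                 missingFeatureRate = missingFeatureRate,
                 missingFisRate = missingFisRate,
                 effectProbs = effectProbs / sum(effectProbs),
                 meanMutations = meanMutations,
                 seed = as.integer(seed)),
            class = "SyntheticCohortSpec")
}

CLASSIFICATION_FOR_EFFECT <- c("silent" = "Silent",
                               "non-silent" = "Missense_Mutation",
                               "null" = "Nonsense_Mutation",
                               "non-coding" = "Intron")

#' Generate a synthetic cohort on disk
#'
#' Writes four files into `dir`: `cohort.maf` (readable by [readMAF()] with
#' zero skipped rows), `fis_table.tsv` ([readFISTable()] dialect),
#' `features.tsv` ([readStaticFeatures()] dialect, nine static covariates
#' with missing cells), and `truth.tsv` (gene, true cluster, driver status,
#' expected and intended observed FIS).
#'
#' @param spec a [syntheticCohortSpec()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the four file paths plus the in-memory
#'   `truth` data.frame and `mutations` table.
#' @export
generateCohort <- function(spec, dir) {
  stopifnot(inherits(spec, "SyntheticCohortSpec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)
  G <- spec$nGenes
  genes <- sprintf("G%05d", seq_len(G))
  patients <- sprintf("P%04d", seq_len(spec$nPatients))
  trueCluster <- rep_len(seq_len(spec$nClustersTrue), G)

  ## cluster-structured static covariates (9 columns)
  centers <- matrix(rnorm(spec$nClustersTrue * 9L, sd = 1.5),
                    nrow = spec$nClustersTrue)
  X9 <- centers[trueCluster, , drop = FALSE] +
    matrix(rnorm(G * 9L), nrow = G)
  dimnames(X9) <- list(genes, STATIC_COLUMNS)

  ## smooth link -> expected FIS (mean 8, sd 3 on the gene scale)
  lp <- switch(spec$fisLink,
    linear = drop(X9 %*% rnorm(9L)),
    quadratic = drop(X9 %*% rnorm(9L) + 0.3 * (X9^2) %*% rnorm(9L)),
    "relu-mix" = {
      A <- matrix(rnorm(9L * 4L), nrow = 9L)
      drop(relu(X9 %*% A) %*% rnorm(4L))
    })
  z <- (lp - mean(lp)) / sd(lp)
  expected <- pmax(0.5, 8 + 3 * z)
  observed <- pmax(0.1, expected + rnorm(G, sd = spec$noiseSd))

  ## spike drivers at driverEffect x the null 99.9th percentile
  nDrivers <- round(spec$driverFraction * G)
  isDriver <- rep(FALSE, G)
  if (nDrivers > 0L) {
    q999 <- quantile(observed, 0.999, names = FALSE)
    idx <- sample.int(G, nDrivers)
    isDriver[idx] <- TRUE
    observed[idx] <- spec$driverEffect * q999
  }

  ## decompose each gene's observed FIS into per-mutation scores
  nMut <- 1L + rpois(G, spec$meanMutations - 1)
  total <- sum(nMut)
  geneIdx <- rep.int(seq_len(G), nMut)
  w <- rgamma(total, shape = 5)
  wsum <- tapply(w, geneIdx, sum)
  fis <- observed[geneIdx] * w / as.numeric(wsum[as.character(geneIdx)])
  eff <- sample(names(spec$effectProbs), total, replace = TRUE,
                prob = spec$effectProbs)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, total, replace = TRUE)
  alt <- bases[(match(ref, bases) + sample(3L, total, replace = TRUE) - 1L) %% 4L + 1L]
  mutations <- data.frame(
    gene = genes[geneIdx],
    chrom = as.character((seq_len(total) - 1L) %% 22L + 1L),
    start = 10000L + seq_len(total) * 10L,
    end = 10000L + seq_len(total) * 10L,
    variant_classification = unname(CLASSIFICATION_FOR_EFFECT[eff]),
    ref = ref, alt = alt,
    sample = sample(patients, total, replace = TRUE),
    effect = eff, fis = fis,
    stringsAsFactors = FALSE)

  ## files
  mafPath <- file.path(dir, "cohort.maf")
  writeMAF(mutations, mafPath)

  keep <- runif(total) >= spec$missingFisRate
  fisPath <- file.path(dir, "fis_table.tsv")
  writeTSV(data.frame(chrom = mutations$chrom[keep],
                      pos = mutations$start[keep],
                      ref = mutations$ref[keep], alt = mutations$alt[keep],
                      score = mutations$fis[keep]), fisPath)

  Xout <- X9
  Xout[matrix(runif(length(Xout)) < spec$missingFeatureRate,
              nrow = nrow(Xout))] <- NA_real_
  featPath <- file.path(dir, "features.tsv")
  writeTSV(data.frame(gene = genes, Xout, check.names = FALSE), featPath)

  truth <- data.frame(gene = genes, true_cluster = trueCluster,
                      is_driver = isDriver, expected_fis = expected,
                      observed_fis = observed, n_mutations = nMut,
                      stringsAsFactors = FALSE)
  truthPath <- file.path(dir, "truth.tsv")
  writeTSV(truth, truthPath)

  invisible(list(maf = mafPath, fis_table = fisPath, features = featPath,
                 truth_file = truthPath, truth = truth,
                 mutations = mutations))
}
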