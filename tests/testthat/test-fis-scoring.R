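## A small annotated cohort reused across blocks: two mutations resolvable
## by lookup, the rest exercising the imputation cascade.
scoringFixture <- function() {
  maf <- writeToyMAF(list(
    gene  = c("A", "A", "B", "B", "C", "D"),
    chrom = c("1", "1", "2", "2", "3", "4"),
    start = c(100, 200, 300, 400, 500, 600),
    end   = c(100, 200, 300, 400, 500, 600),
    vc    = c("Missense_Mutation", "Missense_Mutation", "Missense_Mutation",
              "Silent", "Nonsense_Mutation", "Intron"),
    ref   = rep("A", 6), alt = rep("T", 6),
    sample = c("S1", "S2", "S1", "S3", "S2", "S3")))
  tab <- readFISTable(writeToyFISTable(data.frame(
    chrom = c("1", "1"), pos = c(100L, 200L), ref = c("A", "A"),
    alt = c("T", "T"), score = c(1.5, 2.5))))
  list(muts = readMAF(maf), tab = tab)
}

test_that("FIS resolution follows lookup -> effect mean -> fixed fallback", {
  fx <- scoringFixture()
  ann <- annotateFIS(fx$muts, fx$tab)
  ## direct lookups
  expect_equal(ann$fis[1:2], c(1.5, 2.5))
  expect_equal(ann$fis_source[1:2], c("lookup", "lookup"))
  ## missing non-silent -> cohort mean of looked-up non-silent {1.5, 2.5}
  expect_equal(ann$fis[3], 2.0)
  expect_equal(ann$fis_source[3], "effect_mean")
  ## effects with no looked-up score anywhere -> fixed values
  expect_equal(ann$fis[ann$effect == "silent"], 0)
  expect_equal(ann$fis[ann$effect == "null"], 3)
  expect_equal(ann$fis[ann$effect == "non-coding"], 1)
  expect_true(all(ann$fis_source[4:6] == "fixed_fallback"))
})

test_that("all four fixed fallback values apply when nothing is looked up", {
  maf <- writeToyMAF(list(
    gene = c("A", "B", "C", "D"), chrom = as.character(1:4),
    start = 1:4 * 10, end = 1:4 * 10,
    vc = c("Silent", "Intron", "Missense_Mutation", "Splice_Site"),
    ref = rep("G", 4), alt = rep("C", 4),
    sample = rep("S1", 4)))
  tab <- readFISTable(writeToyFISTable(data.frame(
    chrom = "9", pos = 999L, ref = "A", alt = "T", score = 9)))
  ann <- annotateFIS(readMAF(maf), tab)
  expect_equal(ann$fis, c(0, 1, 2, 3))
  expect_true(all(ann$fis_source == "fixed_fallback"))
})

test_that("annotation is idempotent", {
  fx <- scoringFixture()
  once <- annotateFIS(fx$muts, fx$tab)
  twice <- annotateFIS(once[names(fx$muts)], fx$tab)
  expect_equal(once$fis, twice$fis)
  expect_equal(once$fis_source, twice$fis_source)
})

test_that("gene profiles sum mutation FISs and track per-sample spread", {
  fx <- scoringFixture()
  ann <- annotateFIS(fx$muts, fx$tab)
  prof <- geneFISProfiles(ann)
  rowA <- prof[prof$gene == "A", ]
  expect_equal(rowA$observed_fis, 4.0)       # 1.5 + 2.5
  expect_equal(rowA$n_mutations, 2L)
  expect_equal(rowA$n_deleterious, 2L)
  ## samples S1=1.5, S2=2.5 -> sample sd
  expect_equal(rowA$fis_sd, sd(c(1.5, 2.5)))
  ## single-sample gene -> sd 0
  expect_equal(prof$fis_sd[prof$gene == "C"], 0)
  ## per-sample sums add back to the observed FIS
  ps <- attr(prof, "perSample")
  expect_equal(sum(ps$fis[ps$gene == "B"]),
               prof$observed_fis[prof$gene == "B"])
})

test_that("hand-built per-sample sums give the sqrt(2) sample sd", {
  ann <- data.frame(gene = c("G", "G"), sample = c("S1", "S2"),
                    fis = c(1.0, 3.0), effect = c("non-silent", "null"))
  prof <- geneFISProfiles(ann)
  expect_equal(prof$fis_sd, sqrt(2))
  expect_equal(prof$observed_fis, 4.0)
})

test_that("observed FIS is conserved and matches a raw re-scan", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(30:80, 1)
    genes <- sample(LETTERS[1:8], n, replace = TRUE)
    ann <- data.frame(
      gene = genes,
      sample = sample(sprintf("S%d", 1:6), n, replace = TRUE),
      fis = round(runif(n, 0, 4), 3),
      effect = sample(c("silent", "non-silent", "null", "non-coding"),
                      n, replace = TRUE))
    prof <- geneFISProfiles(ann)
    ## conservation: totals match (same addends, possibly regrouped)
    expect_equal(sum(prof$observed_fis), sum(ann$fis), tolerance = 1e-12)
    ## oracle: per-gene brute-force re-scan
    for (g in unique(genes))
      expect_identical(prof$observed_fis[prof$gene == g],
                       sum(ann$fis[ann$gene == g]))
  }
})

test_that("adding a positive-FIS mutation strictly increases observed FIS", {
  ann <- data.frame(gene = "G", sample = "S1", fis = 2.0,
                    effect = "non-silent")
  before <- geneFISProfiles(ann)$observed_fis
  ann2 <- rbind(ann, data.frame(gene = "G", sample = "S2", fis = 0.4,
                                effect = "silent"))
  expect_gt(geneFISProfiles(ann2)$observed_fis, before)
})

test_that("MAF-derived covariates default to zero for absent genes", {
  fx <- scoringFixture()
  prof <- geneFISProfiles(annotateFIS(fx$muts, fx$tab))
  m <- mafDerivedFeatures(prof, genes = c("A", "Z"))
  expect_equal(unname(m["A", ]), c(2, 2, sd(c(1.5, 2.5))))
  expect_equal(unname(m["Z", ]), c(0, 0, 0))
})

test_that("annotated-mutation audit table round-trips", {
  fx <- scoringFixture()
  ann <- annotateFIS(fx$muts, fx$tab)
  path <- tempfile(fileext = ".tsv")
  writeAnnotatedMutations(ann, path)
  back <- readAnnotatedMutations(path)
  expect_equal(back$fis, ann$fis)
  expect_equal(back$gene, ann$gene)
  expect_equal(back$fis_source, ann$fis_source)
})
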