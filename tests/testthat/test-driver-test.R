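## A GammaBackground built directly from known parts, bypassing the fit.
madeBackground <- function(assignment, fits, N = 3000) {
  attr(assignment, "nClusters") <- max(assignment)
  new("GammaBackground",
      assignment = setNames(as.integer(assignment), names(assignment)),
      nClusters = as.integer(max(assignment)), genesPerCluster = N,
      truncation = 0.05, fits = fits)
}

profilesFor <- function(obs) {
  data.frame(gene = names(obs), observed_fis = unname(obs),
             n_mutations = 1L, n_deleterious = 1L, fis_sd = 0)
}

test_that("gamma p-values follow the upper tail with the <= 0 rule", {
  ## exponential special case: shape 1, rate 1
  expect_equal(genePValue(1, 1, 1), exp(-1))
  ## non-positive observed FIS is never significant
  expect_equal(genePValue(-0.3, 5, 2), 1)
  expect_equal(genePValue(0, 5, 2), 1)
  ## monotone: larger observed FIS, smaller p
  p <- genePValue(c(0.5, 1, 2, 4), 2, 0.5)
  expect_true(all(diff(p) < 0))
  ## NA parameters propagate
  expect_true(is.na(genePValue(1, NA_real_, NA_real_)))
})

test_that("BH q-values match the brute-force step-up enumeration", {
  expect_equal(bhQValues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhQValues(1.0), 1.0)
  expect_error(bhQValues(c(0.5, 1.2)), "0, 1")
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(1:400, 1)
    p <- runif(n)^sample(1:3, 1)
    if (rep %% 3 == 0) p[sample(n, min(n, 3))] <- NA
    q <- bhQValues(p)
    expect_equal(q, bhBrute(p), tolerance = 1e-12)
    ## q is monotone non-decreasing when re-sorted by p
    ok <- !is.na(p)
    expect_true(all(diff(q[ok][order(p[ok])]) >= -1e-15))
  }
})

test_that("a single extreme gene among nulls is the sole driver", {
  set.seed(3)
  nulls <- rgamma(100, shape = 4, rate = 1)
  obs <- setNames(c(nulls, qgamma(1e-8, 4, 1, lower.tail = FALSE)),
                  sprintf("g%03d", 1:101))
  fits <- data.frame(cluster = 1L, alpha = 4, beta = 1, shift = 0,
                     n_used = 101L, usable = TRUE)
  bg <- madeBackground(setNames(rep(1L, 101), names(obs)), fits)
  calls <- callDrivers(profilesFor(obs), bg)
  expect_equal(calls$gene[calls$is_driver], "g101")
  expect_lt(calls$p_value[1], 1e-6)
})

test_that("all non-positive observed FISs yield zero drivers", {
  obs <- setNames(c(-1, -0.2, 0), c("a", "b", "c"))
  fits <- data.frame(cluster = 1L, alpha = 2, beta = 1, shift = 0,
                     n_used = 3L, usable = TRUE)
  bg <- madeBackground(setNames(rep(1L, 3), names(obs)), fits)
  calls <- callDrivers(profilesFor(obs), bg)
  expect_equal(calls$p_value, rep(1, 3))
  expect_false(any(calls$is_driver))
})

test_that("per-cluster and global BH agree when cluster p-vectors match", {
  set.seed(8)
  base <- rgamma(60, 3, 1)
  obs <- setNames(c(base, base), sprintf("g%03d", 1:120))
  cl <- setNames(rep(1:2, each = 60), names(obs))
  fits <- data.frame(cluster = 1:2, alpha = 3, beta = 1, shift = 0,
                     n_used = 60L, usable = TRUE)
  bg <- madeBackground(cl, fits)
  perCluster <- callDrivers(profilesFor(obs), bg, scope = "per_cluster")
  globalBH <- callDrivers(profilesFor(obs), bg, scope = "global")
  ord <- function(x) x[order(x$gene), c("gene", "q_value", "is_driver")]
  expect_equal(ord(perCluster), ord(globalBH), tolerance = 1e-12)
  ## brute-force check of the global variant
  expect_equal(globalBH$q_value, bhBrute(globalBH$p_value),
               tolerance = 1e-12)
})

test_that("unfittable clusters propagate NA and are never drivers", {
  obs <- setNames(c(10, 1, 2), c("a", "b", "c"))
  fits <- data.frame(cluster = 1:2, alpha = c(NA, 2), beta = c(NA, 1),
                     shift = c(0, 0), n_used = c(2L, 2L),
                     usable = c(FALSE, TRUE))
  bg <- madeBackground(setNames(c(1L, 2L, 2L), names(obs)), fits)
  expect_message(calls <- callDrivers(profilesFor(obs), bg), "unfittable")
  expect_true(is.na(calls$p_value[calls$gene == "a"]))
  expect_false(calls$is_driver[calls$gene == "a"])
})

test_that("genes absent from the profiles are tested with observed FIS 0", {
  obs <- setNames(5, "present")
  fits <- data.frame(cluster = 1L, alpha = 2, beta = 1, shift = 0,
                     n_used = 2L, usable = TRUE)
  bg <- madeBackground(setNames(c(1L, 1L), c("present", "absent")), fits)
  calls <- callDrivers(profilesFor(obs), bg)
  expect_equal(calls$p_value[calls$gene == "absent"], 1)
})

test_that("p-values are uniform when observed FISs come from the null", {
  ## calibration: draws from the fitted gamma itself must give U(0,1)
  ## p-values (KS at level 0.01 in at least 18 of 20 seeded replicates)
  passes <- 0L
  for (s in 1:20) {
    set.seed(400 + s)
    x <- rgamma(2000, shape = 3.2, rate = 0.7)
    p <- genePValue(x, 3.2, 0.7)
    ks <- suppressWarnings(ks.test(p, "punif"))
    passes <- passes + (ks$p.value > 0.01)
  }
  expect_gte(passes, 18L)
})

test_that("driver calls and gene lists are written sorted by q then p", {
  set.seed(12)
  obs <- setNames(c(rgamma(20, 2, 1), 40), sprintf("g%02d", 1:21))
  fits <- data.frame(cluster = 1L, alpha = 2, beta = 1, shift = 0,
                     n_used = 21L, usable = TRUE)
  bg <- madeBackground(setNames(rep(1L, 21), names(obs)), fits)
  calls <- callDrivers(profilesFor(obs), bg)
  expect_false(is.unsorted(calls$q_value, na.rm = TRUE))
  path <- tempfile(fileext = ".tsv")
  writeDriverCalls(calls, path, tempfile(fileext = "_genes.txt"))
  back <- read.delim(path)
  expect_equal(back$gene, calls$gene)
})
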