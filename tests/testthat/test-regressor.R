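## Build a FISModel from explicit weight arrays (identity response scaling).
handMadeModel <- function(W2, b2, W3, b3, activation = "linear") {
  new("FISModel", W2 = W2, b2 = b2, W3 = W3, b3 = b3,
      epochs = 1L, seed = 0L, lossTrace = 0,
      outputActivation = activation, targetCenter = 0, targetScale = 1,
      featureNames = paste0("f", seq_len(ncol(W2))))
}

normalizedMatrix <- function(G, p = 12, seed = 1) {
  set.seed(seed)
  v <- matrix(rnorm(G * p), G, p,
              dimnames = list(sprintf("g%05d", seq_len(G)),
                              paste0("f", seq_len(p))))
  normalizeFeatures(FeatureMatrix(v))
}

test_that("forward pass matches the straight-line reimplementation", {
  set.seed(5)
  for (activation in c("linear", "relu")) {
    for (rep in 1:5) {
      h <- sample(3:20, 1); p <- sample(2:12, 1); n <- sample(5:40, 1)
      W2 <- matrix(rnorm(h * p), h, p)
      b2 <- rnorm(h)
      W3 <- matrix(rnorm(h), 1, h)
      b3 <- rnorm(1)
      X <- matrix(rnorm(n * p), n, p,
                  dimnames = list(sprintf("s%02d", 1:n), paste0("f", 1:p)))
      model <- handMadeModel(W2, b2, W3, b3, activation)
      expect_equal(unname(predictFIS(model, X)),
                   forwardBrute(W2, b2, W3, b3, X, activation),
                   tolerance = 1e-10)
    }
  }
})

test_that("a hand-set one-weight network reproduces the pencil forward pass", {
  ## single hidden unit: h = relu(2 x1 - 1), y = 3 h + 0.5
  W2 <- matrix(c(2, 0), 1, 2); b2 <- -1
  W3 <- matrix(3, 1, 1); b3 <- 0.5
  X <- matrix(c(1, 0,    # h = relu(1) = 1  -> y = 3.5
                0, 5),   # h = relu(-1) = 0 -> y = 0.5
              nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("f1", "f2")))
  model <- handMadeModel(W2, b2, W3, b3)
  expect_equal(unname(predictFIS(model, X)), c(3.5, 0.5))
})

test_that("zeroed weights with an output bias predict the constant", {
  model <- handMadeModel(matrix(0, 4, 3), rep(0, 4), matrix(0, 1, 4), 1.7)
  X <- matrix(rnorm(15), 5, 3, dimnames = list(paste0("g", 1:5), NULL))
  expect_equal(unname(predictFIS(model, X)), rep(1.7, 5))
})

test_that("training is deterministic and bit-identical under a fixed seed", {
  fm <- normalizedMatrix(200)
  y <- setNames(rnorm(200, 10, 3), geneNames(fm))
  m1 <- trainFISModel(fm, y, seed = 42, epochs = 3)
  m2 <- trainFISModel(fm, y, seed = 42, epochs = 3)
  expect_identical(modelWeights(m1), modelWeights(m2))
  expect_identical(lossTrace(m1), lossTrace(m2))
  ## a different seed changes the weights
  m3 <- trainFISModel(fm, y, seed = 43, epochs = 3)
  expect_false(identical(modelWeights(m1)$W2, modelWeights(m3)$W2))
})

test_that("constant targets are recovered for all genes", {
  fm <- normalizedMatrix(150, seed = 8)
  y <- setNames(rep(4.2, 150), geneNames(fm))
  model <- trainFISModel(fm, y, seed = 1)
  pred <- predictFIS(model, fm)
  expect_true(all(abs(pred - 4.2) <= 4.2 * 1e-2 + 1e-3))
})

test_that("an exact linear signal is fitted to near-OLS quality", {
  set.seed(21)
  n <- 2000; p <- 12
  X <- matrix(rnorm((n + 300) * p), n + 300, p,
              dimnames = list(sprintf("g%05d", seq_len(n + 300)),
                              paste0("f", 1:p)))
  beta <- rnorm(p)
  y <- drop(X %*% beta) + rnorm(n + 300, sd = 0.01)
  fmTrain <- normalizeFeatures(FeatureMatrix(X[1:n, ]))
  model <- trainFISModel(fmTrain, setNames(y[1:n], rownames(X)[1:n]),
                         seed = 1)
  ns <- normalizationStats(fmTrain)
  Xte <- sweep(sweep(X[(n + 1):(n + 300), ], 2, ns$centers), 2,
               ns$scales, "/")
  pred <- predictFIS(model, Xte)
  truth <- y[(n + 1):(n + 300)]
  r2 <- 1 - sum((truth - pred)^2) / sum((truth - mean(truth))^2)
  ## the OLS oracle attains essentially 1 here; the network must be close
  ols <- lm.fit(cbind(1, X[1:n, ]), y[1:n])
  predOLS <- drop(cbind(1, X[(n + 1):(n + 300), ]) %*% ols$coefficients)
  r2OLS <- 1 - sum((truth - predOLS)^2) / sum((truth - mean(truth))^2)
  expect_gte(r2OLS, 0.999)
  expect_gte(r2, 0.99)
})

test_that("training rejects unnamed or non-finite targets", {
  fm <- normalizedMatrix(20, seed = 2)
  y <- setNames(rnorm(20), geneNames(fm))
  y[3] <- NA
  expect_error(trainFISModel(fm, y, seed = 1, epochs = 1),
               geneNames(fm)[3])
  expect_error(trainFISModel(fm, y[-1], seed = 1, epochs = 1), "missing")
})

test_that("predictions are invariant to gene ordering", {
  fm <- normalizedMatrix(60, seed = 4)
  y <- setNames(rnorm(60, 5), geneNames(fm))
  model <- trainFISModel(fm, y, seed = 9, epochs = 2)
  pred <- predictFIS(model, fm)
  perm <- sample(nrow(featureValues(fm)))
  predPerm <- predictFIS(model, featureValues(fm)[perm, ])
  expect_equal(predPerm, pred[perm])
})

test_that("the training loss trace mostly decreases", {
  fm <- normalizedMatrix(400, seed = 6)
  signal <- drop(featureValues(fm) %*% rnorm(12))
  y <- setNames(signal + rnorm(400, sd = 0.2 * sd(signal)), geneNames(fm))
  model <- trainFISModel(fm, y, seed = 3)
  tr <- lossTrace(model)
  expect_length(tr, 10L)
  expect_gte(sum(diff(tr) <= 0), 8L)
})

test_that("a dimension mismatch at prediction is fatal", {
  model <- handMadeModel(matrix(0, 2, 3), c(0, 0), matrix(0, 1, 2), 0)
  expect_error(predictFIS(model, matrix(0, 2, 5)), "dimension")
})

test_that("model serialization round-trips weights exactly", {
  fm <- normalizedMatrix(50, seed = 11)
  y <- setNames(rnorm(50, 3), geneNames(fm))
  model <- trainFISModel(fm, y, seed = 2, epochs = 2)
  path <- tempfile()
  writeFISModel(model, path)
  back <- readFISModel(path)
  expect_equal(modelWeights(back), modelWeights(model), tolerance = 1e-15)
  expect_equal(predictFIS(back, fm), predictFIS(model, fm),
               tolerance = 1e-12)
})
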