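## Single-hidden-layer feed-forward FIS regressor (ReLU hidden layer,
## linear output by default), trained by backpropagation with Adam on MSE.

relu <- function(x) (x + abs(x)) / 2

## Forward pass for an n x p input matrix; returns list(H, yhat) on the
## standardized response scale.
mlpForward <- function(W2, b2, W3, b3, X, outputActivation = "linear") {
  U2 <- X %*% t(W2)
  U2 <- sweep(U2, 2L, b2, "+")
  H <- relu(U2)
  y <- drop(H %*% t(W3)) + b3
  if (outputActivation == "relu") y <- relu(y)
  list(H = H, yhat = y)
}

#' Train the FIS regression network
#'
#' Fits a feed-forward network with one hidden layer of `hiddenUnits` ReLU
#' neurons and (by default) a linear output unit, minimizing mean squared
#' error by backpropagation with the Adam optimizer (mini-batches reshuffled
#' every epoch). The response is standardized internally — predictions are
#' returned on the original scale — and every gene in the feature matrix
#' must have a finite target, zero-mutation genes included (target 0).
#' Training is deterministic given `seed`.
#'
#' @param features normalized [FeatureMatrix-class].
#' @param targets named numeric vector of observed FIS, one per gene in
#'   `features`.
#' @param seed integer RNG seed for weight initialization and shuffling.
#' @param hiddenUnits hidden-layer width (default 100).
#' @param epochs passes over the data (default 10).
#' @param learningRate Adam step size (default 0.01).
#' @param batchSize mini-batch size (default 32).
#' @param outputActivation "linear" (default) or "relu". The ReLU output
#'   variant clamps predictions at zero and is provided for fidelity
#'   experiments; linear output is standard for regression.
#' @return a trained [FISModel-class].
#' @export
trainFISModel <- function(features, targets, seed = 1L, hiddenUnits = 100L,
                          epochs = 10L, learningRate = 0.01, batchSize = 32L,
                          outputActivation = c("linear", "relu")) {
  outputActivation <- match.arg(outputActivation)
  stopifnot(is(features, "FeatureMatrix"))
  if (features@state != "normalized")
    stopf("trainFISModel expects a normalized FeatureMatrix")
  X <- features@values
  genes <- rownames(X)
  if (!all(genes %in% names(targets)))
    stopf("missing target(s) for gene(s): %s",
          paste(head(setdiff(genes, names(targets)), 5L), collapse = ", "))
  y <- as.numeric(targets[genes])
  badY <- !is.finite(y)
  if (any(badY))
    stopf("non-finite target(s) for gene(s): %s",
          paste(head(genes[badY], 5L), collapse = ", "))

  n <- nrow(X); p <- ncol(X); h <- as.integer(hiddenUnits)
  yc <- mean(y)
  ys <- sd(y)
  if (!is.finite(ys) || ys == 0) ys <- 1
  yz <- (y - yc) / ys

  ## preserve the caller's RNG state
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))

  ## He init for the hidden layer; zero output layer so the initial model
  ## predicts the (standardized) target mean exactly
  W2 <- matrix(rnorm(h * p, sd = sqrt(2 / p)), nrow = h)
  b2 <- rep(0, h)
  W3 <- matrix(0, nrow = 1L, ncol = h)
  b3 <- 0
  adam <- list(mW2 = W2 * 0, vW2 = W2 * 0, mb2 = b2, vb2 = b2,
               mW3 = W3 * 0, vW3 = W3 * 0, mb3 = 0, vb3 = 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t <- 0L
  loss <- numeric(epochs)

  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = batchSize)
    for (s in starts) {
      idx <- ord[s:min(s + batchSize - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      yb <- yz[idx]
      fw <- mlpForward(W2, b2, W3, b3, Xb, outputActivation)
      resid <- fw$yhat - yb                      # d(MSE)/d(yhat) * n/2
      if (outputActivation == "relu") resid <- resid * (fw$yhat > 0)
      m <- length(idx)
      dOut <- 2 * resid / m
      gW3 <- matrix(dOut %*% fw$H, nrow = 1L)
      gb3 <- sum(dOut)
      dH <- outer(dOut, drop(W3)) * (fw$H > 0)
      gW2 <- t(dH) %*% Xb
      gb2 <- colSums(dH)
      t <- t + 1L
      step <- function(m0, v0, g) {
        m1 <- beta1 * m0 + (1 - beta1) * g
        v1 <- beta2 * v0 + (1 - beta2) * g * g
        upd <- learningRate * (m1 / (1 - beta1^t)) /
          (sqrt(v1 / (1 - beta2^t)) + eps)
        list(m = m1, v = v1, upd = upd)
      }
      sW2 <- step(adam$mW2, adam$vW2, gW2)
      adam$mW2 <- sW2$m; adam$vW2 <- sW2$v; W2 <- W2 - sW2$upd
      sb2 <- step(adam$mb2, adam$vb2, gb2)
      adam$mb2 <- sb2$m; adam$vb2 <- sb2$v; b2 <- b2 - sb2$upd
      sW3 <- step(adam$mW3, adam$vW3, gW3)
      adam$mW3 <- sW3$m; adam$vW3 <- sW3$v; W3 <- W3 - sW3$upd
      sb3 <- step(adam$mb3, adam$vb3, gb3)
      adam$mb3 <- sb3$m; adam$vb3 <- sb3$v; b3 <- b3 - sb3$upd
    }
    loss[epoch] <- mean((mlpForward(W2, b2, W3, b3, X,
                                    outputActivation)$yhat - yz)^2)
  }

  dimnames(W2) <- dimnames(W3) <- NULL
  names(b2) <- NULL
  new("FISModel", W2 = W2, b2 = b2, W3 = W3, b3 = as.numeric(b3)[1L],
      epochs = as.integer(epochs), seed = as.integer(seed),
      lossTrace = loss, outputActivation = outputActivation,
      targetCenter = yc, targetScale = ys, featureNames = colnames(X))
}

#' Predict estimated FIS for all genes
#'
#' Runs the forward pass (hidden ReLU layer, then the output unit) and
#' back-transforms from the standardized response scale. Predictions are a
#' pure function of the weights and features: invariant to gene order.
#'
#' @param model a [FISModel-class].
#' @param features normalized [FeatureMatrix-class] with the covariate
#'   columns the model was trained on.
#' @return named numeric vector of estimated FIS, one per gene.
#' @export
predictFIS <- function(model, features) {
  stopifnot(is(model, "FISModel"))
  X <- if (is(features, "FeatureMatrix")) features@values else as.matrix(features)
  if (ncol(X) != ncol(model@W2))
    stopf("feature dimension %d does not match model input dimension %d",
          ncol(X), ncol(model@W2))
  yz <- mlpForward(model@W2, model@b2, model@W3, model@b3, X,
                   model@outputActivation)$yhat
  out <- yz * model@targetScale + model@targetCenter
  if (any(!is.finite(out)))
    stopf("non-finite prediction(s) produced")
  stats::setNames(out, rownames(X))
}

#' @describeIn predictFIS `predict` method delegating to `predictFIS`.
#' @param object a `FISModel`.
#' @param ... passed on (expects `features`).
#' @export
setMethod("predict", "FISModel", function(object, ...) {
  predictFIS(object, ...)
})

#' Serialize / restore a FISModel as JSON-free flat text
#'
#' Weights and metadata are written to a plain-text key-value format so a
#' model can be audited and reloaded without binary artifacts.
#'
#' @param model a [FISModel-class].
#' @param path output path.
#' @return `writeFISModel`: the path, invisibly. `readFISModel`: the model.
#' @export
writeFISModel <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(x) paste(format(x, digits = 17), collapse = "\t")
  writeLines(c(
    sprintf("hidden_units\t%d", nrow(model@W2)),
    sprintf("input_dim\t%d", ncol(model@W2)),
    sprintf("epochs\t%d", model@epochs),
    sprintf("seed\t%d", model@seed),
    sprintf("output_activation\t%s", model@outputActivation),
    sprintf("target_center\t%s", num(model@targetCenter)),
    sprintf("target_scale\t%s", num(model@targetScale)),
    sprintf("feature_names\t%s", paste(model@featureNames, collapse = "\t")),
    sprintf("loss_trace\t%s", num(model@lossTrace)),
    sprintf("b2\t%s", num(model@b2)),
    sprintf("b3\t%s", num(model@b3)),
    sprintf("W2\t%s", num(as.numeric(model@W2))),
    sprintf("W3\t%s", num(as.numeric(model@W3)))), con)
  invisible(path)
}

#' @rdname writeFISModel
#' @export
readFISModel <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\t", fixed = TRUE)
  names(kv) <- vapply(kv, `[`, "", 1L)
  val <- function(k) kv[[k]][-1L]
  h <- as.integer(val("hidden_units")); p <- as.integer(val("input_dim"))
  new("FISModel",
      W2 = matrix(as.numeric(val("W2")), nrow = h, ncol = p),
      b2 = as.numeric(val("b2")),
      W3 = matrix(as.numeric(val("W3")), nrow = 1L, ncol = h),
      b3 = as.numeric(val("b3")),
      epochs = as.integer(val("epochs")), seed = as.integer(val("seed")),
      lossTrace = as.numeric(val("loss_trace")),
      outputActivation = as.character(val("output_activation")),
      targetCenter = as.numeric(val("target_center")),
      targetScale = as.numeric(val("target_scale")),
      featureNames = as.character(val("feature_names")))
}
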