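## a deliberately tiny configuration: fast forward/backward, all stages on
tiny_cfg <- function(nClasses = 5L, ...) {
  args <- list(
    lstmHidden = 4L, nHeads = 2L, attnDim = 8L,
    dsConvBlocks = list(c(6L, 3L), c(8L, 3L)),
    rriDense = 3L, classifierHidden = 6L, nClasses = nClasses,
    dropout = 0, inputPool = 2L
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(modelConfig, args)
}

test_that("model outputs are valid probability rows", {
  m <- buildCanet(tiny_cfg(), seed = 2)
  bs <- fixture_beats(2, seed = 3) # 10 beats
  p <- predictProba(m, bs[, 1:7])
  expect_identical(dim(p$probabilities), c(7L, 5L))
  expect_true(all(p$probabilities >= 0))
  expect_lt(max(abs(rowSums(p$probabilities) - 1)), 1e-6)
  expect_true(all(p$labels %in% AAMI_CLASSES))
})

test_that("attention weight rows are probability distributions", {
  m <- buildCanet(tiny_cfg(), seed = 2)
  bs <- fixture_beats(1, seed = 3)
  invisible(predictProba(m, bs))
  A <- attentionWeights(m)
  expect_identical(length(dim(A)), 4L) # batch x heads x steps x steps
  sums <- apply(A, c(1, 2, 3), sum)
  expect_lt(max(abs(sums - 1)), 1e-6)
})

test_that("depthwise-separable blocks have the predicted parameter count", {
  ## oracle: enumerate the tensors of a freshly built block
  for (dims in list(c(8L, 16L, 3L), c(4L, 4L, 5L), c(16L, 32L, 7L))) {
    cIn <- dims[1L]
    cOut <- dims[2L]
    K <- dims[3L]
    l <- canet:::layer_conv_block(cIn, cOut, K, separable = TRUE)
    convParams <- length(l$params$Wd) + length(l$params$bd) +
      length(l$params$Wp) + length(l$params$bp)
    expect_identical(convParams, cIn * K + cIn + cIn * cOut + cOut)
  }
})

test_that("the separable/standard parameter ratio follows the closed form", {
  for (dims in list(c(8, 16, 3), c(3, 7, 5), c(64, 128, 5), c(1, 1, 2))) {
    cIn <- dims[1]
    cOut <- dims[2]
    K <- dims[3]
    ## oracle: direct enumeration of bias-free weight tensors
    sep <- K * cIn + cIn * cOut
    std <- K * cIn * cOut
    expect_equal(
      depthwiseSeparableParamRatio(cIn, cOut, K),
      sep / std,
      tolerance = 1e-12
    )
    expect_equal(
      depthwiseSeparableParamRatio(cIn, cOut, K),
      1 / cOut + 1 / K,
      tolerance = 1e-12
    )
  }
  expect_equal(depthwiseSeparableParamRatio(8, 16, 3), (24 + 128) / 384)
  ## K = 1 saves nothing and warns
  expect_warning(r <- depthwiseSeparableParamRatio(4, 8, 1), "saves nothing")
  expect_gt(r, 1)
})

test_that("separable convolutions make the whole model smaller", {
  sep <- buildCanet(tiny_cfg(), seed = 1)
  std <- buildCanet(tiny_cfg(separable = FALSE), seed = 1)
  expect_lt(nParams(sep), nParams(std))
  ## same claim at the default geometry
  sepD <- buildCanet(reducedModelConfig(), seed = 1)
  stdD <- buildCanet(reducedModelConfig(separable = FALSE), seed = 1)
  expect_lt(nParams(sepD), nParams(stdD))
})

test_that("the default configuration stays lightweight", {
  expect_lt(nParams(buildCanet(modelConfig(), seed = 1)), 5e5)
})

test_that("all baselines satisfy the prediction contract", {
  bs <- fixture_beats(2, seed = 5)
  for (b in c("rnn", "cnn", "lstm", "gru", "bilstm")) {
    m <- buildBaseline(b, tiny_cfg(), seed = 3)
    p <- predictProba(m, bs)
    expect_identical(dim(p$probabilities), c(10L, 5L))
    expect_lt(max(abs(rowSums(p$probabilities) - 1)), 1e-6)
  }
  expect_error(buildBaseline("transformer", tiny_cfg()), "valid names")
})

test_that("bilstm roughly doubles the recurrent parameters of lstm", {
  cfg <- tiny_cfg()
  lstm <- buildBaseline("lstm", cfg, seed = 1)
  bi <- buildBaseline("bilstm", cfg, seed = 1)
  ## oracle: enumerate recurrent tensors only (the head differs by the
  ## wider feature vector)
  recParams <- function(m) {
    sum(vapply(m$trunk, function(l) {
      if (l$type == "lstm") sum(lengths(lapply(l$params, as.vector))) else 0L
    }, numeric(1)))
  }
  expect_identical(recParams(bi), 2 * recParams(lstm))
})

test_that("model gradients match finite differences", {
  expect_lt(gradcheck_model(buildCanet(tiny_cfg(nClasses = 3L), seed = 2)), 1e-3)
  expect_lt(gradcheck_model(buildBaseline("gru", tiny_cfg(nClasses = 3L), seed = 3)), 1e-3)
  expect_lt(gradcheck_model(buildBaseline("cnn", tiny_cfg(nClasses = 3L), seed = 4)), 1e-3)
})

test_that("evaluation-mode forwards are deterministic", {
  m <- buildCanet(tiny_cfg(), seed = 6)
  bs <- fixture_beats(2, seed = 7)
  p1 <- predictProba(m, bs)
  p2 <- predictProba(m, bs)
  expect_identical(p1$probabilities, p2$probabilities)
})

test_that("shuffling time steps changes the output", {
  m <- buildCanet(tiny_cfg(), seed = 8)
  set.seed(9)
  w <- matrix(rnorm(250), 250, 1)
  rri <- matrix(c(800, 800, 800, 1), 1)
  p1 <- predictProba(m, w, rri)$probabilities
  wPerm <- w[sample.int(250), , drop = FALSE]
  p2 <- predictProba(m, wPerm, rri)$probabilities
  expect_gt(max(abs(p1 - p2)), 1e-8)
})

test_that("invalid configurations are rejected with the violated constraint", {
  expect_error(modelConfig(nHeads = 3), "divisible")
  expect_error(modelConfig(attnDim = 64), "2 \\* lstmHidden")
  expect_error(modelConfig(nClasses = 1), "nClasses")
  expect_error(modelConfig(dropout = 1), "dropout")
})

test_that("checkpoints restore weights and predictions", {
  d <- withr::local_tempdir()
  m <- buildCanet(tiny_cfg(), seed = 11)
  bs <- fixture_beats(2, seed = 12)
  p1 <- predictProba(m, bs)$probabilities
  saveModel(m, file.path(d, "m.ckpt"))
  m2 <- loadModel(file.path(d, "m.ckpt"))
  p2 <- predictProba(m2, bs)$probabilities
  expect_equal(p1, p2, tolerance = 1e-12)
})
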