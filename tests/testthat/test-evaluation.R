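test_that("confusion matrices count pairs exactly", {
  yt <- c("N", "V", "N", "S")
  expect_identical(
    diag(confusionMatrix(yt, yt)),
    c(N = 2L, S = 1L, V = 1L, F = 0L, Q = 0L)
  )
  cm <- confusionMatrix(yt, rep("N", 4))
  expect_identical(sum(cm[, "N"]), 4L)
  expect_identical(sum(cm[, colnames(cm) != "N"]), 0L)
  ## oracle: explicit double loop on a random case
  set.seed(1)
  classes <- c("A", "B", "C")
  yt <- sample(classes, 30, replace = TRUE)
  yp <- sample(classes, 30, replace = TRUE)
  cm <- confusionMatrix(yt, yp, classes)
  for (i in seq_along(classes)) {
    for (j in seq_along(classes)) {
      expect_identical(
        cm[i, j],
        sum(yt == classes[i] & yp == classes[j])
      )
    }
  }
  expect_error(confusionMatrix(c("N", "X"), c("N", "N")), "unknown label")
  expect_error(confusionMatrix("N", c("N", "N")), "length")
})

test_that("metrics reproduce hand evaluation of the four formulas", {
  ## perfect binary classifier
  m <- computeMetrics(matrix(c(1, 0, 0, 1), 2, 2))
  expect_true(all(m$perClass[, c("ACC", "PRE", "REC", "F1")] == 1))
  ## hand-evaluated: TP=50 TN=40 FP=5 FN=5 for class 1
  cm <- matrix(c(50, 5, 5, 40), 2, 2, byrow = TRUE)
  m <- computeMetrics(cm)
  expect_equal(m$perClass$ACC[1], 0.90, tolerance = 1e-12)
  expect_equal(m$perClass$PRE[1], 10 / 11, tolerance = 1e-12)
  expect_equal(m$perClass$REC[1], 10 / 11, tolerance = 1e-12)
  expect_equal(m$perClass$F1[1], 10 / 11, tolerance = 1e-12)
  expect_equal(m$overallAccuracy, 0.9, tolerance = 1e-12)
  ## a class never predicted: precision undefined, F1 zero
  cm2 <- matrix(c(5, 0, 3, 0), 2, 2, byrow = TRUE)
  m2 <- computeMetrics(cm2)
  expect_true(is.na(m2$perClass$PRE[2]))
  expect_identical(m2$perClass$F1[2], 0)
  expect_error(computeMetrics(matrix(0, 2, 2)), "at least one")
})

test_that("metrics are invariant under class permutation and counts add up", {
  set.seed(2)
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    cm <- matrix(rpois(k * k, 8), k, k)
    rownames(cm) <- colnames(cm) <- paste0("C", seq_len(k))
    m <- computeMetrics(cm)
    ## counts are consistent with row/column sums
    for (i in seq_len(k)) {
      expect_identical(
        m$perClass$TP[i] + m$perClass$FN[i],
        as.integer(sum(cm[i, ]))
      )
      expect_identical(
        m$perClass$TP[i] + m$perClass$FP[i],
        as.integer(sum(cm[, i]))
      )
      expect_identical(
        m$perClass$TP[i] + m$perClass$TN[i] + m$perClass$FP[i] +
          m$perClass$FN[i],
        as.integer(sum(cm))
      )
      ## F1 is the harmonic mean of PRE and REC
      pre <- m$perClass$PRE[i]
      rec <- m$perClass$REC[i]
      if (!is.na(pre) && !is.na(rec) && pre + rec > 0) {
        expect_equal(m$perClass$F1[i], 2 * pre * rec / (pre + rec),
          tolerance = 1e-12
        )
      }
    }
    ## simultaneous row+column permutation permutes the table rows
    p <- sample(k)
    mp <- computeMetrics(cm[p, p])
    expect_equal(mp$perClass$F1, m$perClass$F1[p], tolerance = 1e-12)
    expect_equal(mp$overallAccuracy, m$overallAccuracy, tolerance = 1e-12)
  }
})

test_that("AUC equals the Mann-Whitney statistic", {
  expect_equal(rocCurve(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.1))$auc, 1.0)
  expect_equal(rocCurve(c(1, 1, 0, 0), c(0.1, 0.2, 0.8, 0.9))$auc, 0.0)
  set.seed(3)
  for (rep in 1:20) {
    n <- 200
    y <- runif(n) < 0.4
    if (!any(y) || all(y)) next
    scores <- round(rnorm(n), sample(c(1, 2, 8), 1)) # induce ties sometimes
    r <- rocCurve(y, scores)
    ## oracle: direct pairwise comparison with ties counted half
    pos <- scores[y]
    neg <- scores[!y]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(r$auc, mean(cmp), tolerance = 1e-12)
    ## curve shape invariants
    expect_true(all(diff(r$tpr) >= 0))
    expect_true(all(diff(r$fpr) >= 0))
    expect_equal(r$tpr[1], 0)
    expect_equal(r$tpr[length(r$tpr)], 1)
    expect_equal(r$fpr[length(r$fpr)], 1)
  }
  expect_error(rocCurve(c(1, 1), c(0.5, 0.2)), "positive and one negative")
})

test_that("roc agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  y <- runif(150) < 0.5
  s <- rnorm(150) + y
  r <- rocCurve(y, s)
  ref <- pROC::auc(pROC::roc(y, s, quiet = TRUE))
  expect_equal(r$auc, as.numeric(ref), tolerance = 1e-10)
})

test_that("training reduces the loss on a separable two-class task", {
  bs <- fixture_beats(100, classes = c("N", "V"), seed = 20)
  m <- buildBaseline("cnn", modelConfig(
    lstmHidden = 4L, nHeads = 2L, attnDim = 8L,
    dsConvBlocks = list(c(8L, 5L), c(8L, 5L)), rriDense = 4L,
    classifierHidden = 8L, nClasses = 5L, dropout = 0, inputPool = 4L
  ), seed = 3)
  m <- trainModel(m, bs, NULL, trainConfig(epochs = 10, learningRate = 1e-3, seed = 4))
  expect_lt(tail(m$history$loss, 1), m$history$loss[1])
})

test_that("training is deterministic given its seed", {
  bs <- fixture_beats(30, classes = c("N", "V"), seed = 21)
  va <- fixture_beats(10, classes = c("N", "V"), seed = 22)
  run <- function() {
    m <- buildCanet(modelConfig(
      lstmHidden = 4L, nHeads = 2L, attnDim = 8L,
      dsConvBlocks = list(c(6L, 3L)), rriDense = 3L,
      classifierHidden = 6L, nClasses = 5L, dropout = 0.2, inputPool = 4L
    ), seed = 5)
    m <- trainModel(m, bs, va, trainConfig(epochs = 3, seed = 9))
    m$history
  }
  h1 <- run()
  h2 <- run()
  expect_identical(h1, h2)
})

test_that("overlapping train/validation sources raise a leakage error", {
  bs <- fixture_beats(10, classes = c("N", "V"), seed = 23)
  m <- buildCanet(modelConfig(
    lstmHidden = 4L, nHeads = 2L, attnDim = 8L,
    dsConvBlocks = list(c(6L, 3L)), rriDense = 3L, classifierHidden = 6L,
    nClasses = 5L, inputPool = 4L
  ), seed = 1)
  expect_error(trainModel(m, bs, bs[, 1:5]), "leakage")
  expect_error(externalTest(m, bs, SummarizedExperiment::colData(bs)$source[1]), "leakage")
})

test_that("held-out evaluation refuses augmented beats", {
  bs <- fixture_beats(5, seed = 24)
  bal <- balanceClasses(bs, targetPerClass = 8L, seed = 1)
  m <- buildCanet(modelConfig(
    lstmHidden = 4L, nHeads = 2L, attnDim = 8L,
    dsConvBlocks = list(c(6L, 3L)), rriDense = 3L, classifierHidden = 6L,
    nClasses = 5L, inputPool = 4L
  ), seed = 1)
  expect_error(externalTest(m, bal), "never-augmented")
})

test_that("cross-validation keeps books straight", {
  bs <- fixture_beats(15, classes = c("N", "V"), seed = 25)
  factory <- function(seed) {
    buildBaseline("cnn", modelConfig(
      lstmHidden = 4L, nHeads = 2L, attnDim = 8L,
      dsConvBlocks = list(c(8L, 5L), c(8L, 5L)), rriDense = 4L,
      classifierHidden = 8L, nClasses = 5L, dropout = 0, inputPool = 4L
    ), seed = seed)
  }
  cv <- runCrossValidation(bs,
    k = 3, modelFactory = factory,
    trainCfg = trainConfig(epochs = 2, learningRate = 1e-3, seed = 2),
    seed = 7
  )
  expect_length(cv$folds, 3)
  ## each validation fold holds 5 originals per class
  for (f in 0:2) {
    vi <- which(cv$foldSplit$assignments == f)
    expect_identical(length(vi), 10L)
    expect_true(all(table(beatLabels(bs)[vi]) == 5L))
  }
  ## summary has mean and sd per class
  expect_true(all(c("meanACC", "sdACC", "meanF1", "sdF1") %in% colnames(cv$summary)))
})
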