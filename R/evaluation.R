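#' Training configuration
#'
#' @param epochs number of passes over the training set.
#' @param learningRate Adam step size.
#' @param batchSize minibatch size.
#' @param gradClipNorm global gradient-norm clipping threshold
#'   (`Inf` disables clipping).
#' @param seed integer seed controlling shuffling, dropout and any other
#'   training randomness; runs are deterministic given it.
#' @param optimizer only `"adam"` is implemented.
#' @return validated list of class `trainConfig`.
#' @export
trainConfig <- function(epochs = 30L, learningRate = 1e-4, batchSize = 64L,
                        gradClipNorm = 1.0, seed = 1L, optimizer = "adam") {
  if (epochs < 1L) stop("epochs must be >= 1")
  if (learningRate <= 0) stop("learningRate must be positive")
  if (batchSize < 1L) stop("batchSize must be >= 1")
  if (!identical(optimizer, "adam")) stop("only the 'adam' optimizer is available")
  structure(
    list(
      epochs = as.integer(epochs), learningRate = learningRate,
      batchSize = as.integer(batchSize), gradClipNorm = gradClipNorm,
      seed = as.integer(seed), optimizer = optimizer
    ),
    class = "trainConfig"
  )
}

## cross-entropy loss and gradient for a logits matrix and 1-based labels
xent <- function(logits, y) {
  P <- softmax_rows(logits)
  n <- nrow(P)
  eps <- 1e-12
  loss <- -mean(log(P[cbind(seq_len(n), y)] + eps))
  dLogits <- P
  dLogits[cbind(seq_len(n), y)] <- dLogits[cbind(seq_len(n), y)] - 1
  list(loss = loss, dLogits = dLogits / n)
}

#' Train a classifier
#'
#' Minimizes multiclass cross-entropy with Adam, global gradient-norm
#' clipping and seeded minibatch shuffling. Training and validation sets
#' must be disjoint in provenance (`source`), which is asserted; a NaN loss
#' aborts with the epoch and batch where it occurred.
#'
#' @param model a `canetModel` from [buildCanet()] or [buildBaseline()].
#' @param trainSegments,validSegments [BeatSegmentSet-class] objects;
#'   `validSegments` may be NULL.
#' @param config a [trainConfig()].
#' @param verbose print per-epoch progress.
#' @return the trained model, with a `history` data.frame (epoch, mean
#'   training loss, validation accuracy) stored in `model$history`.
#' @export
trainModel <- function(model, trainSegments, validSegments = NULL,
                       config = trainConfig(), verbose = FALSE) {
  if (!is.null(validSegments)) {
    overlap <- intersect(
      colData(trainSegments)$source,
      colData(validSegments)$source
    )
    if (length(overlap)) {
      stop(
        "leakage: ", length(overlap),
        " source(s) present in both training and validation sets, e.g. ",
        overlap[1L]
      )
    }
  }
  W <- t(beatWindows(trainSegments))
  R <- rriMatrix(trainSegments)
  cls <- class_levels(model)
  y <- match(beatLabels(trainSegments), cls)
  if (anyNA(y)) {
    ## e.g. a binary model trained on two of the five beat classes: bind
    ## the model's output units to the labels actually present
    seen <- sort(unique(beatLabels(trainSegments)))
    if (length(seen) == model$config$nClasses) {
      model$classes <- seen
      cls <- seen
      y <- match(beatLabels(trainSegments), cls)
    } else {
      stop(
        "labels {", paste(seen, collapse = ","), "} do not fit the model's ",
        model$config$nClasses, " output classes"
      )
    }
  }
  n <- nrow(W)
  if (n < 1L) stop("empty training set")
  layers <- all_layers(model)
  adam_init(layers)
  history <- data.frame(
    epoch = integer(0), loss = numeric(0),
    valAccuracy = numeric(0)
  )
  step <- 0L
  with_local_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batchSize))
      epLoss <- 0
      for (bi in seq_along(batches)) {
        idx <- batches[[bi]]
        zero_grads(layers)
        logits <- model_forward(model, W[idx, , drop = FALSE],
          R[idx, , drop = FALSE],
          training = TRUE
        )
        ce <- xent(logits, y[idx])
        if (!is.finite(ce$loss)) {
          stop("divergence: non-finite loss at epoch ", ep, ", batch ", bi)
        }
        model_backward(model, ce$dLogits)
        step <- step + 1L
        adam_step(layers, config$learningRate, step,
          clipNorm = config$gradClipNorm
        )
        epLoss <- epLoss + ce$loss * length(idx)
      }
      valAcc <- NA_real_
      if (!is.null(validSegments) && ncol(validSegments)) {
        pred <- predictProba(model, validSegments)
        valAcc <- mean(pred$labels == beatLabels(validSegments))
      }
      history[ep, ] <- list(ep, epLoss / n, valAcc)
      if (verbose) {
        message(sprintf(
          "epoch %d/%d  loss %.4f  val acc %s", ep, config$epochs,
          epLoss / n, ifelse(is.na(valAcc), "-", sprintf("%.4f", valAcc))
        ))
      }
    }
  })
  model$history <- history
  model
}

#' Confusion matrix
#'
#' @param yTrue,yPred label vectors of equal length.
#' @param classes ordered class levels; every label must appear here.
#' @return `k x k` integer matrix; entry `(i, j)` counts true class `i`
#'   predicted as class `j`.
#' @export
confusionMatrix <- function(yTrue, yPred, classes = AAMI_CLASSES) {
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  bad <- setdiff(unique(c(yTrue, yPred)), classes)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  as.matrix(unclass(table(
    factor(yTrue, levels = classes),
    factor(yPred, levels = classes)
  )))
}

#' Per-class classification metrics
#'
#' One-vs-rest TP/TN/FP/FN per class, then accuracy
#' `(TP + TN) / (TP + FP + TN + FN)`, precision `TP / (TP + FP)`, recall
#' `TP / (TP + FN)` and F1 (the harmonic mean of precision and recall).
#' A zero denominator leaves precision or recall `NA` (undefined) and sets
#' F1 to 0. Macro averages ignore `NA` entries.
#'
#' @param confusion `k x k` confusion matrix from [confusionMatrix()].
#' @return list of class `metricsTable`: `perClass` (data.frame with
#'   counts and rates per class), `macro` (named vector of macro-averaged
#'   ACC/PRE/REC/F1), `overallAccuracy` (trace / total).
#' @examples
#' cm <- matrix(c(50, 5, 5, 40), 2, 2)
#' computeMetrics(cm)$perClass
#' @export
computeMetrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (any(confusion < 0) || sum(confusion) == 0) {
    stop("confusion matrix must be nonnegative with at least one count")
  }
  k <- nrow(confusion)
  n <- sum(confusion)
  cls <- rownames(confusion) %||% paste0("C", seq_len(k))
  per <- data.frame(
    class = cls, TP = integer(k), TN = integer(k), FP = integer(k),
    FN = integer(k), ACC = numeric(k), PRE = numeric(k), REC = numeric(k),
    F1 = numeric(k), stringsAsFactors = FALSE
  )
  for (i in seq_len(k)) {
    tp <- confusion[i, i]
    fn <- sum(confusion[i, ]) - tp
    fp <- sum(confusion[, i]) - tp
    tn <- n - tp - fn - fp
    pre <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (is.na(pre) || is.na(rec) || (pre + rec) == 0) {
      0
    } else {
      2 * pre * rec / (pre + rec)
    }
    per[i, 2:9] <- list(tp, tn, fp, fn, (tp + tn) / n, pre, rec, f1)
  }
  structure(
    list(
      perClass = per,
      macro = c(
        ACC = mean(per$ACC), PRE = mean(per$PRE, na.rm = TRUE),
        REC = mean(per$REC, na.rm = TRUE), F1 = mean(per$F1)
      ),
      overallAccuracy = sum(diag(confusion)) / n
    ),
    class = "metricsTable"
  )
}

#' ROC curve and AUC for a binary problem
#'
#' Thresholds are the unique scores in descending order (ties grouped),
#' with a leading sentinel; AUC is the trapezoidal area under the
#' (FPR, TPR) curve, which equals the Mann-Whitney U statistic divided by
#' `nPos * nNeg`.
#'
#' @param yTrue logical or 0/1 vector (positives TRUE/1).
#' @param scores numeric classifier scores, higher = more positive.
#' @return list of class `rocCurve`: `thresholds`, `tpr`, `fpr`, `auc`.
#' @export
rocCurve <- function(yTrue, scores) {
  yTrue <- as.logical(yTrue)
  nPos <- sum(yTrue)
  nNeg <- sum(!yTrue)
  if (nPos == 0L || nNeg == 0L) {
    stop("need at least one positive and one negative")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  ## cumulative counts at each threshold (score >= thr is predicted positive)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  yt <- yTrue[ord]
  grp <- match(s, thr)
  tpAt <- cumsum(yt)
  fpAt <- cumsum(!yt)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tpAt[last] / nPos)
  fpr <- c(0, fpAt[last] / nNeg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(
    list(
      thresholds = c(Inf, thr), tpr = tpr, fpr = fpr, auc = auc
    ),
    class = "rocCurve"
  )
}

#' One-vs-rest ROC curves for a multiclass problem
#'
#' @param yTrue character labels.
#' @param probabilities `n x k` matrix with column names = classes.
#' @return list with `perClass` (named list of [rocCurve()] objects) and
#'   `macroAuc` (mean per-class AUC over classes present in `yTrue`).
#' @export
multiclassRoc <- function(yTrue, probabilities) {
  cls <- colnames(probabilities)
  curves <- list()
  for (cl in cls) {
    pos <- yTrue == cl
    if (any(pos) && any(!pos)) {
      curves[[cl]] <- rocCurve(pos, probabilities[, cl])
    }
  }
  if (!length(curves)) stop("no class with both positives and negatives")
  list(
    perClass = curves,
    macroAuc = mean(vapply(curves, function(r) r$auc, numeric(1)))
  )
}

#' Stratified cross-validation of a beat classifier
#'
#' For each fold: the training split is class-balanced by augmentation
#' ([balanceClasses()]) while the validation split keeps only untouched
#' originals; a fresh model is built, trained and evaluated. Because
#' augmentation happens inside the training split, no augmented copy of a
#' validation beat can reach training (asserted via `source`).
#'
#' @param segments a [BeatSegmentSet-class] of original segments.
#' @param k number of folds.
#' @param modelFactory function(seed) returning an untrained `canetModel`.
#' @param trainCfg a [trainConfig()].
#' @param balance balance training splits by augmentation.
#' @param seed seed for fold assignment and per-fold training seeds.
#' @param verbose print progress.
#' @return list of class `cvResult`: `folds` (per-fold `metricsTable`),
#'   `rocs` (per-fold multiclass ROC), `summary` (data.frame of mean and
#'   sd per metric per class across folds).
#' @export
runCrossValidation <- function(segments, k = 5L, modelFactory = buildCanet,
                               trainCfg = trainConfig(), balance = TRUE,
                               seed = 1L, verbose = FALSE) {
  fs <- makeFolds(segments, k, seed)
  foldMetrics <- list()
  rocs <- list()
  for (f in seq_len(k) - 1L) {
    trIdx <- which(fs$assignments != f)
    vaIdx <- which(fs$assignments == f)
    train <- segments[, trIdx]
    valid <- segments[, vaIdx]
    if (balance) {
      train <- balanceClasses(train, seed = seed + 1000L + f)
    }
    model <- modelFactory(seed = seed + f)
    cfg <- trainCfg
    cfg$seed <- trainCfg$seed + f
    model <- trainModel(model, train, valid, cfg, verbose = verbose)
    pred <- predictProba(model, valid)
    cm <- confusionMatrix(
      beatLabels(valid), pred$labels,
      classes = class_levels(model)
    )
    foldMetrics[[f + 1L]] <- computeMetrics(cm)
    rocs[[f + 1L]] <- multiclassRoc(beatLabels(valid), pred$probabilities)
    if (verbose) {
      message(sprintf(
        "fold %d: accuracy %.4f", f + 1L,
        foldMetrics[[f + 1L]]$overallAccuracy
      ))
    }
  }
  perClassStack <- do.call(rbind, lapply(seq_along(foldMetrics), function(i) {
    cbind(fold = i, foldMetrics[[i]]$perClass)
  }))
  agg <- do.call(rbind, lapply(
    split(perClassStack, perClassStack$class),
    function(d) {
      data.frame(
        class = d$class[1L],
        meanACC = mean(d$ACC), sdACC = stats::sd(d$ACC),
        meanPRE = mean(d$PRE, na.rm = TRUE), sdPRE = stats::sd(d$PRE),
        meanREC = mean(d$REC, na.rm = TRUE), sdREC = stats::sd(d$REC),
        meanF1 = mean(d$F1), sdF1 = stats::sd(d$F1)
      )
    }
  ))
  structure(
    list(folds = foldMetrics, rocs = rocs, summary = agg, foldSplit = fs),
    class = "cvResult"
  )
}

#' Evaluate a trained model on held-out beats
#'
#' The held-out set must be source-disjoint from everything the model was
#' trained on (pass the training sources); only raw, never-augmented beats
#' are accepted.
#'
#' @param model a trained `canetModel`.
#' @param heldout a [BeatSegmentSet-class] of original segments.
#' @param trainSources character vector of training `source` strings used
#'   for the leakage check (NULL skips the check).
#' @return list with `metrics` (a `metricsTable`), `roc` (multiclass ROC)
#'   and `confusion`.
#' @export
externalTest <- function(model, heldout, trainSources = NULL) {
  if (any(colData(heldout)$augmented)) {
    stop("held-out evaluation must use raw, never-augmented beats")
  }
  if (!is.null(trainSources)) {
    overlap <- intersect(trainSources, colData(heldout)$source)
    if (length(overlap)) {
      stop(
        "leakage: held-out set shares ", length(overlap),
        " source(s) with training, e.g. ", overlap[1L]
      )
    }
  }
  pred <- predictProba(model, heldout)
  cm <- confusionMatrix(
    beatLabels(heldout), pred$labels,
    classes = class_levels(model)
  )
  list(
    metrics = computeMetrics(cm),
    roc = multiclassRoc(beatLabels(heldout), pred$probabilities),
    confusion = cm
  )
}
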