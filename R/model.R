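#' Architecture configuration
#'
#' Holds every architecture hyperparameter of the beat classifier. The
#' forward path is: per-beat window (length L, one channel, optionally
#' average-pooled by `inputPool` to shorten the step sequence) -> BiLSTM ->
#' multi-head self-attention with residual connection and layer
#' normalization -> stacked depthwise-separable 1-D convolution blocks
#' (depthwise then pointwise convolution, batch normalization, ReLU,
#' stride-2 max pooling) -> global average pooling -> concatenation with the
#' RRI branch (4 features -> `rriDense`, ReLU) -> `classifierHidden` with
#' ReLU and dropout -> `nClasses` logits.
#'
#' @param lstmHidden LSTM hidden size per direction.
#' @param lstmLayers number of stacked BiLSTM layers.
#' @param nHeads attention heads; must divide `attnDim`.
#' @param attnDim attention model width; must equal `2 * lstmHidden` (the
#'   BiLSTM output width).
#' @param dsConvBlocks list of `c(channels, kernel)` pairs.
#' @param rriDense width of the RRI branch.
#' @param classifierHidden width of the classifier hidden layer.
#' @param nClasses number of output classes.
#' @param dropout dropout fraction in `[0, 1)` on the classifier hidden
#'   layer (training only).
#' @param inputPool average-pool factor applied to the input window before
#'   the BiLSTM (1 = none); shortens the step sequence the recurrent and
#'   attention stages traverse.
#' @param separable use depthwise-separable convolutions (`FALSE` swaps in
#'   standard convolutions of the same geometry, for parameter-count
#'   comparisons).
#'
#' @return validated list of class `modelConfig`.
#' @export
modelConfig <- function(lstmHidden = 64L, lstmLayers = 1L, nHeads = 4L,
                        attnDim = 2L * lstmHidden,
                        dsConvBlocks = list(c(64L, 5L), c(128L, 5L)),
                        rriDense = 16L, classifierHidden = 64L,
                        nClasses = 5L, dropout = 0.2, inputPool = 1L,
                        separable = TRUE) {
  bad <- character(0)
  if (attnDim != 2L * lstmHidden) {
    bad <- c(bad, "attnDim must equal 2 * lstmHidden (the BiLSTM output width)")
  }
  if (attnDim %% nHeads != 0L) bad <- c(bad, "attnDim must be divisible by nHeads")
  if (nClasses < 2L) bad <- c(bad, "nClasses must be >= 2")
  if (dropout < 0 || dropout >= 1) bad <- c(bad, "dropout must lie in [0, 1)")
  sizes <- c(
    lstmHidden, lstmLayers, rriDense, classifierHidden,
    unlist(dsConvBlocks), inputPool
  )
  if (any(sizes < 1L)) bad <- c(bad, "all sizes must be positive")
  if (length(bad)) stop("invalid model config: ", paste(bad, collapse = "; "))
  structure(
    list(
      lstmHidden = as.integer(lstmHidden), lstmLayers = as.integer(lstmLayers),
      nHeads = as.integer(nHeads), attnDim = as.integer(attnDim),
      dsConvBlocks = lapply(dsConvBlocks, as.integer),
      rriDense = as.integer(rriDense),
      classifierHidden = as.integer(classifierHidden),
      nClasses = as.integer(nClasses), dropout = dropout,
      inputPool = as.integer(inputPool), separable = isTRUE(separable)
    ),
    class = "modelConfig"
  )
}

#' A small configuration for desk-scale training
#'
#' Same architecture as the default, with reduced widths and an input pool
#' of 4 (a 250-sample window becomes a 62-step sequence). Trains in minutes
#' on one CPU while remaining comfortably expressive for the synthetic
#' five-class task.
#'
#' @param ... overrides passed to [modelConfig()].
#' @return a `modelConfig`.
#' @export
reducedModelConfig <- function(...) {
  args <- list(
    lstmHidden = 16L, nHeads = 2L, attnDim = 32L,
    dsConvBlocks = list(c(16L, 5L), c(32L, 5L)),
    rriDense = 8L, classifierHidden = 32L, inputPool = 4L
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(modelConfig, args)
}

## assemble layer lists for a given architecture; called under a set seed
build_layers <- function(kind, cfg) {
  trunk <- list()
  convIn <- NULL
  if (kind == "canet") {
    inDim <- 1L
    for (i in seq_len(cfg$lstmLayers)) {
      trunk <- c(trunk, list(
        fwd = layer_lstm(inDim, cfg$lstmHidden, reverse = FALSE),
        bwd = layer_lstm(inDim, cfg$lstmHidden, reverse = TRUE)
      ))
      inDim <- 2L * cfg$lstmHidden
    }
    trunk <- c(trunk, list(attn = layer_attention(cfg$attnDim, cfg$nHeads)))
    convIn <- cfg$attnDim
    for (blk in cfg$dsConvBlocks) {
      trunk <- c(trunk, list(conv = layer_conv_block(
        convIn, blk[1L], blk[2L],
        separable = cfg$separable
      )))
      convIn <- blk[1L]
    }
    trunk <- c(trunk, list(gap = layer_gap()))
  } else if (kind %in% c("rnn", "lstm", "gru")) {
    maker <- switch(kind, rnn = layer_rnn, lstm = layer_lstm, gru = layer_gru)
    trunk <- list(fwd = maker(1L, cfg$lstmHidden))
    convIn <- cfg$lstmHidden
  } else if (kind == "bilstm") {
    trunk <- list(
      fwd = layer_lstm(1L, cfg$lstmHidden, reverse = FALSE),
      bwd = layer_lstm(1L, cfg$lstmHidden, reverse = TRUE)
    )
    convIn <- 2L * cfg$lstmHidden
  } else if (kind == "cnn") {
    c1 <- cfg$dsConvBlocks[[1L]]
    c2 <- cfg$dsConvBlocks[[min(2L, length(cfg$dsConvBlocks))]]
    trunk <- list(
      conv = layer_conv_block(1L, c1[1L], c1[2L], separable = FALSE),
      conv = layer_conv_block(c1[1L], c2[1L], c2[2L], separable = FALSE),
      gap = layer_gap()
    )
    convIn <- c2[1L]
  } else {
    stop(
      "unknown model '", kind,
      "'; valid: canet, rnn, cnn, lstm, gru, bilstm"
    )
  }
  rri <- layer_dense(4L, cfg$rriDense, activation = "relu")
  head <- layer_dense(convIn + cfg$rriDense, cfg$classifierHidden,
    activation = "relu"
  )
  drop <- layer_dropout(cfg$dropout)
  out <- layer_dense(cfg$classifierHidden, cfg$nClasses)
  list(trunk = trunk, rri = rri, head = head, drop = drop, out = out, kind = kind)
}

#' Build the CANet classifier
#'
#' Constructs the hybrid BiLSTM / multi-head-attention /
#' depthwise-separable-convolution classifier with freshly initialized
#' weights (Glorot-uniform, deterministic given `seed`).
#'
#' @param config a [modelConfig()].
#' @param seed integer seed for weight initialization.
#' @return a model object of class `canetModel`.
#' @seealso [buildBaseline()], [trainModel()], [predictProba()]
#' @export
buildCanet <- function(config = modelConfig(), seed = 1L) {
  new_model("canet", config, seed)
}

#' Build a baseline classifier
#'
#' Baseline architectures sharing CANet's input/output contract (window +
#' RRI features in, class probabilities out): `"rnn"`, `"lstm"`, `"gru"`,
#' `"bilstm"` use the final hidden state of the recurrence; `"cnn"` uses
#' two standard convolution blocks with pooling.
#'
#' @param name one of `"rnn"`, `"cnn"`, `"lstm"`, `"gru"`, `"bilstm"`.
#' @param config a [modelConfig()].
#' @param seed integer seed for weight initialization.
#' @return a model object of class `canetModel`.
#' @export
buildBaseline <- function(name, config = modelConfig(), seed = 1L) {
  if (!name %in% c("rnn", "cnn", "lstm", "gru", "bilstm")) {
    stop(
      "unknown baseline '", name,
      "'; valid names: rnn, cnn, lstm, gru, bilstm"
    )
  }
  new_model(name, config, seed)
}

new_model <- function(kind, config, seed) {
  stopifnot(inherits(config, "modelConfig"))
  m <- new.env(parent = emptyenv())
  m$kind <- kind
  m$config <- config
  with_local_seed(seed, {
    parts <- build_layers(kind, config)
    m$trunk <- parts$trunk
    m$rriLayer <- parts$rri
    m$headLayer <- parts$head
    m$dropLayer <- parts$drop
    m$outLayer <- parts$out
  })
  m$rriScale <- c(1000, 1000, 1000, 1) # ms -> s; ratio unscaled
  class(m) <- "canetModel"
  m
}

all_layers <- function(model) {
  c(
    model$trunk,
    list(model$rriLayer, model$headLayer, model$dropLayer, model$outLayer)
  )
}

## average-pool the raw window by the configured factor: [B, L] -> [B, T, 1]
pool_input <- function(W, p) {
  B <- nrow(W)
  T <- ncol(W) %/% p
  if (p == 1L) {
    X <- W
    dim(X) <- c(B, T, 1L)
    return(X)
  }
  M <- kronecker(diag(T), matrix(1 / p, p, 1L))
  Xp <- W[, seq_len(T * p), drop = FALSE] %*% M
  dim(Xp) <- c(B, T, 1L)
  Xp
}

## forward pass to logits; windows [B, L], rri [B, 4]
model_forward <- function(model, windows, rri, training = FALSE) {
  cfg <- model$config
  X <- pool_input(windows, cfg$inputPool)
  recurrentPair <- function(i) {
    # adjacent fwd/bwd LSTM layers form one BiLSTM: concat along features
    Hf <- nn_forward(model$trunk[[i]], X, training)
    Hb <- nn_forward(model$trunk[[i + 1L]], X, training)
    d <- dim(Hf)
    Y <- array(0, c(d[1L], d[2L], 2L * d[3L]))
    Y[, , seq_len(d[3L])] <- Hf
    Y[, , d[3L] + seq_len(d[3L])] <- Hb
    Y
  }
  nms <- names(model$trunk)
  i <- 1L
  while (i <= length(model$trunk)) {
    if (!is.null(nms) && nms[i] == "fwd" && i < length(model$trunk) &&
      nms[i + 1L] == "bwd") {
      X <- recurrentPair(i)
      i <- i + 2L
    } else {
      X <- nn_forward(model$trunk[[i]], X, training)
      i <- i + 1L
    }
  }
  if (is.matrix(X)) {
    model$featMode <- "pooled"
    feat <- X
  } else if (model$kind == "bilstm") {
    ## forward direction's state at the last step, reverse direction's at
    ## the first (each direction's terminal state)
    d <- dim(X)
    H <- d[3L] %/% 2L
    fEnd <- X[, d[2L], seq_len(H), drop = FALSE]
    bEnd <- X[, 1L, H + seq_len(H), drop = FALSE]
    dim(fEnd) <- c(d[1L], H)
    dim(bEnd) <- c(d[1L], H)
    model$featMode <- "bilstm_ends"
    model$seqLen <- d[2L]
    feat <- cbind(fEnd, bEnd)
  } else {
    ## unidirectional recurrent baselines: final hidden state
    d <- dim(X)
    feat <- X[, d[2L], , drop = FALSE]
    dim(feat) <- c(d[1L], d[3L])
    model$featMode <- "last"
    model$seqLen <- d[2L]
  }
  model$trunkOutDim <- ncol(feat)
  rriN <- rri / matrix(model$rriScale, nrow(rri), 4L, byrow = TRUE)
  rriF <- nn_forward(model$rriLayer, rriN, training)
  Z <- cbind(feat, rriF)
  Hh <- nn_forward(model$headLayer, Z, training)
  Hd <- nn_forward(model$dropLayer, Hh, training)
  nn_forward(model$outLayer, Hd, training)
}

## backward from dLogits; populates layer grads, returns nothing useful.
## Stores the gradient at the GAP input (last conv block output) in
## model$gapInputGrad for the activation-map explainer.
model_backward <- function(model, dLogits) {
  dHd <- nn_backward(model$outLayer, dLogits)
  dHh <- nn_backward(model$dropLayer, dHd)
  dZ <- nn_backward(model$headLayer, dHh)
  k <- model$trunkOutDim
  dFeat <- dZ[, seq_len(k), drop = FALSE]
  dRriF <- dZ[, k + seq_len(ncol(dZ) - k), drop = FALSE]
  nn_backward(model$rriLayer, dRriF)
  ## scatter the feature gradient back into the trunk's output shape
  dX <- switch(model$featMode,
    pooled = dFeat,
    bilstm_ends = {
      B <- nrow(dFeat)
      H <- ncol(dFeat) %/% 2L
      tmp <- array(0, c(B, model$seqLen, 2L * H))
      tmp[, model$seqLen, seq_len(H)] <- dFeat[, seq_len(H)]
      tmp[, 1L, H + seq_len(H)] <- dFeat[, H + seq_len(H)]
      tmp
    },
    last = {
      B <- nrow(dFeat)
      H <- ncol(dFeat)
      tmp <- array(0, c(B, model$seqLen, H))
      tmp[, model$seqLen, ] <- dFeat
      tmp
    }
  )
  nms <- names(model$trunk)
  i <- length(model$trunk)
  while (i >= 1L) {
    l <- model$trunk[[i]]
    if (l$type == "gap") {
      dX <- nn_backward(l, dX)
      model$gapInputGrad <- dX
      i <- i - 1L
    } else if (!is.null(nms) && nms[i] == "bwd" && i > 1L &&
      nms[i - 1L] == "fwd") {
      H <- dim(dX)[3L] %/% 2L
      dHf <- dX[, , seq_len(H), drop = FALSE]
      dHb <- dX[, , H + seq_len(H), drop = FALSE]
      dXb <- nn_backward(l, dHb)
      dXf <- nn_backward(model$trunk[[i - 1L]], dHf)
      dX <- dXf + dXb
      i <- i - 2L
    } else {
      dX <- nn_backward(l, dX)
      i <- i - 1L
    }
  }
  model$inputGrad <- dX # gradient at the (pooled) input, [B, T, 1]
  invisible(NULL)
}

#' Class probabilities for a batch of beats
#'
#' Runs the model in evaluation mode and applies a row-wise softmax.
#'
#' @param model a `canetModel`.
#' @param segments a [BeatSegmentSet-class], or a numeric matrix of windows
#'   (`L x n`) together with `rri`.
#' @param rri optional `n x 4` RRI feature matrix when `segments` is a bare
#'   matrix.
#' @return list with `probabilities` (`n x nClasses` matrix, rows sum to 1)
#'   and `labels` (argmax class, using the AAMI class order).
#' @export
predictProba <- function(model, segments, rri = NULL) {
  if (is(segments, "BeatSegmentSet")) {
    W <- t(beatWindows(segments))
    rri <- rriMatrix(segments)
  } else {
    W <- t(segments)
    if (is.null(rri)) rri <- matrix(0, nrow(W), 4L)
  }
  logits <- model_forward(model, W, rri, training = FALSE)
  P <- softmax_rows(logits)
  cls <- class_levels(model)
  colnames(P) <- cls
  list(probabilities = P, labels = cls[max.col(P, ties.method = "first")])
}

class_levels <- function(model) {
  if (!is.null(model$classes)) {
    model$classes
  } else if (model$config$nClasses == length(AAMI_CLASSES)) {
    AAMI_CLASSES
  } else {
    paste0("C", seq_len(model$config$nClasses))
  }
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Total trainable parameter count
#'
#' @param model a `canetModel`.
#' @return integer number of trainable scalars (batch-norm running
#'   statistics excluded).
#' @export
nParams <- function(model) {
  as.integer(nn_count_params(all_layers(model)))
}

#' Parameter ratio of depthwise-separable vs standard convolution
#'
#' For a kernel of width `K` mapping `cIn` channels to `cOut`, the
#' bias-free weight-count ratio is `(cIn K + cIn cOut) / (K cIn cOut)
#' = 1 / cOut + 1 / K`, the classic separable-convolution saving.
#'
#' @param cIn,cOut,K positive integers.
#' @return the ratio (a warning is emitted when `K = 1`, where the
#'   factorization saves nothing and the ratio exceeds 1).
#' @examples
#' depthwiseSeparableParamRatio(8, 16, 3) # 1/16 + 1/3
#' @export
depthwiseSeparableParamRatio <- function(cIn, cOut, K) {
  stopifnot(cIn >= 1, cOut >= 1, K >= 1)
  ratio <- (cIn * K + cIn * cOut) / (K * cIn * cOut)
  if (K == 1) {
    warning("K = 1: a 1-wide depthwise stage saves nothing (ratio = 1/cOut + 1 > 1)")
  }
  ratio
}

#' Attention weights of the last forward pass
#'
#' @param model a `canetModel` built with [buildCanet()], after at least one
#'   forward pass.
#' @return array `[batch, heads, steps, steps]`; each row of the last axis
#'   sums to 1.
#' @export
attentionWeights <- function(model) {
  for (l in model$trunk) {
    if (l$type == "attention") {
      return(l$attnWeights)
    }
  }
  stop("model has no attention layer")
}

#' Gradient-times-activation map for one beat
#'
#' Attributes the model's decision for one beat (its predicted class, or a
#' chosen class) to positions along the input window. Two attribution
#' points are available:
#'
#' * `"input"` (default) — integrated gradients at the (pooled) input: the
#'   class-logit gradient is averaged along the straight path from a zero
#'   baseline to the input and multiplied by the input (the path-integral
#'   refinement of gradient-times-activation, which a single-point gradient
#'   approximates). Because the gradient is traced back through the
#'   attention and BiLSTM stages, this localizes the evidence in the
#'   waveform itself, matching how heat maps over ECG beats are read
#'   (activation over the QRS, T wave, and so on), and it is deterministic.
#' * `"conv"` — gradient times activation at the last convolution block.
#'   In this architecture the recurrent and attention stages mix
#'   information across time steps *before* the convolutions, so this
#'   variant is close to uniform and mainly useful for inspecting the
#'   convolutional head itself.
#'
#' Either way the channel-summed product is rectified, linearly upsampled
#' to the window length and max-normalized to `[0, 1]`.
#'
#' @param model a `canetModel`.
#' @param window numeric vector: one beat window (length L).
#' @param rri numeric length-4 RRI feature vector (zeros if unknown).
#' @param classIndex class to explain (default: the predicted class).
#' @param method `"input"` or `"conv"` (see above).
#' @param igSteps number of midpoint steps of the path integral for
#'   `method = "input"` (1 degenerates to a plain gradient-times-input at
#'   half scale).
#' @return numeric vector of length `length(window)`, values in `[0, 1]`.
#' @export
computeActivationMap <- function(model, window, rri = rep(0, 4),
                                 classIndex = NULL,
                                 method = c("input", "conv"),
                                 igSteps = 16L) {
  method <- match.arg(method)
  R <- matrix(rri, nrow = 1L)
  W <- matrix(window, nrow = 1L)
  logits <- model_forward(model, W, R, training = FALSE)
  ci <- if (is.null(classIndex)) which.max(logits[1L, ]) else classIndex
  dLogits <- matrix(0, 1L, model$config$nClasses)
  dLogits[1L, ci] <- 1
  backward_at <- function(Win) {
    model_forward(model, Win, R, training = FALSE)
    zero_grads(all_layers(model))
    model_backward(model, dLogits)
  }
  imp <- if (method == "conv") {
    backward_at(W)
    gapIdx <- which(vapply(model$trunk, function(l) l$type == "gap", logical(1)))
    if (!length(gapIdx)) stop("model has no convolution/GAP stage")
    lastConv <- model$trunk[[gapIdx - 1L]]
    pmax(apply(model$gapInputGrad * lastConv$cache$Y, 2L, sum), 0)
  } else {
    ## integrated gradients: average the logit gradient along the path
    ## from the zero baseline to the input (midpoint rule), times input
    total <- 0
    for (k in seq_len(igSteps)) {
      backward_at(((k - 0.5) / igSteps) * W)
      total <- total + model$inputGrad[1L, , 1L]
    }
    act <- pool_input(W, model$config$inputPool)
    pmax(total / igSteps * act[1L, , 1L], 0)
  }
  L <- length(window)
  up <- stats::approx(seq_along(imp), imp, n = L)$y
  if (max(up) > 0) up <- up / max(up)
  up
}

#' Serialize a model to a checkpoint file
#'
#' Writes the architecture configuration as embedded JSON together with all
#' parameter arrays and batch-norm running statistics.
#'
#' @param model a `canetModel`.
#' @param path file to write.
#' @return invisibly, `path`.
#' @export
saveModel <- function(model, path) {
  layers <- all_layers(model)
  state <- list(
    kind = model$kind,
    classes = model$classes,
    configJson = jsonlite::toJSON(unclass(model$config), auto_unbox = TRUE),
    params = lapply(layers, function(l) l$params),
    bn = lapply(layers, function(l) {
      if (l$type == "conv_block") list(runMean = l$runMean, runVar = l$runVar)
    })
  )
  saveRDS(state, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path file written by [saveModel()].
#' @return a `canetModel`.
#' @export
loadModel <- function(path) {
  state <- readRDS(path)
  cfgList <- jsonlite::fromJSON(state$configJson)
  cfgList$dsConvBlocks <- lapply(
    seq_len(nrow(cfgList$dsConvBlocks)),
    function(i) as.integer(cfgList$dsConvBlocks[i, ])
  )
  cfg <- do.call(modelConfig, cfgList)
  model <- new_model(state$kind, cfg, seed = 1L)
  model$classes <- state$classes
  layers <- all_layers(model)
  for (i in seq_along(layers)) {
    layers[[i]]$params <- state$params[[i]]
    if (!is.null(state$bn[[i]])) {
      layers[[i]]$runMean <- state$bn[[i]]$runMean
      layers[[i]]$runVar <- state$bn[[i]]$runVar
    }
  }
  model
}

#' @export
print.canetModel <- function(x, ...) {
  cat(
    "<canetModel '", x$kind, "': ", nParams(x), " trainable parameters, ",
    x$config$nClasses, " classes>\n",
    sep = ""
  )
  invisible(x)
}
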