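## Internal neural-network engine.
##
## Layers are environments holding `params`, `grads`, optimizer state and a
## forward cache; `nn_forward()` / `nn_backward()` dispatch on `$type`.
## Everything is double precision, vectorized over the batch; gradients are
## derived analytically and verified against central finite differences in
## the test suite.

sigm <- function(x) 1 / (1 + exp(-x))

## Glorot-uniform initialisation, deterministic given the RNG state
glorot <- function(fanIn, fanOut, dims = c(fanIn, fanOut)) {
  lim <- sqrt(6 / (fanIn + fanOut))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

new_layer <- function(type, params, extra = list()) {
  l <- new.env(parent = emptyenv())
  l$type <- type
  l$params <- params
  l$grads <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  l$cache <- NULL
  for (nm in names(extra)) assign(nm, extra[[nm]], envir = l)
  l
}

`%||%` <- function(a, b) if (is.null(a)) b else a

zero_grads <- function(layers) {
  for (l in layers) {
    for (nm in names(l$grads)) l$grads[[nm]][] <- 0
  }
  invisible(NULL)
}

## ---- constructors ------------------------------------------------------

layer_dense <- function(inDim, outDim, activation = "linear") {
  new_layer("dense",
    params = list(W = glorot(inDim, outDim), b = numeric(outDim)),
    extra = list(activation = activation)
  )
}

layer_dropout <- function(p) {
  new_layer("dropout", params = list(), extra = list(p = p))
}

layer_lstm <- function(inDim, hidden, reverse = FALSE) {
  b <- numeric(4L * hidden)
  b[hidden + seq_len(hidden)] <- 1 # forget-gate bias: retain memory early on
  new_layer("lstm",
    params = list(
      Wx = glorot(inDim, 4L * hidden, c(inDim, 4L * hidden)),
      Wh = glorot(hidden, 4L * hidden, c(hidden, 4L * hidden)),
      b = b
    ),
    extra = list(H = hidden, reverse = reverse)
  )
}

layer_gru <- function(inDim, hidden, reverse = FALSE) {
  new_layer("gru",
    params = list(
      Wx = glorot(inDim, 3L * hidden, c(inDim, 3L * hidden)),
      Wh = glorot(hidden, 3L * hidden, c(hidden, 3L * hidden)),
      bx = numeric(3L * hidden),
      bh = numeric(3L * hidden)
    ),
    extra = list(H = hidden, reverse = reverse)
  )
}

layer_rnn <- function(inDim, hidden, reverse = FALSE) {
  new_layer("rnn",
    params = list(
      Wx = glorot(inDim, hidden), Wh = glorot(hidden, hidden),
      b = numeric(hidden)
    ),
    extra = list(H = hidden, reverse = reverse)
  )
}

layer_attention <- function(dModel, nHeads) {
  stopifnot(dModel %% nHeads == 0L)
  new_layer("attention",
    params = list(
      Wq = glorot(dModel, dModel), Wk = glorot(dModel, dModel),
      Wv = glorot(dModel, dModel), Wo = glorot(dModel, dModel),
      gamma = rep(1, dModel), beta = numeric(dModel)
    ),
    extra = list(D = dModel, nHeads = nHeads, attnWeights = NULL)
  )
}

## depthwise-separable (or standard) 1-D conv block:
## conv -> batchnorm -> ReLU -> maxpool(2)
layer_conv_block <- function(cIn, cOut, K, separable = TRUE) {
  params <- if (separable) {
    list(
      Wd = glorot(K, cIn, c(K, cIn)) / sqrt(cIn), bd = numeric(cIn),
      Wp = glorot(cIn, cOut), bp = numeric(cOut),
      gamma = rep(1, cOut), beta = numeric(cOut)
    )
  } else {
    list(
      W = glorot(K * cIn, cOut, c(K, cIn, cOut)), b = numeric(cOut),
      gamma = rep(1, cOut), beta = numeric(cOut)
    )
  }
  new_layer("conv_block",
    params = params,
    extra = list(
      K = K, cIn = cIn, cOut = cOut, separable = separable,
      runMean = numeric(cOut), runVar = rep(1, cOut), bnMomentum = 0.1,
      eps = 1e-5
    )
  )
}

layer_gap <- function() new_layer("gap", params = list())

## ---- forward -----------------------------------------------------------

## broadcast a channel vector over an array [B, T, C]
bcast_ch <- function(w, B, T) rep(w, each = B * T)

pad_time <- function(X, pad) {
  d <- dim(X)
  Xp <- array(0, c(d[1L], d[2L] + 2L * pad, d[3L]))
  Xp[, pad + seq_len(d[2L]), ] <- X
  Xp
}

nn_forward <- function(l, X, training = FALSE) {
  switch(l$type,
    dense = {
      Z <- X %*% l$params$W +
        matrix(l$params$b, nrow(X), length(l$params$b), byrow = TRUE)
      Y <- if (l$activation == "relu") pmax(Z, 0) else Z
      l$cache <- list(X = X, Z = Z)
      Y
    },
    dropout = {
      if (training && l$p > 0) {
        mask <- (matrix(stats::runif(length(X)), nrow(X)) >= l$p) / (1 - l$p)
        l$cache <- list(mask = mask)
        X * mask
      } else {
        l$cache <- list(mask = NULL)
        X
      }
    },
    lstm = forward_lstm(l, X),
    gru = forward_gru(l, X),
    rnn = forward_rnn(l, X),
    attention = forward_attention(l, X),
    conv_block = forward_conv_block(l, X, training),
    gap = {
      d <- dim(X)
      l$cache <- list(T = d[2L])
      ## mean over time: reshape [B, T*C] and multiply by a block
      ## averaging matrix (much faster than apply)
      X2 <- X
      dim(X2) <- c(d[1L], d[2L] * d[3L])
      M <- kronecker(diag(d[3L]), matrix(1 / d[2L], d[2L], 1L))
      X2 %*% M
    },
    stop("unknown layer type ", l$type)
  )
}

forward_lstm <- function(l, X) {
  d <- dim(X)
  B <- d[1L]
  T <- d[2L]
  H <- l$H
  ts <- if (l$reverse) rev(seq_len(T)) else seq_len(T)
  h <- matrix(0, B, H)
  cc <- matrix(0, B, H)
  Hout <- array(0, c(B, T, H))
  G <- array(0, c(B, T, 4L * H)) # activated gates i,f,g,o
  Cs <- array(0, c(B, T, H))
  bMat <- matrix(l$params$b, B, 4L * H, byrow = TRUE)
  for (t in ts) {
    Z <- X[, t, , drop = FALSE]
    dim(Z) <- c(B, d[3L])
    Z <- Z %*% l$params$Wx + h %*% l$params$Wh + bMat
    i <- sigm(Z[, 1:H, drop = FALSE])
    f <- sigm(Z[, H + 1:H, drop = FALSE])
    g <- tanh(Z[, 2 * H + 1:H, drop = FALSE])
    o <- sigm(Z[, 3 * H + 1:H, drop = FALSE])
    cc <- f * cc + i * g
    h <- o * tanh(cc)
    Hout[, t, ] <- h
    G[, t, ] <- cbind(i, f, g, o)
    Cs[, t, ] <- cc
  }
  l$cache <- list(X = X, G = G, Cs = Cs, Hout = Hout, ts = ts)
  Hout
}

forward_gru <- function(l, X) {
  d <- dim(X)
  B <- d[1L]
  T <- d[2L]
  H <- l$H
  ts <- if (l$reverse) rev(seq_len(T)) else seq_len(T)
  h <- matrix(0, B, H)
  Hout <- array(0, c(B, T, H))
  G <- array(0, c(B, T, 3L * H)) # z, r, n (activated)
  Ss <- array(0, c(B, T, H)) # s = h_prev Whn + bhn
  bx <- matrix(l$params$bx, B, 3L * H, byrow = TRUE)
  bh <- matrix(l$params$bh, B, 3L * H, byrow = TRUE)
  for (t in ts) {
    Xt <- X[, t, , drop = FALSE]
    dim(Xt) <- c(B, d[3L])
    Ax <- Xt %*% l$params$Wx + bx
    Ah <- h %*% l$params$Wh + bh
    z <- sigm(Ax[, 1:H, drop = FALSE] + Ah[, 1:H, drop = FALSE])
    r <- sigm(Ax[, H + 1:H, drop = FALSE] + Ah[, H + 1:H, drop = FALSE])
    s <- Ah[, 2 * H + 1:H, drop = FALSE]
    nn <- tanh(Ax[, 2 * H + 1:H, drop = FALSE] + r * s)
    hPrev <- h
    h <- (1 - z) * nn + z * hPrev
    Hout[, t, ] <- h
    G[, t, ] <- cbind(z, r, nn)
    Ss[, t, ] <- s
  }
  l$cache <- list(X = X, G = G, Ss = Ss, Hout = Hout, ts = ts)
  Hout
}

forward_rnn <- function(l, X) {
  d <- dim(X)
  B <- d[1L]
  T <- d[2L]
  H <- l$H
  ts <- if (l$reverse) rev(seq_len(T)) else seq_len(T)
  h <- matrix(0, B, H)
  Hout <- array(0, c(B, T, H))
  bMat <- matrix(l$params$b, B, H, byrow = TRUE)
  for (t in ts) {
    Xt <- X[, t, , drop = FALSE]
    dim(Xt) <- c(B, d[3L])
    h <- tanh(Xt %*% l$params$Wx + h %*% l$params$Wh + bMat)
    Hout[, t, ] <- h
  }
  l$cache <- list(X = X, Hout = Hout, ts = ts)
  Hout
}

forward_attention <- function(l, X) {
  d <- dim(X)
  B <- d[1L]
  T <- d[2L]
  D <- l$D
  nH <- l$nHeads
  dh <- D %/% nH
  X2 <- matrix(X, B * T, D) # (b,t) rows, column-major over b then t
  Q <- X2 %*% l$params$Wq
  K <- X2 %*% l$params$Wk
  V <- X2 %*% l$params$Wv
  O <- matrix(0, B * T, D)
  A <- array(0, c(B, nH, T, T))
  rowOf <- function(b) b + B * (seq_len(T) - 1L) # rows of sample b
  for (b in seq_len(B)) {
    rows <- rowOf(b)
    for (hh in seq_len(nH)) {
      cols <- (hh - 1L) * dh + seq_len(dh)
      Qh <- Q[rows, cols, drop = FALSE]
      Kh <- K[rows, cols, drop = FALSE]
      Vh <- V[rows, cols, drop = FALSE]
      S <- Qh %*% t(Kh) / sqrt(dh)
      S <- exp(S - apply(S, 1L, max))
      Ah <- S / rowSums(S)
      A[b, hh, , ] <- Ah
      O[rows, cols] <- Ah %*% Vh
    }
  }
  P <- O %*% l$params$Wo
  R <- X2 + P # residual
  ## layer norm over features, per (b, t) row
  mu <- rowMeans(R)
  v <- rowMeans((R - mu)^2)
  xhat <- (R - mu) / sqrt(v + 1e-5)
  Y2 <- xhat * matrix(l$params$gamma, B * T, D, byrow = TRUE) +
    matrix(l$params$beta, B * T, D, byrow = TRUE)
  l$attnWeights <- A
  l$cache <- list(
    X2 = X2, Q = Q, K = K, V = V, O = O, A = A, xhat = xhat, v = v,
    B = B, T = T
  )
  Y <- Y2
  dim(Y) <- c(B, T, D)
  Y
}

forward_conv_block <- function(l, X, training) {
  d <- dim(X)
  B <- d[1L]
  T <- d[2L]
  K <- l$K
  pad <- (K - 1L) %/% 2L
  Xp <- pad_time(X, pad)
  if (l$separable) {
    ## depthwise
    Dw <- array(0, c(B, T, l$cIn))
    for (k in seq_len(K)) {
      Dw <- Dw + Xp[, k + seq_len(T) - 1L, , drop = FALSE] *
        bcast_ch(l$params$Wd[k, ], B, T)
    }
    Dw <- Dw + bcast_ch(l$params$bd, B, T)
    ## pointwise
    Dw2 <- matrix(Dw, B * T, l$cIn)
    C2 <- Dw2 %*% l$params$Wp +
      matrix(l$params$bp, B * T, l$cOut, byrow = TRUE)
  } else {
    C2 <- matrix(0, B * T, l$cOut)
    for (k in seq_len(K)) {
      Xk <- Xp[, k + seq_len(T) - 1L, , drop = FALSE]
      dim(Xk) <- c(B * T, l$cIn)
      C2 <- C2 + Xk %*% matrix(l$params$W[k, , ], l$cIn, l$cOut)
    }
    C2 <- C2 + matrix(l$params$b, B * T, l$cOut, byrow = TRUE)
    Dw <- NULL
  }
  ## batch norm over (B, T) per output channel
  if (training) {
    mu <- colMeans(C2)
    v <- colMeans(C2^2) - mu^2
    l$runMean <- (1 - l$bnMomentum) * l$runMean + l$bnMomentum * mu
    l$runVar <- (1 - l$bnMomentum) * l$runVar + l$bnMomentum * v
  } else {
    mu <- l$runMean
    v <- l$runVar
  }
  xhat <- (C2 - matrix(mu, B * T, l$cOut, byrow = TRUE)) /
    matrix(sqrt(v + l$eps), B * T, l$cOut, byrow = TRUE)
  Bn <- xhat * matrix(l$params$gamma, B * T, l$cOut, byrow = TRUE) +
    matrix(l$params$beta, B * T, l$cOut, byrow = TRUE)
  ## ReLU
  Rl <- pmax(Bn, 0)
  Ra <- array(Rl, c(B, T, l$cOut))
  ## max pool width 2, stride 2
  T2 <- T %/% 2L
  a <- Ra[, 2L * seq_len(T2) - 1L, , drop = FALSE]
  b2 <- Ra[, 2L * seq_len(T2), , drop = FALSE]
  Y <- pmax(a, b2)
  l$cache <- list(
    Xp = Xp, Dw = Dw, xhat = xhat, v = v, relumask = Bn > 0,
    poolmask = a >= b2, B = B, T = T, T2 = T2, training = training,
    Y = Y
  )
  Y
}

## ---- backward ----------------------------------------------------------

nn_backward <- function(l, dY) {
  switch(l$type,
    dense = {
      dZ <- if (l$activation == "relu") dY * (l$cache$Z > 0) else dY
      l$grads$W <- l$grads$W + crossprod(l$cache$X, dZ)
      l$grads$b <- l$grads$b + colSums(dZ)
      dZ %*% t(l$params$W)
    },
    dropout = {
      if (is.null(l$cache$mask)) dY else dY * l$cache$mask
    },
    lstm = backward_lstm(l, dY),
    gru = backward_gru(l, dY),
    rnn = backward_rnn(l, dY),
    attention = backward_attention(l, dY),
    conv_block = backward_conv_block(l, dY),
    gap = {
      B <- nrow(dY)
      C <- ncol(dY)
      T <- l$cache$T
      dX <- array(0, c(B, T, C))
      for (t in seq_len(T)) dX[, t, ] <- dY / T
      dX
    },
    stop("unknown layer type ", l$type)
  )
}

backward_lstm <- function(l, dH) {
  cache <- l$cache
  X <- cache$X
  d <- dim(X)
  B <- d[1L]
  T <- d[2L]
  Din <- d[3L]
  H <- l$H
  ts <- cache$ts
  dX <- array(0, dim(X))
  dhNext <- matrix(0, B, H)
  dcNext <- matrix(0, B, H)
  dWx <- l$grads$Wx
  dWh <- l$grads$Wh
  db <- l$grads$b
  for (k in rev(seq_along(ts))) {
    t <- ts[k]
    tPrev <- if (k > 1L) ts[k - 1L] else NA_integer_
    i <- cache$G[, t, 1:H, drop = FALSE]
    dim(i) <- c(B, H)
    f <- cache$G[, t, H + 1:H, drop = FALSE]
    dim(f) <- c(B, H)
    g <- cache$G[, t, 2 * H + 1:H, drop = FALSE]
    dim(g) <- c(B, H)
    o <- cache$G[, t, 3 * H + 1:H, drop = FALSE]
    dim(o) <- c(B, H)
    cc <- cache$Cs[, t, , drop = FALSE]
    dim(cc) <- c(B, H)
    cPrev <- if (is.na(tPrev)) matrix(0, B, H) else {
      tmp <- cache$Cs[, tPrev, , drop = FALSE]
      dim(tmp) <- c(B, H)
      tmp
    }
    hPrev <- if (is.na(tPrev)) matrix(0, B, H) else {
      tmp <- cache$Hout[, tPrev, , drop = FALSE]
      dim(tmp) <- c(B, H)
      tmp
    }
    dh <- dH[, t, , drop = FALSE]
    dim(dh) <- c(B, H)
    dh <- dh + dhNext
    tc <- tanh(cc)
    do <- dh * tc
    dc <- dcNext + dh * o * (1 - tc^2)
    di <- dc * g
    dg <- dc * i
    df <- dc * cPrev
    dZ <- cbind(
      di * i * (1 - i), df * f * (1 - f),
      dg * (1 - g^2), do * o * (1 - o)
    )
    Xt <- X[, t, , drop = FALSE]
    dim(Xt) <- c(B, Din)
    dWx <- dWx + crossprod(Xt, dZ)
    dWh <- dWh + crossprod(hPrev, dZ)
    db <- db + colSums(dZ)
    dX[, t, ] <- dZ %*% t(l$params$Wx)
    dhNext <- dZ %*% t(l$params$Wh)
    dcNext <- dc * f
  }
  l$grads$Wx <- dWx
  l$grads$Wh <- dWh
  l$grads$b <- db
  dX
}

backward_gru <- function(l, dH) {
  cache <- l$cache
  X <- cache$X
  d <- dim(X)
  B <- d[1L]
  T <- d[2L]
  Din <- d[3L]
  H <- l$H
  ts <- cache$ts
  dX <- array(0, dim(X))
  dhNext <- matrix(0, B, H)
  dWx <- l$grads$Wx
  dWh <- l$grads$Wh
  dbx <- l$grads$bx
  dbh <- l$grads$bh
  for (k in rev(seq_along(ts))) {
    t <- ts[k]
    tPrev <- if (k > 1L) ts[k - 1L] else NA_integer_
    z <- cache$G[, t, 1:H, drop = FALSE]
    dim(z) <- c(B, H)
    r <- cache$G[, t, H + 1:H, drop = FALSE]
    dim(r) <- c(B, H)
    nn <- cache$G[, t, 2 * H + 1:H, drop = FALSE]
    dim(nn) <- c(B, H)
    s <- cache$Ss[, t, , drop = FALSE]
    dim(s) <- c(B, H)
    hPrev <- if (is.na(tPrev)) matrix(0, B, H) else {
      tmp <- cache$Hout[, tPrev, , drop = FALSE]
      dim(tmp) <- c(B, H)
      tmp
    }
    dh <- dH[, t, , drop = FALSE]
    dim(dh) <- c(B, H)
    dh <- dh + dhNext
    dn <- dh * (1 - z)
    dz <- dh * (hPrev - nn)
    dhPrev <- dh * z
    dpreN <- dn * (1 - nn^2)
    dr <- dpreN * s
    ds <- dpreN * r
    dpreZ <- dz * z * (1 - z)
    dpreR <- dr * r * (1 - r)
    dAx <- cbind(dpreZ, dpreR, dpreN)
    dAh <- cbind(dpreZ, dpreR, ds)
    Xt <- X[, t, , drop = FALSE]
    dim(Xt) <- c(B, Din)
    dWx <- dWx + crossprod(Xt, dAx)
    dWh <- dWh + crossprod(hPrev, dAh)
    dbx <- dbx + colSums(dAx)
    dbh <- dbh + colSums(dAh)
    dX[, t, ] <- dAx %*% t(l$params$Wx)
    dhNext <- dhPrev + dAh %*% t(l$params$Wh)
  }
  l$grads$Wx <- dWx
  l$grads$Wh <- dWh
  l$grads$bx <- dbx
  l$grads$bh <- dbh
  dX
}

backward_rnn <- function(l, dH) {
  cache <- l$cache
  X <- cache$X
  d <- dim(X)
  B <- d[1L]
  Din <- d[3L]
  H <- l$H
  ts <- cache$ts
  dX <- array(0, dim(X))
  dhNext <- matrix(0, B, H)
  for (k in rev(seq_along(ts))) {
    t <- ts[k]
    tPrev <- if (k > 1L) ts[k - 1L] else NA_integer_
    h <- cache$Hout[, t, , drop = FALSE]
    dim(h) <- c(B, H)
    hPrev <- if (is.na(tPrev)) matrix(0, B, H) else {
      tmp <- cache$Hout[, tPrev, , drop = FALSE]
      dim(tmp) <- c(B, H)
      tmp
    }
    dh <- dH[, t, , drop = FALSE]
    dim(dh) <- c(B, H)
    dh <- dh + dhNext
    dZ <- dh * (1 - h^2)
    Xt <- X[, t, , drop = FALSE]
    dim(Xt) <- c(B, Din)
    l$grads$Wx <- l$grads$Wx + crossprod(Xt, dZ)
    l$grads$Wh <- l$grads$Wh + crossprod(hPrev, dZ)
    l$grads$b <- l$grads$b + colSums(dZ)
    dX[, t, ] <- dZ %*% t(l$params$Wx)
    dhNext <- dZ %*% t(l$params$Wh)
  }
  dX
}

backward_attention <- function(l, dY) {
  cache <- l$cache
  B <- cache$B
  T <- cache$T
  D <- l$D
  nH <- l$nHeads
  dh <- D %/% nH
  dY2 <- matrix(dY, B * T, D)
  ## layer norm backward (biased variance, per row)
  xhat <- cache$xhat
  g <- l$params$gamma
  l$grads$gamma <- l$grads$gamma + colSums(dY2 * xhat)
  l$grads$beta <- l$grads$beta + colSums(dY2)
  dxhat <- dY2 * matrix(g, B * T, D, byrow = TRUE)
  inv <- 1 / sqrt(cache$v + 1e-5)
  dR <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  ## residual
  dX2 <- dR
  dP <- dR
  l$grads$Wo <- l$grads$Wo + crossprod(cache$O, dP)
  dO <- dP %*% t(l$params$Wo)
  dQ <- matrix(0, B * T, D)
  dK <- matrix(0, B * T, D)
  dV <- matrix(0, B * T, D)
  for (b in seq_len(B)) {
    rows <- b + B * (seq_len(T) - 1L)
    for (hh in seq_len(nH)) {
      cols <- (hh - 1L) * dh + seq_len(dh)
      Ah <- matrix(cache$A[b, hh, , ], T, T)
      Vh <- cache$V[rows, cols, drop = FALSE]
      Qh <- cache$Q[rows, cols, drop = FALSE]
      Kh <- cache$K[rows, cols, drop = FALSE]
      dOh <- dO[rows, cols, drop = FALSE]
      dAh <- dOh %*% t(Vh)
      dV[rows, cols] <- t(Ah) %*% dOh
      dS <- Ah * (dAh - rowSums(dAh * Ah)) / sqrt(dh)
      dQ[rows, cols] <- dS %*% Kh
      dK[rows, cols] <- t(dS) %*% Qh
    }
  }
  X2 <- cache$X2
  l$grads$Wq <- l$grads$Wq + crossprod(X2, dQ)
  l$grads$Wk <- l$grads$Wk + crossprod(X2, dK)
  l$grads$Wv <- l$grads$Wv + crossprod(X2, dV)
  dX2 <- dX2 + dQ %*% t(l$params$Wq) + dK %*% t(l$params$Wk) +
    dV %*% t(l$params$Wv)
  dX <- dX2
  dim(dX) <- c(B, T, D)
  dX
}

backward_conv_block <- function(l, dY) {
  cache <- l$cache
  B <- cache$B
  T <- cache$T
  T2 <- cache$T2
  K <- l$K
  pad <- (K - 1L) %/% 2L
  cOut <- l$cOut
  cIn <- l$cIn
  ## max pool backward
  dR <- array(0, c(B, T, cOut))
  dR[, 2L * seq_len(T2) - 1L, ] <- dY * cache$poolmask
  dR[, 2L * seq_len(T2), ] <- dY * !cache$poolmask
  ## ReLU backward
  dBn <- matrix(dR, B * T, cOut) * cache$relumask
  ## batch norm backward
  xhat <- cache$xhat
  l$grads$gamma <- l$grads$gamma + colSums(dBn * xhat)
  l$grads$beta <- l$grads$beta + colSums(dBn)
  dxhat <- dBn * matrix(l$params$gamma, B * T, cOut, byrow = TRUE)
  inv <- matrix(1 / sqrt(cache$v + l$eps), B * T, cOut, byrow = TRUE)
  if (cache$training) {
    m1 <- matrix(colMeans(dxhat), B * T, cOut, byrow = TRUE)
    m2 <- matrix(colMeans(dxhat * xhat), B * T, cOut, byrow = TRUE)
    dC2 <- inv * (dxhat - m1 - xhat * m2)
  } else {
    dC2 <- inv * dxhat # eval mode: mu, var are constants
  }
  if (l$separable) {
    ## pointwise backward
    Dw2 <- matrix(cache$Dw, B * T, cIn)
    l$grads$Wp <- l$grads$Wp + crossprod(Dw2, dC2)
    l$grads$bp <- l$grads$bp + colSums(dC2)
    dDw2 <- dC2 %*% t(l$params$Wp)
    dDw <- array(dDw2, c(B, T, cIn))
    ## depthwise backward
    l$grads$bd <- l$grads$bd + colSums(matrix(dDw, B * T, cIn))
    dXp <- array(0, dim(cache$Xp))
    for (k in seq_len(K)) {
      sl <- k + seq_len(T) - 1L
      Xk <- cache$Xp[, sl, , drop = FALSE]
      l$grads$Wd[k, ] <- l$grads$Wd[k, ] +
        colSums(matrix(dDw * Xk, B * T, cIn))
      dXp[, sl, ] <- dXp[, sl, , drop = FALSE] +
        dDw * bcast_ch(l$params$Wd[k, ], B, T)
    }
  } else {
    l$grads$b <- l$grads$b + colSums(dC2)
    dXp <- array(0, dim(cache$Xp))
    for (k in seq_len(K)) {
      sl <- k + seq_len(T) - 1L
      Xk <- cache$Xp[, sl, , drop = FALSE]
      dim(Xk) <- c(B * T, cIn)
      l$grads$W[k, , ] <- matrix(l$grads$W[k, , ], cIn, cOut) +
        crossprod(Xk, dC2)
      dXk <- dC2 %*% t(matrix(l$params$W[k, , ], cIn, cOut))
      dXp[, sl, ] <- dXp[, sl, , drop = FALSE] + array(dXk, c(B, T, cIn))
    }
  }
  dXp[, pad + seq_len(T), , drop = FALSE]
}

## ---- optimizer ---------------------------------------------------------

adam_init <- function(layers) {
  for (l in layers) {
    l$opt <- list(
      m = lapply(l$params, function(p) array(0, dim(p) %||% length(p))),
      v = lapply(l$params, function(p) array(0, dim(p) %||% length(p)))
    )
  }
  invisible(NULL)
}

## global gradient-norm clipping followed by one Adam step
adam_step <- function(layers, lr, step, clipNorm = NULL,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (!is.null(clipNorm) && is.finite(clipNorm)) {
    total <- 0
    for (l in layers) for (g in l$grads) total <- total + sum(g^2)
    total <- sqrt(total)
    if (total > clipNorm) {
      sc <- clipNorm / total
      for (l in layers) for (nm in names(l$grads)) {
        l$grads[[nm]] <- l$grads[[nm]] * sc
      }
    }
  }
  bc1 <- 1 - beta1^step
  bc2 <- 1 - beta2^step
  for (l in layers) {
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      l$opt$m[[nm]] <- beta1 * l$opt$m[[nm]] + (1 - beta1) * g
      l$opt$v[[nm]] <- beta2 * l$opt$v[[nm]] + (1 - beta2) * g^2
      mhat <- l$opt$m[[nm]] / bc1
      vhat <- l$opt$v[[nm]] / bc2
      l$params[[nm]] <- l$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  invisible(NULL)
}

## ---- parameter plumbing (used by tests for finite differences) ---------

nn_get_params <- function(layers) {
  unlist(lapply(layers, function(l) lapply(l$params, as.vector)))
}

nn_set_params <- function(layers, theta) {
  pos <- 0L
  for (l in layers) {
    for (nm in names(l$params)) {
      n <- length(l$params[[nm]])
      v <- theta[pos + seq_len(n)]
      dim(v) <- dim(l$params[[nm]])
      l$params[[nm]] <- v
      pos <- pos + n
    }
  }
  invisible(NULL)
}

nn_get_grads <- function(layers) {
  unlist(lapply(layers, function(l) lapply(l$grads, as.vector)))
}

nn_count_params <- function(layers) {
  sum(vapply(layers, function(l) {
    sum(vapply(l$params, length, integer(1)))
  }, numeric(1)))
}
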