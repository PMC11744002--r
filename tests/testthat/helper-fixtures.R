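## shared fixtures, built in code at test time

## a short clean normal-rhythm record with ground truth
fixture_record <- function(seed = 3L, duration = 30, bpm = 75, ...) {
  generateRecord(rhythmSpec(
    meanBpm = bpm, duration = duration,
    seed = seed, ...
  ))
}

## small labelled beat sets for classifier tests
fixture_beats <- function(nPerClass, classes = c("N", "S", "V", "F", "Q"),
                          seed = 1L, snrDb = 20) {
  synthBeatSet(nPerClass, classes = classes, snrDb = snrDb, seed = seed)
}

## finite-difference gradient check for a model on a small batch;
## returns the maximum relative error over all parameters
gradcheck_model <- function(model, B = 4L, L = 20L, h = 1e-5, seed = 42L) {
  set.seed(seed)
  W <- matrix(rnorm(B * L), B, L)
  R <- cbind(matrix(800 + 100 * rnorm(B * 3), B, 3), 1 + 0.2 * rnorm(B))
  y <- sample.int(model$config$nClasses, B, replace = TRUE)
  layers <- canet:::all_layers(model)
  lossAt <- function(theta) {
    canet:::nn_set_params(layers, theta)
    logits <- canet:::model_forward(model, W, R, training = TRUE)
    canet:::xent(logits, y)$loss
  }
  theta0 <- canet:::nn_get_params(layers)
  canet:::zero_grads(layers)
  logits <- canet:::model_forward(model, W, R, training = TRUE)
  ce <- canet:::xent(logits, y)
  canet:::model_backward(model, ce$dLogits)
  g <- canet:::nn_get_grads(layers)
  num <- vapply(seq_along(theta0), function(i) {
    tp <- theta0
    tp[i] <- tp[i] + h
    lp <- lossAt(tp)
    tp[i] <- theta0[i] - h
    lm <- lossAt(tp)
    (lp - lm) / (2 * h)
  }, numeric(1))
  canet:::nn_set_params(layers, theta0)
  max(abs(num - g) / pmax(abs(num) + abs(g), 1e-6))
}
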