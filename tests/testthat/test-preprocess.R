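test_that("Mallat pyramid reconstructs the input exactly", {
  set.seed(1)
  for (wav in c("haar", "db2", "db4", "db8", "sym4")) {
    for (n in c(64, 100, 137, 1024)) {
      x <- rnorm(n)
      lev <- min(4L, floor(log2(n)))
      p <- dwtDecompose(x, waveletConfig(
        waveletName = wav, nLevels = lev,
        zeroApproximation = FALSE, zeroDetailLevels = integer(0)
      ))
      expect_length(p$details, lev)
      r <- dwtReconstruct(p)
      expect_lt(max(abs(r - x)), 1e-8 * max(abs(x)))
    }
  }
})

test_that("a constant signal lives entirely in the approximation band", {
  p <- dwtDecompose(rep(3.7, 256), waveletConfig(
    waveletName = "db4",
    nLevels = 4, zeroApproximation = FALSE, zeroDetailLevels = integer(0)
  ))
  for (d in p$details) expect_lt(max(abs(d)), 1e-10)
  expect_gt(max(abs(p$approximation)), 1)
})

test_that("orthogonal filter banks conserve impulse energy", {
  ## oracle: direct energy summation of the input
  x <- numeric(128)
  x[64] <- 1
  p <- dwtDecompose(x, waveletConfig(
    waveletName = "db4", nLevels = 3,
    zeroApproximation = FALSE, zeroDetailLevels = integer(0)
  ))
  bandEnergy <- sum(p$approximation^2) + sum(vapply(p$details, function(d) sum(d^2), 1))
  ## symmetric extension duplicates boundary content, so energy matches
  ## only for interior-supported signals like this centered impulse
  expect_lt(abs(bandEnergy - sum(x^2)), 1e-8)
})

test_that("decomposition depth is limited by the signal length", {
  expect_error(
    dwtDecompose(rnorm(100), waveletConfig(nLevels = 9)),
    "at most"
  )
})

test_that("baseline drift is strongly attenuated", {
  fs <- 360
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  drift <- sin(2 * pi * 0.3 * t) # 1 mV drift, inside the kill band
  den <- waveletDenoise(drift, fs)
  expect_lt(sqrt(mean(den^2)) / sqrt(mean(drift^2)), 0.1) # >= 20 dB
})

test_that("denoising improves the SNR of noisy beats", {
  ## hard thresholding preserves the sharp QRS coefficients; SNR is taken
  ## against the demeaned clean reference because removing the baseline
  ## band removes the DC offset by design
  fs <- 360
  cfg <- waveletConfig(softThresholdK = 0.7, thresholdType = "hard")
  improvements <- vapply(1:10, function(s) {
    gen <- generateRecord(rhythmSpec(
      meanBpm = 75, duration = 10,
      whiteSnrDb = 10, seed = s
    ))
    x <- channelSignal(gen$record)
    den <- waveletDenoise(x, fs, cfg)
    dm <- function(v) v - mean(v)
    snr <- function(sig) {
      10 * log10(mean(dm(gen$clean)^2) / mean((dm(sig) - dm(gen$clean))^2))
    }
    snr(den) - snr(x)
  }, numeric(1))
  expect_gt(mean(improvements), 3)
})

test_that("clean beats keep their R amplitude through denoising", {
  fs <- 360
  gen <- fixture_record(seed = 21, duration = 10)
  x <- channelSignal(gen$record)
  den <- waveletDenoise(x, fs)
  rIdx <- gen$annotations$sampleIndex + 1L
  ## amplitude relative to the inter-beat baseline (the median), since
  ## removing the approximation band removes the DC offset by design
  ampIn <- mean(x[rIdx]) - median(x)
  ampOut <- mean(den[rIdx]) - median(den)
  expect_lt(abs(ampOut - ampIn) / ampIn, 0.1)
})

test_that("denoising is stable under re-application", {
  fs <- 360
  gen <- fixture_record(seed = 22, duration = 10)
  d1 <- waveletDenoise(channelSignal(gen$record), fs)
  d2 <- waveletDenoise(d1, fs)
  ## the band structure is already clean: only soft-threshold shrinkage of
  ## small retained coefficients remains
  expect_lt(
    sqrt(mean((d2 - d1)^2)),
    0.05 * sqrt(mean(d1^2))
  )
})

test_that("gaussian smoothing keeps constants and matches its impulse response", {
  fs <- 360
  expect_equal(
    gaussianSmooth(rep(2.5, 200), fs),
    rep(2.5, 200),
    tolerance = 1e-12
  )
  ## unit impulse -> sampled gaussian kernel
  sigma <- 5 / fs # 5 samples
  n <- 201
  x <- numeric(n)
  x[101] <- 1
  y <- gaussianSmooth(x, fs, gaussianConfig(sigmaSeconds = sigma))
  half <- ceiling(4 * 5)
  k <- exp(-((-half):half)^2 / (2 * 25))
  k <- k / sum(k)
  expect_lt(max(abs(y[101 + (-half:half)] - k)), 1e-6)
})

test_that("gaussian smoothing contracts variance and is linear", {
  fs <- 360
  set.seed(4)
  x <- rnorm(500)
  y <- rnorm(500)
  cfg <- gaussianConfig(sigmaSeconds = 3 / fs)
  expect_lt(var(gaussianSmooth(x, fs, cfg)), var(x))
  lhs <- gaussianSmooth(2 * x - 3 * y, fs, cfg)
  rhs <- 2 * gaussianSmooth(x, fs, cfg) - 3 * gaussianSmooth(y, fs, cfg)
  expect_lt(max(abs(lhs - rhs)), 1e-9)
})

test_that("parameter errors are caught", {
  expect_error(gaussianConfig(sigmaSeconds = 0), "positive")
  expect_error(gaussianSmooth(rnorm(10), 10, gaussianConfig(0.01)), "half a sample")
  expect_error(waveletConfig(waveletName = "nope"), "unknown wavelet")
  expect_error(waveletConfig(zeroDetailLevels = 10, nLevels = 9), "1..nLevels")
  expect_error(dwtDecompose(c(1, NA, 3), waveletConfig(nLevels = 1)), "finite")
})
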