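test_that("templates encode the class-distinguishing morphology", {
  n <- makeTemplate("N")$components
  v <- makeTemplate("V")$components
  ## ventricular: no P wave, QRS at least twice as wide
  expect_false("P" %in% v$wave)
  expect_gte(
    v$width[v$wave == "R"],
    2 * n$width[n$wave == "R"]
  )
  ## discordant T
  expect_lt(v$amplitude[v$wave == "T"], 0)
  ## normal template waves are time-ordered P < Q < R < S < T
  expect_identical(n$wave[order(n$center)], c("P", "Q", "R", "S", "T"))
  ## supraventricular: inverted P
  s <- makeTemplate("S")$components
  expect_lt(s$amplitude[s$wave == "P"], 0)
  ## fusion: P closer to the QRS than normal
  f <- makeTemplate("F")$components
  expect_gt(f$center[f$wave == "P"], n$center[n$wave == "P"])
  ## R dominates for the positive-R classes
  for (cl in c("N", "S", "F")) {
    comp <- makeTemplate(cl)$components
    expect_identical(comp$wave[which.max(abs(comp$amplitude))], "R")
  }
  expect_error(makeTemplate("X"), "unknown beat class")
})

test_that("rendered beats peak at the stated R index", {
  for (cl in c("N", "S", "V", "F")) {
    b <- renderBeat(makeTemplate(cl), fs = 360)
    expect_lte(abs(which.max(b$waveform) - 1L - b$rIndex), 1L)
  }
})

test_that("rendering matches a pointwise evaluation of the gaussian sum", {
  ## oracle: independent formula evaluation, separate code path
  tpl <- makeTemplate("N")
  fs <- 360
  b <- renderBeat(tpl, fs)
  t <- (seq_along(b$waveform) - 1 - b$rIndex) / fs
  ref <- Reduce(`+`, lapply(seq_len(nrow(tpl$components)), function(i) {
    with(tpl$components[i, ], amplitude * exp(-(t - center)^2 / (2 * width^2)))
  }))
  expect_lt(max(abs(b$waveform - ref)), 1e-12)
  ## zero-jitter renders are identical; jittered renders are seeded
  expect_identical(renderBeat(tpl, fs), renderBeat(tpl, fs))
  expect_identical(
    renderBeat(tpl, fs, amplitudeJitter = 0.1, seed = 4),
    renderBeat(tpl, fs, amplitudeJitter = 0.1, seed = 4)
  )
  expect_gt(sum(b$waveform^2), 0)
  expect_true(all(is.finite(b$waveform)))
})

test_that("a metronomic spec yields exactly spaced beats", {
  gen <- generateRecord(rhythmSpec(meanBpm = 75, duration = 60, seed = 2))
  idx <- gen$annotations$sampleIndex
  expect_true(all(diff(idx) == round(360 * 0.8)))
  expect_gte(nrow(gen$annotations), 72)
})

test_that("class mix proportions follow the requested distribution", {
  gen <- generateRecord(rhythmSpec(
    meanBpm = 150, duration = 250,
    classMix = c(N = 0.8, F = 0.2), seed = 5
  ))
  tab <- table(gen$annotations$aamiClass)
  nBeats <- sum(tab)
  ## binomial 99% bounds around 0.8
  p <- tab[["N"]] / nBeats
  expect_lt(abs(p - 0.8), 2.58 * sqrt(0.8 * 0.2 / nBeats) + 0.01)
  ## bit-identical reproduction under the same seed
  gen2 <- generateRecord(rhythmSpec(
    meanBpm = 150, duration = 250,
    classMix = c(N = 0.8, F = 0.2), seed = 5
  ))
  expect_identical(gen$record@samples, gen2$record@samples)
  expect_identical(
    as.data.frame(gen$annotations),
    as.data.frame(gen2$annotations)
  )
  expect_identical(gen$clean, gen2$clean)
})

test_that("white noise is scaled to the requested SNR exactly", {
  for (snr in c(5, 10, 20)) {
    gen <- generateRecord(rhythmSpec(
      meanBpm = 80, duration = 20,
      whiteSnrDb = snr, seed = 3
    ))
    resid <- channelSignal(gen$record) - gen$clean
    realized <- 10 * log10(mean(gen$clean^2) / mean(resid^2))
    expect_lt(abs(realized - snr), 0.1)
  }
})

test_that("premature ectopic beats shorten the preceding interval", {
  gen <- generateRecord(rhythmSpec(
    meanBpm = 75, duration = 120,
    classSequence = c("N", "N", "N", "V"), seed = 6
  ))
  ann <- gen$annotations
  rr <- diff(ann$sampleIndex) / 360
  isV <- ann$aamiClass[-1L] == "V"
  expect_lt(max(rr[isV]), 0.65 * 0.8 / 0.6 + 1e-9) # 0.8 s * factor 0.6
  expect_gt(min(rr[!isV]), 0.7)
})

test_that("ground-truth R indices sit on waveform maxima", {
  gen <- generateRecord(rhythmSpec(
    meanBpm = 70, duration = 30,
    classMix = c(N = 0.7, S = 0.15, F = 0.15), seed = 8
  ))
  x <- gen$clean
  for (i in seq_len(nrow(gen$annotations))) {
    r <- gen$annotations$sampleIndex[i] + 1L
    win <- x[max(1, r - 10):min(length(x), r + 10)]
    expect_lte(abs(which.max(win) - 11L), 1L)
  }
})

test_that("synthetic beat sets are balanced, labelled and deterministic", {
  bs <- synthBeatSet(10, classes = c("N", "V"), seed = 3)
  expect_identical(ncol(bs), 20L)
  expect_true(all(table(beatLabels(bs)) == 10L))
  bs2 <- synthBeatSet(10, classes = c("N", "V"), seed = 3)
  expect_identical(beatWindows(bs), beatWindows(bs2))
  ## ectopic classes carry a shortened preceding interval in their features
  f <- rriMatrix(bs)
  expect_lt(max(f[beatLabels(bs) == "V", "pre_over_local"]), 0.7)
  expect_gt(min(f[beatLabels(bs) == "N", "pre_over_local"]), 0.9)
})

test_that("the full pipeline closes the loop on a clean record", {
  res <- processRecord(rhythmSpec(
    meanBpm = 75, duration = 60,
    rrJitterFraction = 0.05,
    classMix = c(N = 0.7, S = 0.1, V = 0.1, F = 0.1), seed = 12
  ))
  expect_gte(res$match$sensitivity, 0.99)
  expect_gte(res$match$ppv, 0.99)
  expect_gte(res$labelledFraction, 0.99)
  expect_gt(ncol(res$segments), 0)
})

test_that("invalid rhythm specs are rejected", {
  expect_error(rhythmSpec(meanBpm = 10), "meanBpm")
  expect_error(rhythmSpec(classMix = c(N = 0.5)), "sum to 1")
  expect_error(rhythmSpec(meanBpm = 40, duration = 1), "too short")
})
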