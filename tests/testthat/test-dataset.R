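test_that("segmentation drops boundary beats and normalizes windows", {
  x <- sin(seq_len(1000) / 20)
  x[c(101, 501, 901)] <- 3 # distinct apexes at 0-based 100/500/900
  rec <- ECGRecord(x, fs = 360, recordId = "b")
  ann <- beatAnnotations(c(100L, 500L, 900L), c("N", "V", "N"))
  seg <- segmentBeats(rec, ann, L = 250L, rOffset = 90L)
  ## beat at 900: window would end at 1059 > 999, dropped
  expect_identical(ncol(seg), 2L)
  expect_identical(attr(seg, "droppedBoundaryBeats"), 1L)
  w <- beatWindows(seg)
  expect_lt(max(abs(colMeans(w))), 1e-9)
  expect_equal(apply(w, 2, sd), c(1, 1), tolerance = 1e-9)
  ## R apex lands on the configured offset
  expect_true(all(abs(apply(w, 2, which.max) - 1L - 90L) <= 1))
  expect_identical(beatLabels(seg), c("N", "V"))
})

test_that("segment windows place the generator's R apex at rOffset", {
  gen <- fixture_record(seed = 5, duration = 30)
  seg <- segmentBeats(gen$record, gen$annotations)
  w <- beatWindows(seg)
  expect_true(all(abs(apply(w, 2, which.max) - 1L - 90L) <= 1))
})

test_that("time warping preserves length and is the identity at factor 1", {
  set.seed(2)
  w <- rnorm(250)
  expect_equal(timeWarp(w, 1.0), w, tolerance = 1e-12)
  for (f in c(0.5, 0.8, 1.3, 2.0)) {
    expect_length(timeWarp(w, f), 250)
  }
  expect_error(timeWarp(w, 0.3), "0.5")
})

test_that("time warping moves a known apex the predicted way", {
  tpl <- renderBeat(makeTemplate("N"), fs = 360)
  w <- tpl$waveform[1:250]
  apex <- which.max(w)
  ## factor < 1 stretches: content is resampled to length L/f then
  ## center-cropped, displacing an off-center apex away from the center
  warped <- timeWarp(w, 0.9)
  newApex <- which.max(warped)
  expect_lte(abs(newApex - apex), ceiling(0.1 * 250 / 2))
  ## direction: oracle by direct interpolation of the same window
  direct <- approx(seq_len(250), w, n = round(250 / 0.9))$y
  off <- (length(direct) - 250) %/% 2
  expect_equal(newApex, which.max(direct[(off + 1):(off + 250)]))
})

test_that("noise injection realizes the requested SNR exactly", {
  set.seed(3)
  w <- rnorm(250)
  for (snr in c(5, 15, 30, 59)) {
    out <- noiseInject(w, snr, seed = 7)
    realized <- 10 * log10(mean(w^2) / mean((out - w)^2))
    expect_lt(abs(realized - snr), 0.1)
  }
  ## near-clean injection barely perturbs the signal
  expect_gt(cor(noiseInject(w, 60, seed = 1), w), 0.999)
  ## determinism
  expect_identical(noiseInject(w, 20, seed = 5), noiseInject(w, 20, seed = 5))
  expect_false(identical(noiseInject(w, 20, seed = 5), noiseInject(w, 20, seed = 6)))
  expect_error(noiseInject(rep(0, 100), 20), "zero-power")
  expect_error(noiseInject(w, 0), "snrDb")
})

test_that("class balancing equalizes counts without touching originals", {
  set.seed(4)
  counts <- c(N = 100L, S = 10L, V = 10L, F = 5L, Q = 5L)
  parts <- lapply(names(counts), function(cl) {
    fixture_beats(counts[[cl]], classes = cl, seed = match(cl, names(counts)))
  })
  segs <- do.call(combineSegments, parts)
  bal <- balanceClasses(segs, seed = 9)
  tab <- table(beatLabels(bal))
  expect_true(all(tab == 100L))
  ## deficits: 90 + 90 + 95 + 95 augmented segments
  expect_identical(sum(SummarizedExperiment::colData(bal)$augmented), 370L)
  ## originals all retained, labels pure
  expect_identical(
    sum(!SummarizedExperiment::colData(bal)$augmented), 130L
  )
  aug <- bal[, SummarizedExperiment::colData(bal)$augmented]
  srcLab <- setNames(
    beatLabels(segs),
    SummarizedExperiment::colData(segs)$source
  )
  expect_identical(
    unname(srcLab[SummarizedExperiment::colData(aug)$source]),
    beatLabels(aug)
  )
})

test_that("already balanced input returns unchanged", {
  segs <- fixture_beats(10, seed = 6)
  expect_identical(balanceClasses(segs, seed = 1), segs)
})

test_that("balancing refuses to discard majority beats", {
  segs <- fixture_beats(10, seed = 6)
  expect_error(balanceClasses(segs, targetPerClass = 5), "never discarded")
})

test_that("folds stratify exactly and are seed-deterministic", {
  segs <- fixture_beats(20, seed = 7) # 100 segments, 20 per class
  fs <- makeFolds(segs, k = 5, seed = 3)
  expect_identical(sort(unique(fs$assignments)), 0:4)
  expect_true(all(table(fs$assignments) == 20L))
  ## per-class stratification: exactly 4 per class per fold
  tab <- table(beatLabels(segs), fs$assignments)
  expect_true(all(tab == 4L))
  expect_identical(makeFolds(segs, 5, seed = 3)$assignments, fs$assignments)
  diffs <- vapply(1:10, function(s) {
    !identical(
      makeFolds(segs, 5, seed = s)$assignments,
      makeFolds(segs, 5, seed = s + 100)$assignments
    )
  }, logical(1))
  expect_true(all(diffs))
})

test_that("folds with 10 originals per class give exactly 2 per fold", {
  segs <- fixture_beats(10, seed = 8)
  fs <- makeFolds(segs, k = 5, seed = 1)
  tab <- table(beatLabels(segs), fs$assignments)
  expect_true(all(tab == 2L))
})

test_that("fold construction rejects classes smaller than k", {
  segs <- fixture_beats(3, seed = 9)
  expect_error(makeFolds(segs, k = 5), "fewer than k")
})

test_that("training-fold augmentation never leaks into validation", {
  segs <- fixture_beats(15, seed = 10)
  fs <- makeFolds(segs, k = 3, seed = 2)
  for (f in 0:2) {
    train <- segs[, fs$assignments != f]
    valid <- segs[, fs$assignments == f]
    bal <- balanceClasses(train, targetPerClass = 30L, seed = 5 + f)
    augSources <- SummarizedExperiment::colData(bal)$source[
      SummarizedExperiment::colData(bal)$augmented
    ]
    expect_length(
      intersect(augSources, SummarizedExperiment::colData(valid)$source), 0
    )
  }
})
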