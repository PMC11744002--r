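#' Class-conditional beat templates
#'
#' Each beat class is modelled as a sum of Gaussian wave components
#' (one per P, Q, R, S, T wave where present): `g(t) = A * exp(-(t - mu)^2 /
#' (2 w^2))` with `mu` in seconds relative to the R apex, `A` in millivolts
#' and `w` in seconds. The normal template uses textbook timings and
#' amplitudes; the arrhythmic classes encode the morphology that
#' distinguishes them clinically, deliberately exaggerated so that the
#' classes are separable by construction:
#'
#' * `N` — standard upright P-QRS-T.
#' * `S` — inverted (ectopic) P wave, narrow QRS; at the rhythm level the
#'   preceding R-R interval is shortened (see [generateRecord()]).
#' * `V` — no P wave, QRS widened 2.5x, discordant (negative) T wave.
#' * `F` — intermediate QRS width, P-to-QRS interval shortened.
#' * `Q` — atypical low-amplitude morphology drawn from a seeded family.
#'
#' @param classLabel one of `"N"`, `"S"`, `"V"`, `"F"`, `"Q"`.
#' @param seed optional integer; only used by class `Q`, whose morphology is
#'   sampled from a family of atypical shapes.
#'
#' @return A list with elements `components` (data.frame with columns
#'   `wave`, `center`, `amplitude`, `width`) and `class`.
#' @examples
#' tpl <- makeTemplate("V")
#' tpl$components
#' @export
makeTemplate <- function(classLabel, seed = NULL) {
  comp <- function(wave, center, amplitude, width) {
    data.frame(
      wave = wave, center = center, amplitude = amplitude, width = width,
      stringsAsFactors = FALSE
    )
  }
  components <- switch(classLabel,
    N = rbind(
      comp("P", -0.200, 0.15, 0.025),
      comp("Q", -0.035, -0.10, 0.010),
      comp("R", 0.000, 1.00, 0.012),
      comp("S", 0.035, -0.15, 0.010),
      comp("T", 0.300, 0.30, 0.070)
    ),
    S = rbind(
      comp("P", -0.150, -0.12, 0.020), # inverted ectopic P
      comp("Q", -0.030, -0.08, 0.008),
      comp("R", 0.000, 0.90, 0.009), # narrow QRS
      comp("S", 0.030, -0.12, 0.008),
      comp("T", 0.280, 0.25, 0.060)
    ),
    V = rbind(
      # no P component
      comp("Q", -0.070, -0.25, 0.030),
      comp("R", 0.000, 1.10, 0.030), # 2.5x the normal QRS width
      comp("S", 0.080, -0.35, 0.030),
      comp("T", 0.330, -0.40, 0.080) # discordant T
    ),
    F = rbind(
      comp("P", -0.110, 0.10, 0.022), # shortened P-to-QRS interval
      comp("Q", -0.045, -0.12, 0.015),
      comp("R", 0.000, 0.85, 0.018), # intermediate QRS width
      comp("S", 0.050, -0.18, 0.015),
      comp("T", 0.300, 0.20, 0.070)
    ),
    Q = {
      base <- rbind(
        comp("P", -0.180, 0.05, 0.040),
        comp("R", 0.000, 0.45, 0.045), # low, broad main deflection
        comp("S", 0.090, -0.20, 0.050),
        comp("T", 0.280, -0.10, 0.090)
      )
      if (!is.null(seed)) {
        base$amplitude <- base$amplitude *
          with_local_seed(seed, stats::runif(nrow(base), 0.7, 1.3))
        base$center <- base$center +
          with_local_seed(seed + 1L, stats::runif(nrow(base), -0.02, 0.02)) *
            c(1, 0, 1, 1) # R stays anchored at 0
      }
      base
    },
    stop("unknown beat class: ", classLabel)
  )
  list(components = components, class = classLabel)
}

# Run an expression under a temporary RNG state, restoring the caller's.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Render a single beat waveform from a template
#'
#' Evaluates the sum of Gaussian wave components on a sample grid spanning
#' `preSeconds` before to `postSeconds` after the R apex.
#'
#' @param template a beat template from [makeTemplate()].
#' @param fs sampling rate, Hz (>= 120).
#' @param amplitudeJitter fraction by which each component amplitude is
#'   perturbed uniformly (0 = deterministic).
#' @param seed integer seed governing the jitter.
#' @param preSeconds,postSeconds window extent around the R apex.
#'
#' @return list with `waveform` (numeric vector, mV) and `rIndex`
#'   (0-based index of the true R apex sample).
#' @examples
#' b <- renderBeat(makeTemplate("N"), fs = 360)
#' b$rIndex
#' @export
renderBeat <- function(template, fs, amplitudeJitter = 0, seed = 1L,
                       preSeconds = 0.35, postSeconds = 0.45) {
  if (fs < 120) stop("fs must be >= 120 Hz")
  comp <- template$components
  amps <- comp$amplitude
  if (amplitudeJitter > 0) {
    amps <- amps * with_local_seed(
      seed,
      stats::runif(nrow(comp), 1 - amplitudeJitter, 1 + amplitudeJitter)
    )
  }
  rIndex <- round(preSeconds * fs)
  t <- (seq_len(round((preSeconds + postSeconds) * fs) + 1L) - 1L - rIndex) / fs
  waveform <- numeric(length(t))
  for (i in seq_len(nrow(comp))) {
    waveform <- waveform +
      amps[i] * exp(-(t - comp$center[i])^2 / (2 * comp$width[i]^2))
  }
  list(waveform = waveform, rIndex = as.integer(rIndex))
}

#' Rhythm specification for the synthetic generator
#'
#' @param meanBpm mean heart rate in beats per minute (30-220).
#' @param duration record duration in seconds.
#' @param rrJitterFraction R-R intervals are multiplied by
#'   `1 + U(-f, f)`; 0 gives a metronomic rhythm.
#' @param classMix named numeric vector of class proportions (must sum to 1),
#'   or NULL when `classSequence` is given.
#' @param classSequence explicit character vector of beat classes, recycled
#'   to the number of beats; overrides `classMix`.
#' @param prematureRrFactor multiplier (< 1) applied to the R-R interval
#'   preceding an ectopic (S or V) beat.
#' @param fs sampling rate, Hz.
#' @param whiteSnrDb additive white-noise level as signal-to-noise ratio in
#'   dB, or NULL for no noise.
#' @param baselineAmpMv,baselineFreqHz sinusoidal baseline-wander amplitude
#'   (mV) and frequency (Hz); amplitude NULL or 0 disables it.
#' @param amplitudeJitter per-beat fractional amplitude jitter.
#' @param seed integer seed; the whole record is deterministic given it.
#'
#' @return validated list of class `rhythmSpec`.
#' @export
rhythmSpec <- function(meanBpm = 75, duration = 60, rrJitterFraction = 0,
                       classMix = c(N = 1), classSequence = NULL,
                       prematureRrFactor = 0.6, fs = 360,
                       whiteSnrDb = NULL, baselineAmpMv = NULL,
                       baselineFreqHz = 0.3, amplitudeJitter = 0,
                       seed = 1L) {
  if (meanBpm < 30 || meanBpm > 220) stop("meanBpm must be in [30, 220]")
  if (duration <= 60 / meanBpm) stop("duration too short for a single beat")
  if (is.null(classSequence)) {
    if (abs(sum(classMix) - 1) > 1e-8) stop("classMix proportions must sum to 1")
    if (!all(names(classMix) %in% AAMI_CLASSES)) stop("classMix names must be AAMI classes")
  }
  structure(
    list(
      meanBpm = meanBpm, duration = duration,
      rrJitterFraction = rrJitterFraction, classMix = classMix,
      classSequence = classSequence, prematureRrFactor = prematureRrFactor,
      fs = fs, whiteSnrDb = whiteSnrDb, baselineAmpMv = baselineAmpMv,
      baselineFreqHz = baselineFreqHz, amplitudeJitter = amplitudeJitter,
      seed = as.integer(seed)
    ),
    class = "rhythmSpec"
  )
}

# representative MIT-BIH symbol emitted for each AAMI class
CLASS_TO_SYMBOL <- c(N = "N", S = "A", V = "V", F = "F", Q = "Q")

#' Generate a synthetic annotated ECG record
#'
#' Places class-conditional template beats at R-R intervals
#' `60 / meanBpm * (1 + jitter)`; the interval preceding an ectopic (S or V)
#' beat is additionally multiplied by `prematureRrFactor`. Optionally adds
#' sinusoidal baseline wander and white Gaussian noise scaled so the
#' realized SNR against the clean signal equals `whiteSnrDb` exactly.
#' Everything is deterministic given `spec$seed`.
#'
#' @param spec a [rhythmSpec()].
#'
#' @return list with components:
#'   \describe{
#'     \item{record}{[ECGRecord-class] with the (possibly noisy) signal.}
#'     \item{annotations}{ground-truth [beatAnnotations()] (0-based true R
#'       sample indices and class labels).}
#'     \item{clean}{the noise-free signal (numeric vector), for SNR oracles.}
#'   }
#' @examples
#' out <- generateRecord(rhythmSpec(meanBpm = 75, duration = 10, seed = 7))
#' nrow(out$annotations)
#' @export
generateRecord <- function(spec) {
  stopifnot(inherits(spec, "rhythmSpec"))
  fs <- spec$fs
  n <- round(spec$duration * fs)
  with_local_seed(spec$seed, {
    rrBase <- 60 / spec$meanBpm
    # provisional beat count upper bound
    maxBeats <- ceiling(spec$duration / (rrBase * (1 - spec$rrJitterFraction) *
      min(1, spec$prematureRrFactor))) + 2L
    if (!is.null(spec$classSequence)) {
      classes <- rep_len(spec$classSequence, maxBeats)
    } else {
      classes <- sample(names(spec$classMix), maxBeats,
        replace = TRUE, prob = spec$classMix
      )
    }
    jit <- if (spec$rrJitterFraction > 0) {
      stats::runif(maxBeats, -spec$rrJitterFraction, spec$rrJitterFraction)
    } else {
      numeric(maxBeats)
    }
    rr <- rrBase * (1 + jit)
    rr[classes %in% c("S", "V")] <- rr[classes %in% c("S", "V")] *
      spec$prematureRrFactor
    tR <- 0.5 + cumsum(c(0, rr[-1L]))
    keep <- tR <= spec$duration - 0.5
    tR <- tR[keep]
    classes <- classes[keep]
    if (!length(tR)) stop("duration too short for a single beat")

    clean <- numeric(n)
    tGrid <- (seq_len(n) - 1L) / fs
    rIdx <- integer(length(tR))
    for (b in seq_along(tR)) {
      tpl <- makeTemplate(classes[b], seed = if (classes[b] == "Q") spec$seed + b else NULL)
      comp <- tpl$components
      amps <- comp$amplitude
      if (spec$amplitudeJitter > 0) {
        amps <- amps * stats::runif(nrow(comp), 1 - spec$amplitudeJitter,
          1 + spec$amplitudeJitter)
      }
      rIdx[b] <- as.integer(round(tR[b] * fs))
      for (i in seq_len(nrow(comp))) {
        mu <- tR[b] + comp$center[i]
        w <- comp$width[i]
        lo <- max(1L, floor((mu - 5 * w) * fs) + 1L)
        hi <- min(n, ceiling((mu + 5 * w) * fs) + 1L)
        if (lo > hi) next
        seg <- lo:hi
        clean[seg] <- clean[seg] +
          amps[i] * exp(-(tGrid[seg] - mu)^2 / (2 * w^2))
      }
    }

    x <- clean
    if (!is.null(spec$baselineAmpMv) && spec$baselineAmpMv > 0) {
      x <- x + spec$baselineAmpMv * sin(2 * pi * spec$baselineFreqHz * tGrid)
    }
    if (!is.null(spec$whiteSnrDb)) {
      noise <- stats::rnorm(n)
      pSig <- mean(clean^2)
      if (pSig <= 0) stop("zero-power clean signal; cannot scale noise")
      noise <- noise * sqrt(pSig / (mean(noise^2) * 10^(spec$whiteSnrDb / 10)))
      x <- x + noise
    }

    list(
      record = ECGRecord(x, fs = fs, recordId = paste0("synth", spec$seed)),
      annotations = beatAnnotations(rIdx, CLASS_TO_SYMBOL[classes]),
      clean = clean
    )
  })
}

#' Generate a labelled synthetic beat set directly
#'
#' Renders `nPerClass` windows per requested class straight into a
#' [BeatSegmentSet-class], with per-beat amplitude jitter, optional white
#' noise, per-beat z-score normalization and class-conditional RRI features
#' (ectopic classes S and V get a shortened preceding interval). This is the
#' pre-segmented entry point: it bypasses detection/segmentation and gives
#' exactly balanced classes with known ground truth, which is what the
#' classifier's training and evaluation tests consume.
#'
#' @param nPerClass beats per class.
#' @param classes character vector of classes to include.
#' @param fs sampling rate, Hz.
#' @param L window length in samples.
#' @param rOffset 0-based index of the R apex within the window.
#' @param snrDb white-noise SNR in dB, or NULL for clean beats.
#' @param amplitudeJitter fractional amplitude jitter per component.
#' @param meanRrMs mean R-R interval for the RRI features, in ms.
#' @param seed integer seed.
#'
#' @return A [BeatSegmentSet-class] with `nPerClass * length(classes)` beats.
#' @examples
#' bs <- synthBeatSet(10, classes = c("N", "V"), seed = 3)
#' table(beatLabels(bs))
#' @export
synthBeatSet <- function(nPerClass, classes = AAMI_CLASSES, fs = 360,
                         L = 250L, rOffset = 90L, snrDb = NULL,
                         amplitudeJitter = 0.1, meanRrMs = 800, seed = 1L) {
  pre <- rOffset / fs
  post <- (L - rOffset - 1L) / fs
  nTot <- nPerClass * length(classes)
  windows <- matrix(0, L, nTot)
  label <- character(nTot)
  src <- character(nTot)
  rri <- matrix(0, nTot, 4L)
  with_local_seed(seed, {
    k <- 0L
    for (cl in classes) {
      for (j in seq_len(nPerClass)) {
        k <- k + 1L
        tpl <- makeTemplate(cl, seed = if (cl == "Q") seed + k else NULL)
        comp <- tpl$components
        amps <- comp$amplitude *
          stats::runif(nrow(comp), 1 - amplitudeJitter, 1 + amplitudeJitter)
        t <- (seq_len(L) - 1L - rOffset) / fs
        w <- numeric(L)
        for (i in seq_len(nrow(comp))) {
          w <- w + amps[i] * exp(-(t - comp$center[i])^2 / (2 * comp$width[i]^2))
        }
        if (!is.null(snrDb)) {
          noise <- stats::rnorm(L)
          noise <- noise * sqrt(mean(w^2) / (mean(noise^2) * 10^(snrDb / 10)))
          w <- w + noise
        }
        windows[, k] <- znorm(w)
        label[k] <- cl
        src[k] <- sprintf("synth%d:%s%d", seed, cl, j)
        base <- meanRrMs * stats::runif(1, 0.95, 1.05)
        preRr <- if (cl %in% c("S", "V")) base * 0.6 else base
        localMean <- meanRrMs
        rri[k, ] <- c(preRr, base, localMean, preRr / localMean)
      }
    }
  })
  BeatSegmentSet(windows, label, rri, src,
    augmented = rep(FALSE, nTot), fs = fs, rOffset = rOffset
  )
}

# per-beat z-score with a std floor, shared by segmentation and synthesis
znorm <- function(x, floor = 1e-6) {
  s <- stats::sd(x)
  (x - mean(x)) / max(s, floor)
}
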