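#' Construct class-conditioned micro-vibration parameters
#'
#' @param classLabel "clear" or "incomprehensible".
#' @param carrierBand two-element Hz interval of the band-pass carrier.
#' @param envelopeRate amplitude-envelope frequency, Hz.
#' @param envelopeLatency onset latency of the stimulus-locked component, s.
#' @param amplitude carrier RMS tilt amplitude, radians.
#' @param classSeparation effect size recorded with the object (see
#'   [defaultClassParams()]).
#' @param noiseFloor broadband class-independent tilt RMS, radians.
#' @return A [ClassSignalParams-class].
#' @export
classSignalParams <- function(classLabel, carrierBand, envelopeRate = 2,
                              envelopeLatency = 0, amplitude = 3e-4,
                              classSeparation = 1, noiseFloor = 2e-5) {
  new("ClassSignalParams", classLabel = classLabel,
      carrierBand = as.numeric(carrierBand), envelopeRate = envelopeRate,
      envelopeLatency = envelopeLatency, amplitude = amplitude,
      classSeparation = classSeparation, noiseFloor = noiseFloor)
}

#' Default per-class signal parameters
#'
#' The true class-distinguishing physiological signal is unobserved; the
#' synthetic model separates the two stimulus classes by the spectral
#' centroid and envelope rate of a band-limited tilt carrier, leaving every
#' frame-marginal statistic identical between classes (both classes move
#' with equal RMS amplitude; only the temporal dynamics differ). With
#' separation `s` the common carrier band `(30, 70)` Hz is shifted by
#' `+/- 25 s` Hz and the 2 Hz envelope rate by `+/- 25 s` percent, the
#' "clear" class taking the upper values. `s = 0` makes the two classes
#' identically distributed (the null corpus); `s = 1` is the default
#' operating point.
#'
#' @param classSeparation effect size `s >= 0`.
#' @param fps frame rate (bands must stay below `fps/2`).
#' @param amplitude carrier RMS tilt, radians.
#' @param envelopeLatency onset latency, s (0 by default: recording is
#'   assumed to start after the response has stabilized).
#' @param noiseFloor broadband tilt RMS, radians.
#' @return Named list with `clear` and `incomprehensible`
#'   [ClassSignalParams-class] entries.
#' @examples
#' p <- defaultClassParams(1)
#' p$clear@carrierBand
#' @export
defaultClassParams <- function(classSeparation = 1, fps = 500,
                               amplitude = 3e-4, envelopeLatency = 0,
                               noiseFloor = 2e-5) {
  stopifnot(classSeparation >= 0)
  base <- c(30, 70)
  shift <- 25 * classSeparation
  up <- base + shift
  dn <- pmax(base - shift, c(2, 6))
  if (up[2] >= fps / 2)
    stop("carrier band exceeds the Nyquist frequency", call. = FALSE)
  list(
    clear = classSignalParams("clear", up,
                              envelopeRate = 2 * (1 + 0.25 * classSeparation),
                              envelopeLatency = envelopeLatency,
                              amplitude = amplitude,
                              classSeparation = classSeparation,
                              noiseFloor = noiseFloor),
    incomprehensible = classSignalParams(
      "incomprehensible", dn,
      envelopeRate = 2 * max(1 - 0.25 * classSeparation, 0.1),
      envelopeLatency = envelopeLatency, amplitude = amplitude,
      classSeparation = classSeparation, noiseFloor = noiseFloor))
}

# Class-independent parameters for the control region: the midpoint of the
# two class parameter sets, so control videos carry no label information.
midpointParams <- function(classParams) {
  a <- classParams[[1]]; b <- classParams[[2]]
  classSignalParams("control",
                    (a@carrierBand + b@carrierBand) / 2,
                    envelopeRate = (a@envelopeRate + b@envelopeRate) / 2,
                    envelopeLatency = (a@envelopeLatency +
                                         b@envelopeLatency) / 2,
                    amplitude = (a@amplitude + b@amplitude) / 2,
                    classSeparation = 0,
                    noiseFloor = (a@noiseFloor + b@noiseFloor) / 2)
}

# Band-pass filtered unit-RMS Gaussian noise of length n at rate fps.
bandNoise <- function(n, band, fps) {
  w <- rnorm(n)
  W <- stats::fft(w)
  freq <- (0:(n - 1)) * fps / n
  freq <- pmin(freq, fps - freq)  # two-sided
  keep <- freq >= band[1] & freq <= band[2]
  if (!any(keep)) stop("carrier band contains no Fourier bin", call. = FALSE)
  W[!keep] <- 0
  x <- Re(stats::fft(W, inverse = TRUE) / n)
  x / sqrt(mean(x^2))
}

#' Generate a class-conditioned tilt series
#'
#' Band-limited stochastic tilt: independent band-pass Gaussian carriers for
#' `alphaX` and `alphaY`, scaled to `amplitude` RMS, modulated by a slow
#' sinusoidal envelope at `envelopeRate` (random phase), gated by a smooth
#' onset at `envelopeLatency`, plus a broadband `noiseFloor` component.
#' Draws from the current RNG unless `seed` is given.
#'
#' @param params a [ClassSignalParams-class].
#' @param durationS clip duration, s.
#' @param fps frame rate; the carrier band must lie below `fps/2`.
#' @param seed optional integer seed for reproducible draws.
#' @param amplitudeScale multiplicative amplitude jitter (subject nuisance).
#' @return A [TiltSeries-class] of `round(durationS * fps)` frames.
#' @examples
#' p <- defaultClassParams(1)$clear
#' ts <- generateTiltSeries(p, durationS = 1, fps = 500, seed = 1)
#' @export
generateTiltSeries <- function(params, durationS, fps, seed = NULL,
                               amplitudeScale = 1) {
  stopifnot(is(params, "ClassSignalParams"))
  if (params@carrierBand[2] >= fps / 2)
    stop("carrier band exceeds the Nyquist frequency", call. = FALSE)
  n <- round(durationS * fps)
  if (n < 1) stop("duration * fps must be >= 1", call. = FALSE)
  gen <- function() {
    tt <- (0:(n - 1)) / fps
    onset <- if (params@envelopeLatency > 0)
      1 / (1 + exp(-(tt - params@envelopeLatency) / 0.02)) else rep(1, n)
    one <- function() {
      env <- 1 + 0.6 * sin(2 * pi * params@envelopeRate * tt +
                             runif(1, 0, 2 * pi))
      a <- params@amplitude * amplitudeScale
      carrier <- if (a > 0) bandNoise(n, params@carrierBand, fps) else
        numeric(n)
      a * env * onset * carrier + params@noiseFloor * rnorm(n)
    }
    list(x = one(), y = one())
  }
  xy <- if (is.null(seed)) gen() else withSeed(seed, gen())
  new("TiltSeries", alphaX = xy$x, alphaY = xy$y, fps = fps)
}

#' Spectral centroid of a signal
#'
#' Periodogram-weighted mean frequency (DC excluded); used to verify that
#' generated tilt carriers land on their configured band.
#'
#' @param x numeric signal.
#' @param fps sampling rate.
#' @return Centroid frequency in Hz.
#' @export
spectralCentroid <- function(x, fps) {
  n <- length(x)
  P <- Mod(stats::fft(x - mean(x)))^2
  half <- 2:floor(n / 2)
  f <- (half - 1) * fps / n
  sum(f * P[half]) / sum(P[half])
}

#' Construct a corpus specification
#'
#' Desk-scale defaults: 3 subjects, 4 videos per class per session, 2 s
#' clips at 500 fps, two sessions and the Wernicke-region corpus only. The
#' full-protocol preset of the emulated study is
#' `corpusSpec(nSubjects = 7, videosPerClassPerSession = 10, durationS = 10,
#' fps = 1000)`.
#'
#' @param nSubjects number of synthetic subjects.
#' @param videosPerClassPerSession videos per class per subject per session.
#' @param durationS clip duration in seconds.
#' @param fps frame rate (500 or 1000).
#' @param sessions session tags, recorded in order (first = training
#'   session).
#' @param regions illuminated regions; include "control" for the
#'   forehead-style control corpus.
#' @param subjectGainRange uniform range of the per-subject camera gain.
#' @param tiltJitterRange uniform range of the per-subject tilt-amplitude
#'   jitter.
#' @param masterSeed integer master seed; every video seed derives from it.
#' @return A [CorpusSpec-class].
#' @export
corpusSpec <- function(nSubjects = 3, videosPerClassPerSession = 4,
                       durationS = 2, fps = 500,
                       sessions = c("morning", "afternoon"),
                       regions = "wernicke",
                       subjectGainRange = c(0.8, 1.2),
                       tiltJitterRange = c(0.9, 1.1), masterSeed = 1) {
  new("CorpusSpec", nSubjects = as.integer(nSubjects),
      videosPerClassPerSession = as.integer(videosPerClassPerSession),
      durationS = durationS, fps = fps, sessions = sessions,
      regions = regions, subjectGainRange = subjectGainRange,
      tiltJitterRange = tiltJitterRange, masterSeed = as.integer(masterSeed))
}

#' Generate a labeled synthetic corpus (lazily)
#'
#' Builds the manifest for every (subject, session, region, class, video)
#' combination of the specification: per-video tilt and noise seeds, a
#' per-(subject, session, region) phase-screen seed (re-aiming the laser
#' between sessions produces a fresh speckle realization), and per-subject
#' nuisance gain and tilt-amplitude jitter. Control-region videos keep
#' their class label in the manifest but are generated from the
#' class-independent [midpointParams()] signal, so they carry no label
#' information by construction. Videos are rendered on demand by
#' [corpusVideo()]; identical `masterSeed` yields an identical manifest and
#' identical videos.
#'
#' @param spec a [CorpusSpec-class].
#' @param classParams named list of per-class parameters
#'   (default [defaultClassParams()] at the spec frame rate).
#' @param optics an [OpticalConfig-class]; defaults to [opticalConfig()] at
#'   the spec frame rate.
#' @return A [SpeckleCorpus-class].
#' @examples
#' corp <- generateCorpus(corpusSpec(nSubjects = 1,
#'                                   videosPerClassPerSession = 1))
#' manifest(corp)
#' @export
generateCorpus <- function(spec,
                           classParams = defaultClassParams(fps = spec@fps),
                           optics = suppressWarnings(
                             opticalConfig(fps = spec@fps))) {
  stopifnot(is(spec, "CorpusSpec"))
  classes <- names(classParams)
  ms <- spec@masterSeed
  rows <- list()
  for (si in seq_len(spec@nSubjects)) {
    nuis <- withSeed(mixSeed(ms, si, 7001), c(
      gain = runif(1, spec@subjectGainRange[1], spec@subjectGainRange[2]),
      jit = runif(1, spec@tiltJitterRange[1], spec@tiltJitterRange[2])))
    for (se in seq_along(spec@sessions)) for (re in seq_along(spec@regions)) {
      screenSeed <- mixSeed(ms, si, se, re, 8002)
      for (cl in seq_along(classes)) {
        for (v in seq_len(spec@videosPerClassPerSession)) {
          rows[[length(rows) + 1L]] <- data.frame(
            videoId = sprintf("s%02d_%s_%s_%s_v%02d", si, spec@sessions[se],
                              spec@regions[re], classes[cl], v),
            subject = sprintf("s%02d", si),
            session = spec@sessions[se], region = spec@regions[re],
            classLabel = classes[cl], fps = spec@fps,
            durationS = spec@durationS,
            tiltSeed = mixSeed(ms, si, se, re, cl, v, 1),
            noiseSeed = mixSeed(ms, si, se, re, cl, v, 2),
            screenSeed = screenSeed, gain = nuis[["gain"]],
            ampJitter = nuis[["jit"]], stringsAsFactors = FALSE)
        }
      }
    }
  }
  new("SpeckleCorpus", manifest = do.call(rbind, rows), spec = spec,
      classParams = classParams, controlParams = midpointParams(classParams),
      optics = optics)
}

#' Materialize one corpus video
#'
#' Deterministically regenerates the phase screen, tilt series and rendered
#' frames for a manifest row.
#'
#' @param corpus a [SpeckleCorpus-class].
#' @param videoId a manifest `videoId` (or integer row index).
#' @param noise noise model forwarded to [synthesizeVideo()] (`NULL`
#'   disables noise).
#' @return A [SpeckleVideo-class].
#' @export
corpusVideo <- function(corpus, videoId,
                        noise = list(photonsPerUnit = 10, readNoiseSd = 2)) {
  stopifnot(is(corpus, "SpeckleCorpus"))
  m <- corpus@manifest
  row <- if (is.numeric(videoId)) m[videoId, ] else m[m$videoId == videoId, ]
  if (nrow(row) != 1L) stop("videoId not found in manifest", call. = FALSE)
  params <- if (row$region == "control") corpus@controlParams
            else corpus@classParams[[row$classLabel]]
  tilts <- generateTiltSeries(params, row$durationS, row$fps,
                              seed = row$tiltSeed,
                              amplitudeScale = row$ampJitter)
  screen <- makePhaseScreen(corpus@optics@frameShape,
                            apertureFractionFor(corpus@optics@targetSpecklePx),
                            seed = row$screenSeed)
  synthesizeVideo(tilts, screen, corpus@optics, subjectId = row$subject,
                  sessionTag = row$session, regionTag = row$region,
                  classLabel = row$classLabel, videoId = row$videoId,
                  gain = row$gain, noise = noise, seed = row$noiseSeed)
}

#' Corpus manifest accessor
#'
#' @param x a [SpeckleCorpus-class].
#' @return The manifest data.frame (one row per video).
#' @export
manifest <- function(x) {
  stopifnot(is(x, "SpeckleCorpus"))
  x@manifest
}
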