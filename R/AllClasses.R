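#' @import methods
#' @importFrom stats fft rnorm runif sd quantile setNames
NULL

#' Optical acquisition geometry for secondary-speckle imaging
#'
#' Container for the physical parameters of a defocused-camera speckle
#' acquisition: laser wavelength and spot size, the surface-to-speckle-plane
#' and speckle-plane-to-lens distances, detector pixel pitch, the minimum
#' number of detector pixels per speckle, frame geometry and rate, and two
#' simulator calibration constants (the target speckle grain in pixels and
#' the pixels-per-radian tilt sensitivity of the rendered pattern).
#'
#' @slot wavelength laser wavelength in metres.
#' @slot spotDiameter illuminated spot diameter in metres.
#' @slot z2 distance from the illuminated surface to the secondary speckle
#'   plane, metres.
#' @slot z3 distance from the speckle plane to the camera lens, metres.
#' @slot pixelPitch detector pixel size in metres.
#' @slot minPixelsPerSpeckle minimum number of detector pixels per speckle.
#' @slot laserPower laser power in milliwatts.
#' @slot frameShape integer vector (rows, cols) of the recorded frames.
#' @slot fps frame rate in frames per second.
#' @slot bitDepth sensor bit depth (8, 10, 12 or 16).
#' @slot targetSpecklePx target speckle grain at native resolution, pixels.
#' @slot pxPerRadian simulator calibration: rendered pattern shift in pixels
#'   per radian of surface tilt (small-angle).
#' @seealso [opticalConfig()]
#' @export
setClass("OpticalConfig", representation(
  wavelength = "numeric", spotDiameter = "numeric", z2 = "numeric",
  z3 = "numeric", pixelPitch = "numeric", minPixelsPerSpeckle = "numeric",
  laserPower = "numeric", frameShape = "integer", fps = "numeric",
  bitDepth = "integer", targetSpecklePx = "numeric", pxPerRadian = "numeric"))

setValidity("OpticalConfig", function(object) {
  msg <- character()
  lens <- c(wavelength = object@wavelength, spotDiameter = object@spotDiameter,
            z2 = object@z2, z3 = object@z3, pixelPitch = object@pixelPitch,
            K = object@minPixelsPerSpeckle, fps = object@fps,
            pxPerRadian = object@pxPerRadian)
  if (any(!is.finite(lens)) || any(lens <= 0))
    msg <- c(msg, "all lengths, K, fps and pxPerRadian must be finite and > 0")
  if (object@laserPower < 0) msg <- c(msg, "laserPower must be >= 0")
  if (length(object@frameShape) != 2L || any(object@frameShape < 8L))
    msg <- c(msg, "frameShape must be two integers >= 8")
  if (!object@bitDepth %in% c(8L, 10L, 12L, 16L))
    msg <- c(msg, "bitDepth must be one of 8, 10, 12, 16")
  if (object@targetSpecklePx < 2)
    msg <- c(msg, "targetSpecklePx must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Random phase screen over an elliptical aperture
#'
#' Realizes the random far-field phase of a rough surface: phase values are
#' i.i.d. uniform on \eqn{[0, 2\pi)} inside an aperture whose linear extent is
#' `apertureFraction` of each grid dimension, and the field amplitude is zero
#' outside. The aperture fraction sets the rendered speckle grain
#' (grain in pixels is approximately `1.03 / apertureFraction`).
#'
#' @slot phase numeric matrix of phases in radians (zero outside aperture).
#' @slot aperture logical matrix marking the aperture support.
#' @slot apertureFraction fraction of each grid dimension spanned by the
#'   aperture.
#' @slot seed integer seed that generated the screen.
#' @seealso [makePhaseScreen()]
#' @export
setClass("PhaseScreen", representation(
  phase = "matrix", aperture = "matrix", apertureFraction = "numeric",
  seed = "integer"))

setValidity("PhaseScreen", function(object) {
  msg <- character()
  if (!identical(dim(object@phase), dim(object@aperture)))
    msg <- c(msg, "phase and aperture dimensions differ")
  if (object@apertureFraction <= 0 || object@apertureFraction > 1)
    msg <- c(msg, "apertureFraction must be in (0, 1]")
  inside <- object@phase[object@aperture]
  if (length(inside) && (any(inside < 0) || any(inside >= 2 * pi)))
    msg <- c(msg, "phases inside the aperture must lie in [0, 2*pi)")
  if (any(object@phase[!object@aperture] != 0))
    msg <- c(msg, "phase must be zero outside the aperture")
  if (length(msg)) msg else TRUE
})

#' Per-frame surface tilt series
#'
#' The tilt angles \eqn{(\alpha_x, \alpha_y)} of the illuminated surface,
#' one pair per frame, driving the lateral speckle shifts.
#'
#' @slot alphaX,alphaY tilt angles in radians, one per frame.
#' @slot fps frame rate the series is sampled at.
#' @seealso [generateTiltSeries()]
#' @export
setClass("TiltSeries", representation(
  alphaX = "numeric", alphaY = "numeric", fps = "numeric"))

setValidity("TiltSeries", function(object) {
  msg <- character()
  if (length(object@alphaX) != length(object@alphaY))
    msg <- c(msg, "alphaX and alphaY must have equal length")
  if (any(!is.finite(object@alphaX)) || any(!is.finite(object@alphaY)))
    msg <- c(msg, "tilt values must be finite")
  if (object@fps <= 0) msg <- c(msg, "fps must be > 0")
  if (length(msg)) msg else TRUE
})

#' Recorded (or simulated) speckle pattern video
#'
#' Quantized grayscale frames plus the recording metadata used downstream:
#' subject, session ("morning"/"afternoon"), illuminated region
#' ("wernicke"/"control") and stimulus class label.
#'
#' @slot frames numeric array (rows, cols, T) of quantized intensities.
#' @slot fps frames per second.
#' @slot bitDepth sensor bit depth.
#' @slot subjectId,sessionTag,regionTag,classLabel recording metadata.
#' @slot videoId unique identifier within a corpus.
#' @export
setClass("SpeckleVideo", representation(
  frames = "array", fps = "numeric", bitDepth = "integer",
  subjectId = "character", sessionTag = "character",
  regionTag = "character", classLabel = "character", videoId = "character"))

setValidity("SpeckleVideo", function(object) {
  msg <- character()
  if (length(dim(object@frames)) != 3L)
    msg <- c(msg, "frames must be a (rows, cols, T) array")
  maxval <- 2^object@bitDepth - 1
  rng <- range(object@frames)
  if (rng[1] < 0 || rng[2] > maxval)
    msg <- c(msg, sprintf("intensities must lie in [0, %d]", maxval))
  if (length(msg)) msg else TRUE
})

#' Class-conditioned micro-vibration signal parameters
#'
#' Parameters of the band-limited stochastic tilt model used as a synthetic
#' stand-in for the stimulus-locked cortical hemodynamic signature: a
#' band-pass carrier with a slow sinusoidal amplitude envelope, an onset
#' latency, and a broadband tilt noise floor shared by both classes.
#'
#' @slot classLabel "clear" or "incomprehensible".
#' @slot carrierBand two-element Hz interval of the micro-vibration carrier.
#' @slot envelopeRate slow amplitude-envelope frequency, Hz.
#' @slot envelopeLatency onset latency of the stimulus-locked component, s.
#' @slot amplitude carrier RMS tilt amplitude, radians.
#' @slot classSeparation effect size that scaled the between-class parameter
#'   offsets when the object was built (0 means identical distributions).
#' @slot noiseFloor broadband (class-independent) tilt RMS, radians.
#' @seealso [classSignalParams()], [defaultClassParams()]
#' @export
setClass("ClassSignalParams", representation(
  classLabel = "character", carrierBand = "numeric", envelopeRate = "numeric",
  envelopeLatency = "numeric", amplitude = "numeric",
  classSeparation = "numeric", noiseFloor = "numeric"))

setValidity("ClassSignalParams", function(object) {
  msg <- character()
  if (length(object@carrierBand) != 2L || any(object@carrierBand <= 0) ||
      diff(object@carrierBand) <= 0)
    msg <- c(msg, "carrierBand must be an increasing positive Hz interval")
  if (object@amplitude < 0 || object@noiseFloor < 0)
    msg <- c(msg, "amplitude and noiseFloor must be >= 0")
  if (object@classSeparation < 0)
    msg <- c(msg, "classSeparation must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Synthetic corpus specification
#'
#' Describes a full recording protocol: number of subjects, videos per class
#' per session, clip duration, frame rate, the session and region tags, the
#' per-subject nuisance ranges (camera gain and tilt-amplitude jitter) and
#' the master seed from which every video-level seed is derived.
#'
#' @slot nSubjects,videosPerClassPerSession,durationS,fps protocol counts.
#' @slot sessions,regions tag vectors (e.g. "morning"/"afternoon").
#' @slot subjectGainRange,tiltJitterRange per-subject nuisance ranges.
#' @slot masterSeed integer master seed.
#' @seealso [corpusSpec()], [generateCorpus()]
#' @export
setClass("CorpusSpec", representation(
  nSubjects = "integer", videosPerClassPerSession = "integer",
  durationS = "numeric", fps = "numeric", sessions = "character",
  regions = "character", subjectGainRange = "numeric",
  tiltJitterRange = "numeric", masterSeed = "integer"))

setValidity("CorpusSpec", function(object) {
  msg <- character()
  if (object@nSubjects < 1L || object@videosPerClassPerSession < 1L)
    msg <- c(msg, "counts must be positive")
  if (object@durationS <= 0) msg <- c(msg, "durationS must be > 0")
  if (!object@fps %in% c(500, 1000))
    msg <- c(msg, "supported frame rates are 500 and 1000 fps")
  if (length(object@sessions) < 1L) msg <- c(msg, "at least one session tag")
  if (length(msg)) msg else TRUE
})

#' Lazily materialized synthetic speckle corpus
#'
#' Holds the manifest (one row per video, with the derived seeds and
#' per-subject nuisance values), the generating specification, per-class and
#' control signal parameters and the optical configuration. Videos are
#' rendered on demand with [corpusVideo()] so the corpus itself stays small.
#'
#' @slot manifest data.frame with one row per video.
#' @slot spec the generating [CorpusSpec-class].
#' @slot classParams named list of [ClassSignalParams-class] (one per class).
#' @slot controlParams class-independent parameters for the control region.
#' @slot optics the [OpticalConfig-class] used for rendering.
#' @export
setClass("SpeckleCorpus", representation(
  manifest = "data.frame", spec = "CorpusSpec", classParams = "list",
  controlParams = "ClassSignalParams", optics = "OpticalConfig"))

#' Normalized chunk tensors with metadata
#'
#' The classifier's input unit: non-overlapping runs of `framesPerChunk`
#' consecutive downsampled frames, normalized to \eqn{[0, 1]}, with one
#' metadata row per chunk (source video, start frame, labels).
#'
#' @slot data numeric array (rows, cols, framesPerChunk, nChunks) in [0, 1].
#' @slot meta data.frame: videoId, subject, session, region, classLabel,
#'   chunkIndex (0-based within video), startFrame.
#' @slot framesPerChunk frames per chunk (40 by default upstream).
#' @export
setClass("ChunkSet", representation(
  data = "array", meta = "data.frame", framesPerChunk = "integer"))

setValidity("ChunkSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 4L) msg <- c(msg, "data must be a 4-d array")
  else {
    if (d[3] != object@framesPerChunk)
      msg <- c(msg, "third dimension must equal framesPerChunk")
    if (d[4] != nrow(object@meta))
      msg <- c(msg, "metadata rows must match number of chunks")
  }
  if (length(object@data) &&
      (min(object@data) < 0 || max(object@data) > 1))
    msg <- c(msg, "chunk values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Train/validation/test membership at the video level
#'
#' @slot name split identifier.
#' @slot train,validation,test video-id character vectors (pairwise disjoint).
#' @slot subjects list with train/validation/test subject vectors (empty for
#'   within-subject splits; populated and pairwise disjoint for
#'   cross-subject splits).
#' @slot seed seed used for the shuffle.
#' @export
setClass("SplitSpec", representation(
  name = "character", train = "character", validation = "character",
  test = "character", subjects = "list", seed = "integer"))

setValidity("SplitSpec", function(object) {
  msg <- character()
  if (length(intersect(object@train, object@validation)) ||
      length(intersect(object@train, object@test)) ||
      length(intersect(object@validation, object@test)))
    msg <- c(msg, "train/validation/test video sets must be disjoint")
  s <- object@subjects
  if (length(s) == 3L &&
      (length(intersect(s[[1]], s[[2]])) || length(intersect(s[[1]], s[[3]])) ||
       length(intersect(s[[2]], s[[3]]))))
    msg <- c(msg, "subject sets must be disjoint")
  if (length(msg)) msg else TRUE
})

#' Trained peephole ConvLSTM classifier
#'
#' Flat parameter vector (see the layout in `paramLayout()`), the network
#' dimensions, the batch-norm running statistics frozen at the selected
#' checkpoint, and the per-epoch training history.
#'
#' @slot params numeric parameter vector of the best checkpoint.
#' @slot dims integer vector (T, H, W, filters, kernel, denseUnits).
#' @slot bnMean,bnVar batch-norm running statistics at the checkpoint.
#' @slot netConfig,trainConfig the configurations used.
#' @slot history data.frame of per-epoch train/validation loss and accuracy.
#' @slot bestEpoch epoch of the retained checkpoint.
#' @export
setClass("ConvLSTMModel", representation(
  params = "numeric", dims = "integer", bnMean = "numeric", bnVar = "numeric",
  netConfig = "list", trainConfig = "list", history = "data.frame",
  bestEpoch = "integer"))

#' Confusion-matrix cell counts at a fixed threshold
#'
#' @slot TP,TN,FP,FN non-negative cell counts.
#' @slot threshold the probability threshold used (prediction is positive
#'   when p >= threshold).
#' @export
setClass("ConfusionCounts", representation(
  TP = "numeric", TN = "numeric", FP = "numeric", FN = "numeric",
  threshold = "numeric"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@TP, object@TN, object@FP, object@FN)
  if (any(v < 0) || any(v != round(v))) "counts must be non-negative integers"
  else TRUE
})

#' Full metric report for one evaluation
#'
#' Threshold metrics (precision, recall, accuracy, F1, Cohen's kappa) at the
#' stated threshold plus threshold-free ROC-AUC. Metrics whose denominator
#' is zero are reported as `NA` and flagged in `undefined`, never silently 0.
#'
#' @slot precision,recall,accuracy,f1,kappa,auc metric values (NA if
#'   undefined).
#' @slot counts the underlying [ConfusionCounts-class].
#' @slot n number of scored records.
#' @slot undefined names of metrics with zero denominators.
#' @export
setClass("MetricReport", representation(
  precision = "numeric", recall = "numeric", accuracy = "numeric",
  f1 = "numeric", kappa = "numeric", auc = "numeric",
  counts = "ConfusionCounts", n = "integer", undefined = "character"))
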