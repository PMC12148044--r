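#' Construct an optical acquisition configuration
#'
#' Defaults reproduce the study acquisition: a 532 nm laser forming a ~1 cm
#' spot, a defocused camera at \eqn{Z_2 = 200} mm with a 55 mm lens
#' (\eqn{Z_3}), 3.45 um detector pixels, 128 x 64 px 8-bit frames at
#' 1000 fps, and a native speckle grain of ~16 px. `pxPerRadian` is the
#' simulator's tilt-to-shift sensitivity: the rendered pattern translates by
#' `pxPerRadian * tan(alpha)` pixels per tilt component. It is a
#' self-consistent rendering constant (the camera-plane magnification of a
#' physical setup would play this role) chosen so the default micro-vibration
#' amplitudes produce on the order of one pixel of motion.
#'
#' @param wavelength laser wavelength (m).
#' @param spotDiameter illuminated spot diameter (m).
#' @param z2 surface to speckle-plane distance (m).
#' @param z3 speckle-plane to lens distance (m).
#' @param pixelPitch detector pixel size (m).
#' @param minPixelsPerSpeckle minimum detector pixels per speckle.
#' @param laserPower laser power (mW).
#' @param frameShape integer (rows, cols) of recorded frames.
#' @param fps frame rate (frames/s).
#' @param bitDepth sensor bit depth.
#' @param targetSpecklePx target speckle grain at native resolution (px).
#' @param pxPerRadian rendered pattern shift per radian of tilt (px/rad).
#' @return An [OpticalConfig-class] object.
#' @examples
#' cfg <- opticalConfig()
#' requiredFocalLength(cfg)
#' @export
opticalConfig <- function(wavelength = 532e-9, spotDiameter = 1e-2,
                          z2 = 0.2, z3 = 55e-3, pixelPitch = 3.45e-6,
                          minPixelsPerSpeckle = 2, laserPower = 4.5,
                          frameShape = c(128L, 64L), fps = 1000,
                          bitDepth = 8L, targetSpecklePx = 16,
                          pxPerRadian = 5000) {
  cfg <- new("OpticalConfig", wavelength = wavelength,
             spotDiameter = spotDiameter, z2 = z2, z3 = z3,
             pixelPitch = pixelPitch,
             minPixelsPerSpeckle = minPixelsPerSpeckle,
             laserPower = laserPower,
             frameShape = as.integer(frameShape), fps = fps,
             bitDepth = as.integer(bitDepth),
             targetSpecklePx = targetSpecklePx, pxPerRadian = pxPerRadian)
  ffmin <- farFieldMinDistance(spotDiameter, wavelength)
  if (z2 < ffmin)
    warning(sprintf(paste0(
      "z2 = %.3g m is below the far-field bound D^2/(4 lambda) = %.3g m; ",
      "a physical setup relies on camera defocus to reach the far-field ",
      "regime at such distances"), z2, ffmin), call. = FALSE)
  cfg
}

#' Linear phase factor induced by surface tilt
#'
#' The phase gradient across the illuminated spot produced by tilting the
#' surface by `alpha`: \eqn{\beta = 4\pi \tan(\alpha) / \lambda}, which for
#' small angles reduces to \eqn{4\pi\alpha/\lambda}. In the far field this
#' linear phase translates the speckle pattern rigidly.
#'
#' @param alpha surface tilt angle in radians; must satisfy |alpha| < pi/2.
#' @param wavelength laser wavelength in metres.
#' @return Phase gradient in rad/m.
#' @examples
#' phaseFactor(1e-6, 532e-9)
#' @export
phaseFactor <- function(alpha, wavelength) {
  if (any(!is.finite(alpha)) || any(abs(alpha) >= pi / 2))
    stop("alpha must be finite with |alpha| < pi/2", call. = FALSE)
  if (any(!is.finite(wavelength)) || any(wavelength <= 0))
    stop("wavelength must be finite and > 0", call. = FALSE)
  4 * pi * tan(alpha) / wavelength
}

#' Minimum distance for the far-field approximation
#'
#' The surface-to-observation distance must exceed \eqn{D^2 / (4\lambda)}
#' for the diffracted field to shift rigidly under tilt. Callers may compare
#' a configured `z2` against this bound; [opticalConfig()] warns (but does
#' not fail) when it is violated, since camera defocus creates an effective
#' far field at much shorter distances.
#'
#' @param spotDiameter illuminated spot diameter (m).
#' @param wavelength laser wavelength (m).
#' @return The minimum far-field distance in metres.
#' @examples
#' farFieldMinDistance(1e-3, 532e-9)
#' @export
farFieldMinDistance <- function(spotDiameter, wavelength) {
  if (any(spotDiameter <= 0) || any(wavelength <= 0) ||
      any(!is.finite(c(spotDiameter, wavelength))))
    stop("spotDiameter and wavelength must be finite and > 0", call. = FALSE)
  spotDiameter^2 / (4 * wavelength)
}

#' Required camera focal length for resolvable speckles
#'
#' \eqn{F = K \Delta x Z_3 D / (Z_2 \lambda)}: the focal length needed so
#' that each speckle covers at least `K` detector pixels.
#'
#' @param cfg an [OpticalConfig-class].
#' @return Focal length in metres.
#' @examples
#' requiredFocalLength(opticalConfig())
#' @export
requiredFocalLength <- function(cfg) {
  stopifnot(is(cfg, "OpticalConfig"))
  with(list(K = cfg@minPixelsPerSpeckle, dx = cfg@pixelPitch, z3 = cfg@z3,
            D = cfg@spotDiameter, z2 = cfg@z2, lam = cfg@wavelength),
       K * dx * z3 * D / (z2 * lam))
}

#' Power density over a circular laser spot
#'
#' @param power laser power in milliwatts.
#' @param spotDiameter spot diameter in metres.
#' @return Power density in mW/mm^2. The default acquisition (4.5 mW over a
#'   ~1 cm spot, area ~78.5 mm^2) gives ~0.057 mW/mm^2.
#' @examples
#' powerDensity(4.5, 1e-2)
#' @export
powerDensity <- function(power, spotDiameter) {
  if (any(power < 0)) stop("power must be >= 0", call. = FALSE)
  if (any(spotDiameter <= 0) || any(!is.finite(spotDiameter)))
    stop("spotDiameter must be finite and > 0", call. = FALSE)
  areaMm2 <- pi * (spotDiameter / 2)^2 * 1e6
  power / areaMm2
}

#' Aperture fraction that yields a given speckle grain
#'
#' For a hard elliptical aperture spanning fraction `a` of each grid
#' dimension, the FWHM of the far-field intensity autocorrelation is
#' approximately `1.03 / a` pixels, so `a = 1.03 / targetSpecklePx`.
#'
#' @param targetSpecklePx desired speckle grain in pixels (>= 2).
#' @return The aperture fraction.
#' @export
apertureFractionFor <- function(targetSpecklePx) {
  stopifnot(targetSpecklePx >= 2)
  1.03 / targetSpecklePx
}

#' Generate a random phase screen
#'
#' Draws i.i.d. uniform \eqn{[0, 2\pi)} phases over an elliptical aperture
#' spanning `apertureFraction` of each dimension of a `frameShape` grid.
#' Identical arguments (including seed) give bit-identical screens. Using an
#' aperture fraction of each dimension (rather than a fixed circle) keeps
#' the speckle grain isotropic on non-square sensors.
#'
#' @param frameShape integer (rows, cols) grid size.
#' @param apertureFraction fraction of each dimension spanned by the
#'   aperture, in (0, 1].
#' @param seed integer seed.
#' @return A [PhaseScreen-class].
#' @examples
#' scr <- makePhaseScreen(c(64L, 64L), 0.1, seed = 1)
#' @export
makePhaseScreen <- function(frameShape, apertureFraction, seed) {
  stopifnot(length(frameShape) == 2L, apertureFraction > 0,
            apertureFraction <= 1)
  nr <- as.integer(frameShape[1]); nc <- as.integer(frameShape[2])
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  ar <- apertureFraction * nr / 2; ac <- apertureFraction * nc / 2
  rr <- matrix(seq_len(nr), nr, nc)
  cm <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  aperture <- ((rr - cr) / ar)^2 + ((cm - cc) / ac)^2 <= 1
  if (sum(aperture) < 16L)
    stop("aperture too small: fewer than 16 phase samples", call. = FALSE)
  phase <- matrix(0, nr, nc)
  phase[aperture] <- withSeed(seed, runif(sum(aperture), 0, 2 * pi))
  new("PhaseScreen", phase = phase, aperture = aperture,
      apertureFraction = apertureFraction, seed = as.integer(seed))
}

# Complex aperture field of a screen (amplitude 1 inside, 0 outside).
screenField <- function(screen) {
  screen@aperture * exp(1i * screen@phase)
}

# Linear phase ramp worth (ky, kx) cycles across the grid; multiplying the
# aperture field by this ramp shifts the far-field pattern by (ky, kx)
# pixels along (rows, cols) -- the discrete Fourier shift theorem.
phaseRamp <- function(frameShape, kRow, kCol) {
  nr <- frameShape[1]; nc <- frameShape[2]
  exp(2i * pi * kRow * (0:(nr - 1)) / nr) %o%
    exp(2i * pi * kCol * (0:(nc - 1)) / nc)
}

#' Render one speckle frame for a given surface tilt
#'
#' The far-field intensity is the squared modulus of the 2-d DFT of the
#' aperture field multiplied by the tilt-induced linear phase ramp. A tilt
#' pair `(alphaX, alphaY)` produces a ramp worth
#' `pxPerRadian * tan(alpha)` cycles across the grid, hence a rigid
#' (circular) shift of the pattern by that many pixels along columns (x) and
#' rows (y); integer-cycle ramps shift the noiseless pattern exactly.
#' Intensities are scaled so the zero-tilt mean level sits at `level` of the
#' dynamic range (Parseval makes the mean exactly tilt-invariant), optional
#' shot and read noise are added, and the frame is quantized to the
#' configured bit depth.
#'
#' @param screen a [PhaseScreen-class] matching `cfg@frameShape`.
#' @param tilt numeric `(alphaX, alphaY)` in radians.
#' @param cfg an [OpticalConfig-class].
#' @param gain multiplicative intensity gain (camera-gain nuisance).
#' @param level zero-tilt mean intensity as a fraction of full scale.
#' @param noise `NULL` for a noiseless frame, or
#'   `list(photonsPerUnit =, readNoiseSd =)` for Poisson-like shot noise
#'   (Gaussian approximation with variance I/photonsPerUnit) plus additive
#'   Gaussian read noise in intensity units. Draws from the current RNG.
#' @return Numeric matrix of quantized intensities.
#' @export
renderFrame <- function(screen, tilt, cfg, gain = 1, level = 0.15,
                        noise = NULL) {
  stopifnot(is(screen, "PhaseScreen"), is(cfg, "OpticalConfig"))
  if (!identical(dim(screen@phase), as.integer(cfg@frameShape)))
    stop("screen and cfg frame shapes differ", call. = FALSE)
  stopifnotFinite(tilt, "tilt")
  kCol <- cfg@pxPerRadian * tan(tilt[1])
  kRow <- cfg@pxPerRadian * tan(tilt[2])
  fld <- screenField(screen) * phaseRamp(dim(screen@phase), kRow, kCol)
  I <- Mod(stats::fft(fld))^2
  maxval <- 2^cfg@bitDepth - 1
  # mean(|FFT|^2) over the grid equals the number of aperture samples
  scale <- gain * level * maxval / sum(screen@aperture)
  I <- I * scale
  if (!is.null(noise)) {
    I <- I + rnorm(length(I), sd = sqrt(pmax(I, 0) / noise$photonsPerUnit)) +
      rnorm(length(I), sd = noise$readNoiseSd)
    dim(I) <- dim(screen@phase)
  }
  matrix(pmin(pmax(round(I), 0), maxval), nrow(I), ncol(I))
}

#' Synthesize a speckle video from a tilt series
#'
#' Renders one frame per tilt sample over a fixed phase screen. With zero
#' noise and constant zero tilt all frames are identical; a linear tilt ramp
#' produces a linear displacement trajectory recoverable by
#' [displacementSeries()].
#'
#' @param tilts a [TiltSeries-class].
#' @param screen a [PhaseScreen-class].
#' @param cfg an [OpticalConfig-class].
#' @param subjectId,sessionTag,regionTag,classLabel,videoId metadata.
#' @param gain intensity gain nuisance.
#' @param noise noise model passed to [renderFrame()] (`NULL` disables).
#' @param seed seed for the noise draws (ignored when `noise` is `NULL`).
#' @return A [SpeckleVideo-class] with `length(tilts)` frames.
#' @export
synthesizeVideo <- function(tilts, screen, cfg, subjectId = "s1",
                            sessionTag = "morning", regionTag = "wernicke",
                            classLabel = "clear", videoId = "v1", gain = 1,
                            noise = list(photonsPerUnit = 10,
                                         readNoiseSd = 2),
                            seed = 1) {
  stopifnot(is(tilts, "TiltSeries"))
  nT <- length(tilts@alphaX)
  if (nT < 1) stop("tilt series is empty", call. = FALSE)
  shp <- cfg@frameShape
  frames <- array(0, c(shp[1], shp[2], nT))
  render <- function() {
    for (t in seq_len(nT))
      frames[, , t] <<- renderFrame(screen,
                                    c(tilts@alphaX[t], tilts@alphaY[t]),
                                    cfg, gain = gain, noise = noise)
  }
  if (is.null(noise)) render() else withSeed(seed, render())
  new("SpeckleVideo", frames = frames, fps = tilts@fps,
      bitDepth = cfg@bitDepth, subjectId = subjectId,
      sessionTag = sessionTag, regionTag = regionTag,
      classLabel = classLabel, videoId = videoId)
}

#' Estimate the speckle grain of a frame
#'
#' Measures the full width at half maximum of the radially averaged
#' autocorrelation of the mean-subtracted intensity (computed by
#' Wiener-Khinchin via the FFT, so with periodic boundary). By this
#' convention a single Gaussian blob of image FWHM `w` measures
#' `w * sqrt(2)`, and fully developed speckle from an aperture fraction `a`
#' measures approximately `1.03 / a` pixels. Invariant to global intensity
#' scaling and offsets.
#'
#' @param frame numeric intensity matrix (must not be constant).
#' @return Estimated speckle size in pixels.
#' @examples
#' scr <- makePhaseScreen(c(128L, 64L), apertureFractionFor(16), seed = 3)
#' measureSpeckleSize(renderFrame(scr, c(0, 0), opticalConfig()))
#' @export
measureSpeckleSize <- function(frame) {
  f <- frame - mean(frame)
  if (all(f == 0)) stop("frame is constant", call. = FALSE)
  ac <- Re(ifft2(Mod(stats::fft(f))^2))
  ac <- ac / ac[1, 1]
  nr <- nrow(ac); nc <- ncol(ac)
  # circular autocorrelation: lag 0 at [1, 1]; use wrapped radial lags
  lr <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  lc <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  r <- sqrt(outer(lr^2, lc^2, `+`))
  rmax <- floor(min(nr, nc) / 2)
  breaks <- seq(0, rmax, by = 0.5)
  bin <- cut(as.vector(r), breaks, right = FALSE, labels = FALSE)
  ok <- !is.na(bin)
  prof <- tapply(as.vector(ac)[ok], bin[ok], mean)
  rad <- breaks[as.integer(names(prof))] + 0.25
  below <- which(prof < 0.5)
  if (!length(below)) return(2 * max(rad))
  i2 <- below[1]
  if (i2 == 1) return(2 * rad[1])
  i1 <- i2 - 1
  rHalf <- rad[i1] + (0.5 - prof[i1]) * (rad[i2] - rad[i1]) /
    (prof[i2] - prof[i1])
  unname(2 * rHalf)
}
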