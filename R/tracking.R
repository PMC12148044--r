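# fftshift-style signed frequency indices for length n: 0, 1, ..., -1.
signedFreq <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n / 2 - 1 + (n %% 2), k, k - n)
}

#' Subpixel displacement between two frames by cross-correlation
#'
#' Normalized circular cross-correlation computed in the Fourier domain
#' (periodic boundary, matching the simulator's circular shifts). The
#' integer peak is refined by evaluating the cross-correlation on a local
#' grid of spacing `1/upsample` pixels via a matrix-multiply DFT around the
#' peak. Positive `dy`/`dx` mean `f2` is `f1` moved down rows / right
#' columns.
#'
#' @param f1,f2 equal-shape numeric matrices, neither constant.
#' @param upsample subpixel refinement factor (resolution `1/upsample` px).
#' @return Named vector `c(dx, dy, peak)` with the normalized correlation
#'   peak value (1 for identical frames).
#' @examples
#' scr <- makePhaseScreen(c(64L, 64L), 0.1, seed = 1)
#' cfg <- suppressWarnings(opticalConfig(frameShape = c(64L, 64L)))
#' f1 <- renderFrame(scr, c(0, 0), cfg)
#' frameCrossCorrelation(f1, f1)
#' @export
frameCrossCorrelation <- function(f1, f2, upsample = 20L) {
  if (!identical(dim(f1), dim(f2)))
    stop("frames must have identical shapes", call. = FALSE)
  a <- f1 - mean(f1); b <- f2 - mean(f2)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("constant frame", call. = FALSE)
  S <- stats::fft(b) * Conj(stats::fft(a))
  cc <- Re(ifft2(S))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  nr <- nrow(a); nc <- ncol(a)
  d0r <- signedFreq(nr)[pk[1]]
  d0c <- signedFreq(nc)[pk[2]]
  peak <- max(cc) / (na * nb)
  if (upsample > 1) {
    off <- seq(-1, 1, by = 1 / upsample)
    ur <- signedFreq(nr); uc <- signedFreq(nc)
    Er <- exp(2i * pi * outer(d0r + off, ur / nr))
    Ec <- exp(2i * pi * outer(uc / nc, d0c + off))
    ccUp <- Re(Er %*% S %*% Ec) / length(S)
    ipk <- which(ccUp == max(ccUp), arr.ind = TRUE)[1, ]
    d0r <- d0r + off[ipk[1]]
    d0c <- d0c + off[ipk[2]]
    peak <- max(ccUp) / (na * nb)
  }
  c(dx = unname(d0c), dy = unname(d0r), peak = unname(peak))
}

#' Frame-to-frame displacement trajectory of a video
#'
#' Cross-correlates consecutive frames and cumulates the per-step
#' displacements into a trajectory, the classical speckle-tracking
#' "displacement graph".
#'
#' @param video a [SpeckleVideo-class] with at least two frames.
#' @param upsample subpixel refinement factor per step.
#' @return data.frame with one row per frame transition: `frame, dx, dy,
#'   peak, cumX, cumY`.
#' @export
displacementSeries <- function(video, upsample = 10L) {
  nT <- dim(video@frames)[3]
  if (nT < 2) stop("need at least two frames", call. = FALSE)
  steps <- vapply(seq_len(nT - 1), function(t)
    frameCrossCorrelation(video@frames[, , t], video@frames[, , t + 1],
                          upsample = upsample), numeric(3))
  data.frame(frame = seq_len(nT - 1), dx = steps["dx", ], dy = steps["dy", ],
             peak = steps["peak", ], cumX = cumsum(steps["dx", ]),
             cumY = cumsum(steps["dy", ]))
}
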