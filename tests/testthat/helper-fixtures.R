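# Shared fixtures, built lazily and cached for the whole test run so the
# expensive corpora are rendered only once.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# Default optics on the native 128 x 64 sensor (far-field warning silenced:
# the default geometry deliberately relies on defocus).
fixtureOptics <- function() fixture("optics", function()
  suppressWarnings(opticalConfig()))

fixtureScreen <- function() fixture("screen", function()
  makePhaseScreen(c(128L, 64L), apertureFractionFor(16), seed = 5))

fixtureRefFrame <- function() fixture("refFrame", function()
  renderFrame(fixtureScreen(), c(0, 0), fixtureOptics()))

# One-subject corpus at the default operating separation.
fixtureCorpus1 <- function() fixture("corpus1", function()
  generateCorpus(corpusSpec(nSubjects = 1, masterSeed = 3)))

fixtureChunks1 <- function() fixture("chunks1", function()
  corpusChunks(fixtureCorpus1(), c(16L, 16L)))

# Circular shift: content moves down `dr` rows and right `dc` columns.
circShift <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  m[((seq_len(nr) - 1 - dr) %% nr) + 1, ((seq_len(nc) - 1 - dc) %% nc) + 1]
}

# Tilt angle that imposes a shift of `px` pixels in the rendered pattern.
tiltForPx <- function(px, cfg) atan(px / cfg@pxPerRadian)

# Independent scalar peephole-LSTM recurrence (the oracle for the
# 1x1-kernel, 1x1-grid, single-filter ConvLSTM).
scalarPeepholeLSTM <- function(xs, w) {
  h <- 0; cc <- 0
  H <- C <- numeric(length(xs))
  for (t in seq_along(xs)) {
    i <- 1 / (1 + exp(-(w$wxi * xs[t] + w$whi * h + w$wci * cc + w$bi)))
    f <- 1 / (1 + exp(-(w$wxf * xs[t] + w$whf * h + w$wcf * cc + w$bf)))
    cNew <- f * cc + i * tanh(w$wxc * xs[t] + w$whc * h + w$bc)
    o <- 1 / (1 + exp(-(w$wxo * xs[t] + w$who * h + w$wco * cNew + w$bo)))
    h <- o * tanh(cNew); cc <- cNew
    H[t] <- h; C[t] <- cc
  }
  list(H = H, C = C)
}

# Map a flat parameter vector of the scalar configuration to oracle weights.
scalarWeightsFromParams <- function(p, dims) {
  L <- speckleSense:::paramLayout(dims)
  list(wxi = p[L$oWx + 1], wxf = p[L$oWx + 2], wxc = p[L$oWx + 3],
       wxo = p[L$oWx + 4],
       whi = p[L$oWh + 1], whf = p[L$oWh + 2], whc = p[L$oWh + 3],
       who = p[L$oWh + 4],
       wci = p[L$oPe + 1], wcf = p[L$oPe + 2], wco = p[L$oPe + 3],
       bi = p[L$oB + 1], bf = p[L$oB + 2], bc = p[L$oB + 3], bo = p[L$oB + 4])
}

# Toy linearly separable chunk set: the class is a mean-intensity offset.
toyChunks <- function(n = 40, tt = 10L, h = 8L, w = 8L, seed = 1) {
  withr::local_seed(seed)
  data <- array(0, c(h, w, tt, n))
  lab <- rep(c("clear", "incomprehensible"), length.out = n)
  for (i in seq_len(n)) {
    base <- if (lab[i] == "clear") 0.7 else 0.3
    data[, , , i] <- pmin(pmax(base + array(rnorm(h * w * tt, sd = 0.05),
                                            c(h, w, tt)), 0), 1)
  }
  meta <- data.frame(videoId = sprintf("toy%03d", seq_len(n)),
                     subject = "s01", session = "morning",
                     region = "wernicke", classLabel = lab,
                     chunkIndex = 0L, startFrame = 0L,
                     stringsAsFactors = FALSE)
  new("ChunkSet", data = data, meta = meta, framesPerChunk = tt)
}

toySplit <- function(chunks, nVal = 10) {
  ids <- chunkMeta(chunks)$videoId
  n <- length(ids)
  new("SplitSpec", name = "toy", train = ids[seq_len(n - nVal)],
      validation = ids[(n - nVal + 1):n], test = character(),
      subjects = list(), seed = 1L)
}
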