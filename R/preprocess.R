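# Bilinear interpolation weight matrix mapping nIn samples to nOut, with
# center-aligned pixel coordinates (target center (i+0.5)*nIn/nOut - 0.5 in
# source coordinates, clamped at the edges). Rows sum to one, so constant
# and affine inputs are reproduced exactly.
bilinearWeights <- function(nIn, nOut) {
  W <- matrix(0, nOut, nIn)
  pos <- ((seq_len(nOut) - 0.5) * nIn / nOut) - 0.5
  pos <- pmin(pmax(pos, 0), nIn - 1)
  lo <- floor(pos)
  frac <- pos - lo
  for (i in seq_len(nOut)) {
    j <- lo[i] + 1
    W[i, j] <- W[i, j] + (1 - frac[i])
    if (frac[i] > 0) W[i, j + 1] <- W[i, j + 1] + frac[i]
  }
  W
}

#' Downsample a frame by bilinear interpolation
#'
#' Separable bilinear resampling to `target` resolution with center-aligned
#' pixel grids. Deterministic; reproduces constant and affine frames
#' exactly, and preserves the speckle pattern's motion dynamics (a rigid
#' shift of the input appears as the shift scaled by the resolution ratio).
#'
#' @param frame numeric matrix, at least as large as `target`.
#' @param target integer (rows, cols), default `c(32, 32)`.
#' @return The resampled `target[1] x target[2]` matrix.
#' @examples
#' downsampleFrame(matrix(runif(128 * 64), 128, 64), c(32, 32))
#' @export
downsampleFrame <- function(frame, target = c(32, 32)) {
  if (nrow(frame) < target[1] || ncol(frame) < target[2])
    stop("frame is smaller than the target resolution", call. = FALSE)
  Wr <- bilinearWeights(nrow(frame), target[1])
  Wc <- bilinearWeights(ncol(frame), target[2])
  Wr %*% frame %*% t(Wc)
}

#' Normalize chunk intensities to [0, 1]
#'
#' Max-range scaling: divide by `2^bitDepth - 1`. Per-chunk standardization
#' is deliberately not used, so cross-chunk intensity nuisance (camera gain)
#' survives normalization.
#'
#' @param x numeric array of raw intensities.
#' @param bitDepth container bit depth.
#' @return `x / (2^bitDepth - 1)`.
#' @export
normalizeChunk <- function(x, bitDepth) {
  maxval <- 2^bitDepth - 1
  if (min(x) < 0 || max(x) > maxval)
    stop("intensities outside the container range", call. = FALSE)
  x / maxval
}

#' Split a video into normalized non-overlapping chunks
#'
#' Downsamples every frame to `targetShape`, normalizes to \eqn{[0, 1]} and
#' groups `framesPerChunk` consecutive frames per chunk, in temporal order,
#' dropping any trailing remainder. 100,000 frames yield 2,500 forty-frame
#' chunks.
#'
#' @param video a [SpeckleVideo-class].
#' @param framesPerChunk frames per chunk (default 40).
#' @param targetShape downsampled (rows, cols), default `c(32, 32)`.
#' @return A [ChunkSet-class]; `startFrame` is a multiple of
#'   `framesPerChunk` (0-based).
#' @export
chunkVideo <- function(video, framesPerChunk = 40L,
                       targetShape = c(32L, 32L)) {
  stopifnot(is(video, "SpeckleVideo"), framesPerChunk >= 1)
  nT <- dim(video@frames)[3]
  if (nT < 1) stop("video has no frames", call. = FALSE)
  nChunk <- nT %/% framesPerChunk
  h <- targetShape[1]; w <- targetShape[2]
  Wr <- bilinearWeights(dim(video@frames)[1], h)
  Wc <- t(bilinearWeights(dim(video@frames)[2], w))
  nUsed <- nChunk * framesPerChunk
  data <- array(0, c(h, w, framesPerChunk, nChunk))
  maxval <- 2^video@bitDepth - 1
  for (t in seq_len(nUsed)) {
    ch <- (t - 1) %/% framesPerChunk + 1
    fr <- (t - 1) %% framesPerChunk + 1
    data[, , fr, ch] <- (Wr %*% video@frames[, , t] %*% Wc) / maxval
  }
  meta <- data.frame(
    videoId = rep(video@videoId, nChunk),
    subject = rep(video@subjectId, nChunk),
    session = rep(video@sessionTag, nChunk),
    region = rep(video@regionTag, nChunk),
    classLabel = rep(video@classLabel, nChunk),
    chunkIndex = seq_len(nChunk) - 1L,
    startFrame = (seq_len(nChunk) - 1L) * as.integer(framesPerChunk),
    stringsAsFactors = FALSE)
  new("ChunkSet", data = data, meta = meta,
      framesPerChunk = as.integer(framesPerChunk))
}

#' Number of chunks in a chunk set
#' @param chunks a [ChunkSet-class].
#' @return Integer count.
#' @export
nChunks <- function(chunks) nrow(chunks@meta)

#' Chunk metadata accessor
#' @param chunks a [ChunkSet-class].
#' @return The metadata data.frame.
#' @export
chunkMeta <- function(chunks) chunks@meta

#' Subset a chunk set
#' @param chunks a [ChunkSet-class].
#' @param idx integer or logical index over chunks.
#' @return The subset [ChunkSet-class].
#' @export
chunkSubset <- function(chunks, idx) {
  new("ChunkSet", data = chunks@data[, , , idx, drop = FALSE],
      meta = chunks@meta[idx, , drop = FALSE],
      framesPerChunk = chunks@framesPerChunk)
}

#' Combine chunk sets
#' @param ... [ChunkSet-class] objects with identical chunk geometry.
#' @return The concatenated [ChunkSet-class].
#' @export
combineChunks <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !is(sets[[1]], "ChunkSet"))
    sets <- sets[[1]]
  dims <- dim(sets[[1]]@data)[1:3]
  for (s in sets) stopifnot(identical(dim(s@data)[1:3], dims))
  n <- sum(vapply(sets, nChunks, 1L))
  data <- array(0, c(dims, n))
  at <- 0L
  for (s in sets) {
    k <- nChunks(s)
    if (k > 0) data[, , , at + seq_len(k)] <- s@data
    at <- at + k
  }
  new("ChunkSet", data = data,
      meta = do.call(rbind, lapply(sets, chunkMeta)),
      framesPerChunk = sets[[1]]@framesPerChunk)
}

#' Materialize and chunk an entire corpus
#'
#' Renders each manifest video in turn (videos are never all held in
#' memory), downsamples, normalizes and chunks it.
#'
#' @param corpus a [SpeckleCorpus-class].
#' @param targetShape downsampled (rows, cols) per frame.
#' @param framesPerChunk frames per chunk.
#' @param noise noise model forwarded to [corpusVideo()].
#' @return A [ChunkSet-class] covering the whole corpus.
#' @export
corpusChunks <- function(corpus, targetShape = c(32L, 32L),
                         framesPerChunk = 40L,
                         noise = list(photonsPerUnit = 10, readNoiseSd = 2)) {
  sets <- lapply(corpus@manifest$videoId, function(v)
    chunkVideo(corpusVideo(corpus, v, noise = noise),
               framesPerChunk = framesPerChunk, targetShape = targetShape))
  combineChunks(sets)
}

#' Within-subject split: morning 80/20, afternoon test
#'
#' Morning videos of one subject are shuffled (per class, keeping the split
#' balanced) and divided between training and validation at video
#' granularity; all afternoon videos go to the test set. No video appears
#' in two sets.
#'
#' @param x a [SpeckleCorpus-class] or manifest data.frame.
#' @param subject subject id (e.g. `"s01"`).
#' @param seed shuffle seed.
#' @param trainFraction fraction of morning videos used for training
#'   (default 0.8).
#' @param region restrict to one region tag (default `"wernicke"`).
#' @return A [SplitSpec-class].
#' @export
buildWithinSubjectSplit <- function(x, subject, seed = 1,
                                    trainFraction = 0.8,
                                    region = "wernicke") {
  m <- if (is(x, "SpeckleCorpus")) x@manifest else x
  m <- m[m$subject == subject & m$region == region, , drop = FALSE]
  if (!all(c("morning", "afternoon") %in% m$session))
    stop("subject lacks a morning or afternoon session", call. = FALSE)
  morning <- m[m$session == "morning", ]
  train <- character(); val <- character()
  for (cl in unique(morning$classLabel)) {
    ids <- morning$videoId[morning$classLabel == cl]
    ids <- withSeed(mixSeed(seed, match(cl, sort(unique(morning$classLabel)))),
                    sample(ids))
    nTr <- max(1L, min(length(ids) - 1L, round(trainFraction * length(ids))))
    train <- c(train, ids[seq_len(nTr)])
    val <- c(val, ids[-seq_len(nTr)])
  }
  new("SplitSpec", name = paste0("within_", subject), train = train,
      validation = val, test = m$videoId[m$session == "afternoon"],
      subjects = list(), seed = as.integer(seed))
}

#' Cross-subject splits: two subjects per role, with coverage
#'
#' Builds `nSplits` splits over the first six subjects (sorted), each
#' assigning two subjects to training, two to validation and two to test,
#' subject-disjoint within each split. The assignments are rotations of one
#' seeded permutation, so across the default five splits every subject
#' appears in the training role and in the test role at least once.
#'
#' @param x a [SpeckleCorpus-class] or manifest data.frame.
#' @param nSplits number of splits (default 5).
#' @param seed permutation seed.
#' @param region region tag to use.
#' @return List of [SplitSpec-class] objects.
#' @export
buildCrossSubjectSplits <- function(x, nSplits = 5L, seed = 1,
                                    region = "wernicke") {
  m <- if (is(x, "SpeckleCorpus")) x@manifest else x
  m <- m[m$region == region, , drop = FALSE]
  subjects <- sort(unique(m$subject))
  if (length(subjects) < 6L)
    stop("cross-subject splits require at least 6 subjects", call. = FALSE)
  base <- withSeed(seed, sample(subjects[1:6]))
  lapply(seq_len(nSplits), function(k) {
    rot <- base[((seq_len(6) + (k - 1) - 1) %% 6) + 1]
    roles <- list(train = rot[1:2], validation = rot[3:4], test = rot[5:6])
    ids <- lapply(roles, function(s) m$videoId[m$subject %in% s])
    new("SplitSpec", name = sprintf("xsub_%d", k), train = ids$train,
        validation = ids$validation, test = ids$test, subjects = roles,
        seed = as.integer(seed))
  })
}

#' Assert a split leaks no videos (or subjects) between sets
#'
#' @param split a [SplitSpec-class].
#' @param m optional manifest; when given, subject-level disjointness is
#'   also checked for splits carrying subject roles.
#' @return `TRUE` invisibly; stops on leakage.
#' @export
assertNoLeakage <- function(split, m = NULL) {
  sets <- list(split@train, split@validation, split@test)
  for (i in 1:2) for (j in (i + 1):3)
    if (length(intersect(sets[[i]], sets[[j]])))
      stop("video-level leakage between split sets", call. = FALSE)
  if (!is.null(m) && length(split@subjects) == 3L) {
    subjOf <- function(ids) unique(m$subject[m$videoId %in% ids])
    ss <- lapply(sets, subjOf)
    for (i in 1:2) for (j in (i + 1):3)
      if (length(intersect(ss[[i]], ss[[j]])))
        stop("subject-level leakage between split sets", call. = FALSE)
  }
  invisible(TRUE)
}

#' Partition chunks by a split
#'
#' @param chunks a [ChunkSet-class].
#' @param split a [SplitSpec-class].
#' @return List of [ChunkSet-class]: train, validation, test.
#' @export
splitChunks <- function(chunks, split) {
  m <- chunkMeta(chunks)
  list(train = chunkSubset(chunks, m$videoId %in% split@train),
       validation = chunkSubset(chunks, m$videoId %in% split@validation),
       test = chunkSubset(chunks, m$videoId %in% split@test))
}
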