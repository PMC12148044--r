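# Direct (non-separable) bilinear resampler used as an independent oracle
# for the packaged separable implementation.
naiveBilinear <- function(frame, target) {
  H <- nrow(frame); W <- ncol(frame)
  out <- matrix(0, target[1], target[2])
  for (i in seq_len(target[1])) {
    for (j in seq_len(target[2])) {
      y <- min(max((i - 0.5) * H / target[1] - 0.5, 0), H - 1)
      x <- min(max((j - 0.5) * W / target[2] - 0.5, 0), W - 1)
      y0 <- floor(y); x0 <- floor(x)
      fy <- y - y0; fx <- x - x0
      y1 <- min(y0 + 1, H - 1); x1 <- min(x0 + 1, W - 1)
      out[i, j] <- (1 - fy) * (1 - fx) * frame[y0 + 1, x0 + 1] +
        (1 - fy) * fx * frame[y0 + 1, x1 + 1] +
        fy * (1 - fx) * frame[y1 + 1, x0 + 1] +
        fy * fx * frame[y1 + 1, x1 + 1]
    }
  }
  out
}

test_that("bilinear downsampling is exact on constants and affine ramps", {
  expect_equal(downsampleFrame(matrix(3.7, 64, 64), c(32, 32)),
               matrix(3.7, 32, 32))
  ramp <- outer(seq_len(64), seq_len(64), function(r, c) 2 * r + 0.5 * c)
  down <- downsampleFrame(ramp, c(32, 32))
  # interior of a 2x downscale of an affine function is affine with the
  # same gradients scaled by the resolution ratio
  expect_equal(down[2:31, 2:31],
               outer(2:31, 2:31, function(r, c) {
                 rr <- (r - 0.5) * 2 - 0.5 + 1
                 cc <- (c - 0.5) * 2 - 0.5 + 1
                 2 * rr + 0.5 * cc
               }))
  expect_error(downsampleFrame(matrix(0, 16, 16), c(32, 32)), "smaller")
})

test_that("downsampling matches an independent bilinear oracle", {
  checker <- outer(seq_len(128), seq_len(64),
                   function(r, c) as.numeric((r + c) %% 2 == 0))
  expect_equal(downsampleFrame(checker, c(32, 32)),
               naiveBilinear(checker, c(32, 32)), tolerance = 1e-6)
  withr::local_seed(1)
  noise <- matrix(runif(128 * 64), 128, 64)
  expect_equal(downsampleFrame(noise, c(32, 32)),
               naiveBilinear(noise, c(32, 32)), tolerance = 1e-6)
})

test_that("downsampling preserves motion dynamics", {
  cfg <- fixtureOptics()
  scr <- fixtureScreen()
  f0 <- fixtureRefFrame()
  f1 <- renderFrame(scr, c(tiltForPx(6, cfg), 0), cfg)
  native <- frameCrossCorrelation(f0, f1, upsample = 20)
  d0 <- downsampleFrame(f0, c(32, 32))
  d1 <- downsampleFrame(f1, c(32, 32))
  small <- frameCrossCorrelation(d0, d1, upsample = 20)
  ratio <- ncol(f0) / 32  # 2x per axis in columns, 4x in rows
  expect_equal(unname(small["dx"]) * ratio, unname(native["dx"]),
               tolerance = 0.2 * abs(unname(native["dx"])))
})

test_that("chunking drops remainders and conserves counts", {
  mk <- function(nT) new("SpeckleVideo",
                         frames = array(sample(0:255, 8 * 8 * nT,
                                               replace = TRUE),
                                        c(8, 8, nT)),
                         fps = 500, bitDepth = 8L, subjectId = "s01",
                         sessionTag = "morning", regionTag = "wernicke",
                         classLabel = "clear", videoId = "v")
  expect_equal(nChunks(chunkVideo(mk(39), 40L, c(8L, 8L))), 0)
  ch <- chunkVideo(mk(85), 40L, c(8L, 8L))
  expect_equal(nChunks(ch), 2)
  expect_equal(chunkMeta(ch)$startFrame, c(0L, 40L))
  expect_true(all(chunkMeta(ch)$startFrame %% 40 == 0))
  # count conservation across videos
  lens <- c(85, 120, 40, 39, 200)
  total <- sum(vapply(lens, function(nT)
    nChunks(chunkVideo(mk(nT), 40L, c(8L, 8L))), 1L))
  expect_equal(total, sum(lens %/% 40))
  # chunks inherit video metadata and values are normalized
  expect_true(all(chunkMeta(ch)$classLabel == "clear"))
  expect_true(min(ch@data) >= 0 && max(ch@data) <= 1)
})

test_that("normalization is exact max-range scaling", {
  z <- array(0, c(2, 2, 3))
  expect_identical(normalizeChunk(z, 8L), z)
  expect_equal(normalizeChunk(array(255, c(2, 2, 3)), 8L),
               array(1, c(2, 2, 3)))
  expect_equal(normalizeChunk(array(128, c(1, 1, 1)), 8L)[1], 128 / 255)
  expect_error(normalizeChunk(array(300, c(1, 1, 1)), 8L), "range")
})

test_that("within-subject splits are balanced, disjoint and seeded", {
  spec <- corpusSpec(nSubjects = 1, videosPerClassPerSession = 10,
                     masterSeed = 2)
  corp <- generateCorpus(spec)
  sp <- buildWithinSubjectSplit(corp, "s01", seed = 3)
  m <- manifest(corp)
  # 10 morning videos per class -> 8 train + 2 validation per class
  for (cl in c("clear", "incomprehensible")) {
    ids <- m$videoId[m$session == "morning" & m$classLabel == cl]
    expect_length(intersect(sp@train, ids), 8)
    expect_length(intersect(sp@validation, ids), 2)
  }
  expect_setequal(sp@test, m$videoId[m$session == "afternoon"])
  # disjointness holds for every seed
  for (s in 1:100) {
    spk <- buildWithinSubjectSplit(corp, "s01", seed = s)
    expect_silent(assertNoLeakage(spk))
    expect_length(c(spk@train, spk@validation, spk@test), nrow(m))
  }
  expect_identical(buildWithinSubjectSplit(corp, "s01", seed = 3),
                   buildWithinSubjectSplit(corp, "s01", seed = 3))
  # missing session errors
  mo <- generateCorpus(corpusSpec(nSubjects = 1, sessions = "morning"))
  expect_error(buildWithinSubjectSplit(mo, "s01"), "session")
})

test_that("cross-subject splits partition subjects 2/2/2 with coverage", {
  spec <- corpusSpec(nSubjects = 6, videosPerClassPerSession = 1,
                     masterSeed = 4)
  corp <- generateCorpus(spec)
  splits <- buildCrossSubjectSplits(corp, 5L, seed = 2)
  expect_length(splits, 5)
  m <- manifest(corp)
  inTrain <- character(); inTest <- character()
  for (sp in splits) {
    roles <- sp@subjects
    expect_length(roles$train, 2)
    expect_length(roles$validation, 2)
    expect_length(roles$test, 2)
    expect_setequal(unlist(roles), unique(m$subject))
    expect_silent(assertNoLeakage(sp, m))
    inTrain <- union(inTrain, roles$train)
    inTest <- union(inTest, roles$test)
  }
  expect_setequal(inTrain, unique(m$subject))
  expect_setequal(inTest, unique(m$subject))
  few <- generateCorpus(corpusSpec(nSubjects = 3,
                                   videosPerClassPerSession = 1))
  expect_error(buildCrossSubjectSplits(few), "6 subjects")
})
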