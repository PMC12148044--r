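#' Experiment configuration
#'
#' Bundles everything needed to replicate one of the three experiment
#' designs end to end on a synthetic corpus.
#'
#' @param kind one of `"within_subject"`, `"control_region"`,
#'   `"cross_subject"`.
#' @param corpusSpec a [CorpusSpec-class] (regions must include "control"
#'   for the control experiment).
#' @param classSeparation effect size for [defaultClassParams()].
#' @param net a [netConfig()].
#' @param train a [trainConfig()].
#' @param targetShape chunk spatial resolution.
#' @param chunksPerGroup aggregation group size; `NULL` uses one second of
#'   chunks, `floor(fps / framesPerChunk)`.
#' @param masterSeed master seed for training-run seeds.
#' @return A list of class `"experimentConfig"`.
#' @export
experimentConfig <- function(kind = c("within_subject", "control_region",
                                      "cross_subject"),
                             corpusSpec = speckleSense::corpusSpec(),
                             classSeparation = 1, net = netConfig(),
                             train = trainConfig(),
                             targetShape = c(16L, 16L),
                             chunksPerGroup = NULL, masterSeed = 1L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, corpusSpec = corpusSpec,
                 classSeparation = classSeparation, net = net,
                 train = train, targetShape = as.integer(targetShape),
                 chunksPerGroup = chunksPerGroup,
                 masterSeed = as.integer(masterSeed)),
            class = "experimentConfig")
}

defaultGroupSize <- function(fps, framesPerChunk = 40L)
  max(1L, as.integer(fps) %/% as.integer(framesPerChunk))

# Train on one split and report per-chunk and aggregated metrics.
fitAndReport <- function(chunks, split, net, tc, chunksPerGroup) {
  model <- trainConvLSTM(chunks, split, net, tc)
  preds <- predictChunks(model, splitChunks(chunks, split)$test)
  agg <- aggregateOverSecond(preds, chunksPerGroup)
  list(model = model, split = split, predictions = preds,
       reportChunk = metricReport(preds),
       reportAggregated = metricReport(agg))
}

#' Within-subject experiment: one model per subject
#'
#' For every subject, trains on the shuffled 80/20 morning videos and tests
#' on the afternoon videos of the same subject, reporting per-chunk and
#' 1-s-aggregated metrics.
#'
#' @param corpus a [SpeckleCorpus-class] with morning and afternoon
#'   sessions.
#' @param chunks optional precomputed [ChunkSet-class] for `corpus`
#'   (computed at `targetShape` when omitted).
#' @param net,train network and training configuration.
#' @param targetShape chunk resolution when `chunks` is omitted.
#' @param chunksPerGroup aggregation group size (`NULL`: one second).
#' @param seed seed for split shuffles and training.
#' @return Named list (one entry per subject) of results: the trained
#'   model, split, predictions and [MetricReport-class] pair.
#' @export
runWithinSubject <- function(corpus, chunks = NULL, net = netConfig(),
                             train = trainConfig(),
                             targetShape = c(16L, 16L),
                             chunksPerGroup = NULL, seed = 1) {
  spec <- corpus@spec
  if (!all(c("morning", "afternoon") %in% spec@sessions))
    stop("corpus lacks morning/afternoon sessions", call. = FALSE)
  if (is.null(chunks)) chunks <- corpusChunks(corpus, targetShape)
  if (is.null(chunksPerGroup)) chunksPerGroup <- defaultGroupSize(spec@fps)
  cm <- chunkMeta(chunks)
  chunks <- chunkSubset(chunks, cm$region == "wernicke")
  subjects <- sort(unique(chunkMeta(chunks)$subject))
  out <- lapply(seq_along(subjects), function(i) {
    split <- buildWithinSubjectSplit(corpus, subjects[i],
                                     seed = mixSeed(seed, i))
    assertNoLeakage(split)
    tc <- train; tc$seed <- mixSeed(seed, i, 17)
    fitAndReport(chunks, split, net, tc, chunksPerGroup)
  })
  names(out) <- subjects
  out
}

#' Control-region experiment
#'
#' Two negative controls on the class-independent ("forehead") corpus:
#' (a) the Wernicke-trained within-subject model evaluated on the control
#' chunks of the same subject, and (b) a model trained and tested entirely
#' on control chunks with the within-subject protocol. Both are expected
#' near chance on synthetic data, and aggregation should not lift them.
#'
#' @param corpus a [SpeckleCorpus-class] whose regions include "control".
#' @param subject subject to run the control on (default: first).
#' @param chunks optional precomputed [ChunkSet-class].
#' @param net,train,targetShape,chunksPerGroup,seed as in
#'   [runWithinSubject()].
#' @return List with `transfer` (Wernicke model on control chunks:
#'   predictions and reports) and `controlTrained` (the control-trained
#'   result in [runWithinSubject()] format).
#' @export
runControlRegion <- function(corpus, subject = NULL, chunks = NULL,
                             net = netConfig(), train = trainConfig(),
                             targetShape = c(16L, 16L),
                             chunksPerGroup = NULL, seed = 1) {
  if (!"control" %in% corpus@spec@regions)
    stop("corpus has no control region", call. = FALSE)
  if (is.null(subject)) subject <- corpus@manifest$subject[1]
  if (is.null(chunks)) chunks <- corpusChunks(corpus, targetShape)
  if (is.null(chunksPerGroup))
    chunksPerGroup <- defaultGroupSize(corpus@spec@fps)
  cm <- chunkMeta(chunks)
  sub <- chunkSubset(chunks, cm$subject == subject)
  sm <- chunkMeta(sub)

  wSplit <- buildWithinSubjectSplit(corpus, subject, seed = mixSeed(seed, 1),
                                    region = "wernicke")
  tcW <- train; tcW$seed <- mixSeed(seed, 2)
  wern <- fitAndReport(chunkSubset(sub, sm$region == "wernicke"), wSplit,
                       net, tcW, chunksPerGroup)

  ctrl <- chunkSubset(sub, sm$region == "control")
  ctrlPreds <- predictChunks(wern$model, ctrl)
  transfer <- list(predictions = ctrlPreds,
                   reportChunk = metricReport(ctrlPreds),
                   reportAggregated = metricReport(
                     aggregateOverSecond(ctrlPreds, chunksPerGroup)))

  cSplit <- buildWithinSubjectSplit(corpus, subject, seed = mixSeed(seed, 3),
                                    region = "control")
  tcC <- train; tcC$seed <- mixSeed(seed, 4)
  controlTrained <- fitAndReport(ctrl, cSplit, net, tcC, chunksPerGroup)

  list(wernicke = wern, transfer = transfer,
       controlTrained = controlTrained)
}

#' Cross-subject generalization experiment
#'
#' Trains one model per cross-subject split (two subjects each in train,
#' validation and test), reports per-chunk and aggregated AUC per split,
#' and evaluates the averaged ensemble of the split models on held-out
#' subjects (those beyond the first six) when present.
#'
#' @param corpus a [SpeckleCorpus-class] with at least six subjects.
#' @param chunks optional precomputed [ChunkSet-class].
#' @param nSplits number of splits (default 5).
#' @param net,train,targetShape,chunksPerGroup,seed as in
#'   [runWithinSubject()].
#' @return List with per-split results (`splits`) and, when held-out
#'   subjects exist, the `ensemble` predictions and reports.
#' @export
runCrossSubject <- function(corpus, chunks = NULL, nSplits = 5L,
                            net = netConfig(), train = trainConfig(),
                            targetShape = c(16L, 16L),
                            chunksPerGroup = NULL, seed = 1) {
  if (is.null(chunks)) chunks <- corpusChunks(corpus, targetShape)
  if (is.null(chunksPerGroup))
    chunksPerGroup <- defaultGroupSize(corpus@spec@fps)
  cm <- chunkMeta(chunks)
  chunks <- chunkSubset(chunks, cm$region == "wernicke")
  splits <- buildCrossSubjectSplits(corpus, nSplits, seed = seed)
  results <- lapply(seq_along(splits), function(k) {
    assertNoLeakage(splits[[k]], manifest(corpus))
    tc <- train; tc$seed <- mixSeed(seed, k, 31)
    fitAndReport(chunks, splits[[k]], net, tc, chunksPerGroup)
  })
  subjects <- sort(unique(manifest(corpus)$subject))
  heldOut <- setdiff(subjects, subjects[1:6])
  ensemble <- NULL
  if (length(heldOut)) {
    hm <- chunkMeta(chunks)
    hoChunks <- chunkSubset(chunks, hm$subject %in% heldOut)
    preds <- ensembleAverage(lapply(results, `[[`, "model"), hoChunks)
    ensemble <- list(subjects = heldOut, predictions = preds,
                     reportChunk = metricReport(preds),
                     reportAggregated = metricReport(
                       aggregateOverSecond(preds, chunksPerGroup)))
  }
  list(splits = results, ensemble = ensemble)
}

#' Run a configured experiment
#'
#' Dispatches an [experimentConfig()] to the matching experiment runner,
#' generating the corpus from its specification first.
#'
#' @param cfg an [experimentConfig()].
#' @return The runner's result list, with the generated corpus attached as
#'   attribute `"corpus"`.
#' @export
runExperiment <- function(cfg) {
  stopifnot(inherits(cfg, "experimentConfig"))
  spec <- cfg$corpusSpec
  corpus <- generateCorpus(spec, defaultClassParams(cfg$classSeparation,
                                                    fps = spec@fps))
  args <- list(corpus, net = cfg$net, train = cfg$train,
               targetShape = cfg$targetShape,
               chunksPerGroup = cfg$chunksPerGroup, seed = cfg$masterSeed)
  out <- switch(cfg$kind,
                within_subject = do.call(runWithinSubject, args),
                control_region = do.call(runControlRegion, args),
                cross_subject = do.call(runCrossSubject, args))
  attr(out, "corpus") <- corpus
  out
}
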