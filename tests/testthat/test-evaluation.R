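randomPreds <- function(n, seed) {
  withr::local_seed(seed)
  data.frame(y = stats::rbinom(n, 1, 0.5), p = round(runif(n), 2))
}

test_that("confusion counting matches per-record enumeration", {
  perfect <- data.frame(y = rep(c(1, 0), each = 10),
                        p = rep(c(1, 0), each = 10))
  cc <- confusion(perfect)
  expect_equal(c(cc@TP, cc@TN, cc@FP, cc@FN), c(10, 10, 0, 0))
  # tie rule: p >= threshold predicts positive
  ties <- data.frame(y = c(1, 1, 0, 0), p = rep(0.5, 4))
  ct <- confusion(ties, 0.5)
  expect_equal(c(ct@TP, ct@FP, ct@TN, ct@FN), c(2, 2, 0, 0))
  # enumeration oracle on 200 random records
  pr <- randomPreds(200, 14)
  cr <- confusion(pr, 0.35)
  tp <- 0; tn <- 0; fp <- 0; fn <- 0
  for (i in seq_len(200)) {
    pos <- pr$p[i] >= 0.35
    if (pos && pr$y[i] == 1) tp <- tp + 1
    if (pos && pr$y[i] == 0) fp <- fp + 1
    if (!pos && pr$y[i] == 0) tn <- tn + 1
    if (!pos && pr$y[i] == 1) fn <- fn + 1
  }
  expect_equal(c(cr@TP, cr@TN, cr@FP, cr@FN), c(tp, tn, fp, fn))
  expect_equal(cr@TP + cr@TN + cr@FP + cr@FN, 200)
  expect_error(confusion(pr[0, ]), "no scored")
})

test_that("threshold metrics follow their formulas and flag degeneracy", {
  perfect <- new("ConfusionCounts", TP = 50, TN = 50, FP = 0, FN = 0,
                 threshold = 0.5)
  bm <- basicMetrics(perfect)
  expect_equal(unlist(bm), c(precision = 1, recall = 1, accuracy = 1,
                             f1 = 1))
  # the 89/11 table: accuracy and F1 both 0.89 at any scale factor
  for (k in c(1, 7, 25)) {
    cc <- new("ConfusionCounts", TP = 89 * k, TN = 89 * k, FP = 11 * k,
              FN = 11 * k, threshold = 0.5)
    bm <- basicMetrics(cc)
    expect_equal(bm$accuracy, 0.89)
    expect_equal(bm$f1, 0.89)
  }
  # no predicted positives: precision undefined, flagged not zeroed
  none <- new("ConfusionCounts", TP = 0, TN = 9, FP = 0, FN = 3,
              threshold = 0.5)
  bm <- basicMetrics(none)
  expect_true(is.na(bm$precision))
  expect_true("precision" %in% attr(bm, "undefined"))
})

test_that("both Cohen's kappa formulations agree to 1e-12", {
  perfect <- new("ConfusionCounts", TP = 30, TN = 20, FP = 0, FN = 0,
                 threshold = 0.5)
  expect_equal(as.numeric(cohenKappa(perfect)), 1)
  chance <- new("ConfusionCounts", TP = 25, TN = 25, FP = 25, FN = 25,
                threshold = 0.5)
  expect_equal(as.numeric(cohenKappa(chance)), 0)
  withr::local_seed(3)
  for (rep in 1:200) {
    v <- stats::rpois(4, 20) + c(1, 1, 0, 0)
    cc <- new("ConfusionCounts", TP = v[1], TN = v[2], FP = v[3], FN = v[4],
              threshold = 0.5)
    k1 <- as.numeric(cohenKappa(cc))
    # independent (P0 - Pe) / (1 - Pe) evaluation
    n <- sum(v)
    p0 <- (v[1] + v[2]) / n
    pe <- ((v[1] + v[3]) / n) * ((v[1] + v[4]) / n) +
      ((v[2] + v[4]) / n) * ((v[2] + v[3]) / n)
    expect_equal(k1, (p0 - pe) / (1 - pe), tolerance = 1e-12)
    expect_gte(k1, -1); expect_lte(k1, 1)
  }
  # symmetric balanced table: kappa = 2 * accuracy - 1
  sym <- new("ConfusionCounts", TP = 40, TN = 40, FP = 10, FN = 10,
             threshold = 0.5)
  expect_equal(as.numeric(cohenKappa(sym)),
               2 * basicMetrics(sym)$accuracy - 1)
})

test_that("AUC equals the pair-counting oracle and its invariances hold", {
  sep <- data.frame(y = rep(c(0, 1), each = 5),
                    p = c(runif(5, 0, 0.4), runif(5, 0.6, 1)))
  expect_equal(rocAuc(sep)$auc, 1)
  withr::local_seed(21)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    pr <- data.frame(y = c(0, 1, stats::rbinom(n - 2, 1, 0.5)),
                     p = round(runif(n), 1))
    a <- rocAuc(pr)$auc
    # O(n^2) pair enumeration with half credit for ties
    pos <- pr$p[pr$y == 1]; neg <- pr$p[pr$y == 0]
    wins <- 0
    for (pp in pos) for (nn in neg)
      wins <- wins + (pp > nn) + 0.5 * (pp == nn)
    expect_equal(a, wins / (length(pos) * length(neg)))
    # label inversion flips the AUC
    flip <- pr; flip$y <- 1 - flip$y
    expect_equal(rocAuc(flip)$auc, 1 - a)
    # invariance under a strictly monotone transform
    mono <- pr; mono$p <- stats::plogis(5 * pr$p - 2)
    expect_equal(rocAuc(mono)$auc, a)
  }
  expect_error(rocAuc(data.frame(y = c(1, 1), p = c(0.1, 0.9))),
               "both classes")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  pr <- randomPreds(150, 77)
  ours <- rocAuc(pr)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(pr$y, pr$p, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs)
})

test_that("temporal aggregation groups within videos and drops remainders", {
  mk <- function(videoId, n, y, pfun) data.frame(
    videoId = videoId, chunkIndex = 0:(n - 1), y = y, p = pfun(n))
  # constant probabilities aggregate to themselves
  const <- mk("a", 50, 1, function(n) rep(0.7, n))
  agg <- aggregateOverSecond(const, 25L)
  expect_equal(nrow(agg), 2)
  expect_equal(agg$p, c(0.7, 0.7))
  expect_equal(agg$y, c(1, 1))
  # group means match manual computation; trailing chunks dropped
  withr::local_seed(5)
  two <- rbind(mk("a", 58, 1, runif), mk("b", 30, 0, runif))
  agg2 <- aggregateOverSecond(two, 25L)
  expect_equal(nrow(agg2), 3)  # 2 full groups from a, 1 from b
  aRows <- two[two$videoId == "a", ]
  expect_equal(agg2$p[agg2$videoId == "a"],
               c(mean(aRows$p[1:25]), mean(aRows$p[26:50])))
  # grouping never mixes videos or labels
  expect_equal(agg2$y[agg2$videoId == "b"], 0)
  mixed <- rbind(mk("c", 30, 1, runif))
  mixed$y[4] <- 0
  expect_error(aggregateOverSecond(mixed, 25L), "labels differ")
  gap <- mk("d", 30, 1, runif)
  gap$chunkIndex[20] <- 40
  expect_error(aggregateOverSecond(gap, 25L), "contiguous")
  expect_error(aggregateOverSecond(const, 0L), "chunksPerGroup")
})

test_that("ensemble averaging is the per-chunk mean of member scores", {
  chunks <- toyChunks(n = 12, seed = 6)
  split <- toySplit(chunks, nVal = 4)
  cfgT <- trainConfig(epochs = 2, batchSize = 6)
  models <- lapply(1:3, function(s) {
    tc <- cfgT; tc$seed <- s
    trainConvLSTM(chunks, split, netConfig(filters = 2, denseUnits = 3), tc)
  })
  single <- ensembleAverage(models[1], chunks)
  expect_equal(single$p, predictChunks(models[[1]], chunks)$p)
  ens <- ensembleAverage(models, chunks)
  manual <- rowMeans(vapply(models, function(m)
    predictChunks(m, chunks)$p, numeric(nChunks(chunks))))
  expect_equal(ens$p, manual)
  expect_error(ensembleAverage(list(), chunks), "empty")
})

test_that("metric reports assemble consistently", {
  pr <- randomPreds(120, 31)
  rep1 <- metricReport(pr)
  cc <- confusion(pr)
  expect_equal(rep1@accuracy, (cc@TP + cc@TN) / 120)
  expect_equal(rep1@auc, rocAuc(pr)$auc)
  expect_equal(rep1@kappa, as.numeric(cohenKappa(cc)))
  expect_equal(rep1@n, 120L)
  # serialization round-trip
  f <- tempfile(fileext = ".rds")
  saveRDS(rep1, f)
  expect_equal(readRDS(f), rep1)
  unlink(f)
})
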