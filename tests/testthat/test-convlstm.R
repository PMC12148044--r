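test_that("sigmoid has the textbook values, symmetry and saturation", {
  expect_equal(sigmoid(0), 0.5)
  expect_lt(sigmoid(-50), 1e-20)
  for (x in c(-3, -0.4, 0.9, 7)) expect_equal(sigmoid(x) + sigmoid(-x), 1)
})

test_that("cellStep with all-zero weights gives half-open gates", {
  h <- 4L; w <- 3L; f <- 2L
  zw <- list()
  for (g in c("i", "f", "c", "o")) {
    zw[[paste0("Wx", g)]] <- array(0, c(3, 3, 1, f))
    zw[[paste0("Wh", g)]] <- array(0, c(3, 3, f, f))
    zw[[paste0("b", g)]] <- numeric(f)
  }
  zw$Wci <- zw$Wcf <- zw$Wco <- array(0, c(h, w, f))
  s <- cellStep(array(1, c(h, w, 1)), array(0, c(h, w, f)),
                array(0, c(h, w, f)), zw)
  expect_equal(s$i, array(0.5, c(h, w, f)))
  expect_equal(s$f, array(0.5, c(h, w, f)))
  expect_equal(s$o, array(0.5, c(h, w, f)))
  expect_equal(s$C, array(0, c(h, w, f)))
  expect_equal(s$H, array(0, c(h, w, f)))
})

test_that("the compiled cell matches the scalar peephole-LSTM oracle", {
  dims <- c(20L, 1L, 1L, 1L, 1L, 2L)
  L <- speckleSense:::paramLayout(dims)
  withr::local_seed(31)
  worst <- 0
  for (rep in 1:50) {
    p <- rnorm(L$n)
    xs <- rnorm(20)
    st <- speckleSense:::clstmStatesCpp(p, xs, dims)
    orc <- scalarPeepholeLSTM(xs, scalarWeightsFromParams(p, dims))
    worst <- max(worst, abs(st$H[1, 1, ] - orc$H), abs(st$C[1, 1, ] - orc$C))
  }
  expect_lt(worst, 1e-10)
})

test_that("multi-step compiled unrolling matches the R cellStep reference", {
  dims <- c(6L, 5L, 4L, 3L, 3L, 2L)
  L <- speckleSense:::paramLayout(dims)
  withr::local_seed(7)
  p <- rnorm(L$n, sd = 0.4)
  x <- array(rnorm(5 * 4 * 6), c(5, 4, 6))
  st <- speckleSense:::clstmStatesCpp(p, as.numeric(x), dims)
  w <- speckleSense:::paramsToWeights(p, dims)
  h0 <- c0 <- array(0, c(5, 4, 3))
  for (t in 1:6) {
    s <- cellStep(array(x[, , t], c(5, 4, 1)), h0, c0, w)
    expect_equal(array(st$H[, , t], c(5, 4, 3)), s$H, tolerance = 1e-8)
    expect_equal(array(st$C[, , t], c(5, 4, 3)), s$C, tolerance = 1e-8)
    # gates stay strictly inside (0, 1)
    for (gname in c("i", "f", "o")) {
      expect_true(all(s[[gname]] > 0 & s[[gname]] < 1))
    }
    h0 <- s$H; c0 <- s$C
  }
})

test_that("a saturated forget gate preserves the cell state", {
  dims <- c(2L, 3L, 3L, 1L, 3L, 2L)
  L <- speckleSense:::paramLayout(dims)
  withr::local_seed(8)
  p <- rnorm(L$n, sd = 0.3)
  p[L$oB + 2] <- 30  # forget-gate bias -> sigmoid saturates at 1
  # zero the f-gate kernels and peephole so the bias alone drives the gate
  p[L$oWx + L$kk + seq_len(L$kk)] <- 0
  p[L$oWh + L$kk + seq_len(L$kk)] <- 0
  p[L$oPe + L$hw + seq_len(L$hw)] <- 0
  x <- array(rnorm(9 * 2), c(3, 3, 2))
  st <- speckleSense:::clstmStatesCpp(p, as.numeric(x), dims)
  c1 <- st$C[, , 1]; i2 <- st$i[, , 2]; g2 <- st$g[, , 2]
  expect_equal(st$C[, , 2], c1 + i2 * g2, tolerance = 1e-9)
})

test_that("analytic gradients agree with finite differences", {
  dims <- c(5L, 6L, 5L, 2L, 3L, 4L)
  L <- speckleSense:::paramLayout(dims)
  withr::local_seed(42)
  n <- 2
  x <- array(runif(6 * 5 * 5 * n), c(6, 5, 5, n))
  y <- c(1, 0)
  p <- rnorm(L$n, sd = 0.3)
  mask <- matrix(sample(c(0, 1 / 0.7), 2 * n, replace = TRUE), 2, n)
  lg <- function(pp) speckleSense:::clstmLossGradCpp(
    pp, as.numeric(x), y, dims, as.numeric(mask), 1e-3)
  res <- lg(p)
  idx <- sample(L$n, 120)
  h <- 1e-4
  for (i in idx) {
    pp <- p; pp[i] <- pp[i] + h
    pm <- p; pm[i] <- pm[i] - h
    num <- (lg(pp)$loss - lg(pm)$loss) / (2 * h)
    denom <- max(abs(num) + abs(res$grad[i]), 1e-6)
    expect_lt(abs(num - res$grad[i]) / denom, 1e-3)
  }
})

test_that("inference is deterministic with probabilities in (0, 1)", {
  dims <- c(4L, 6L, 6L, 2L, 3L, 3L)
  L <- speckleSense:::paramLayout(dims)
  withr::local_seed(12)
  for (draw in 1:20) {
    p <- rnorm(L$n, sd = 0.6)
    x <- array(runif(6 * 6 * 4 * 3), c(6, 6, 4, 3))
    pr1 <- speckleSense:::clstmForwardCpp(p, as.numeric(x), dims,
                                          numeric(2), rep(1, 2))
    pr2 <- speckleSense:::clstmForwardCpp(p, as.numeric(x), dims,
                                          numeric(2), rep(1, 2))
    expect_identical(pr1, pr2)
    expect_true(all(pr1 > 0 & pr1 < 1))
    # identical chunks score identically
    xx <- array(rep(x[, , , 1], 2), c(6, 6, 4, 2))
    prs <- speckleSense:::clstmForwardCpp(p, as.numeric(xx), dims,
                                          numeric(2), rep(1, 2))
    expect_equal(prs[1], prs[2])
  }
  # zeroed head gives exactly 0.5
  p0 <- numeric(L$n)
  p0[L$oGamma + seq_len(2)] <- 1
  x <- array(runif(6 * 6 * 4), c(6, 6, 4, 1))
  expect_equal(speckleSense:::clstmForwardCpp(p0, as.numeric(x), dims,
                                              numeric(2), rep(1, 2)),
               0.5)
})

test_that("training solves a linearly separable toy problem", {
  chunks <- toyChunks(n = 60, seed = 2)
  split <- toySplit(chunks, nVal = 16)
  model <- trainConvLSTM(chunks, split,
                         netConfig(filters = 2, denseUnits = 4,
                                   dropout = 0.1),
                         trainConfig(epochs = 20, batchSize = 16, seed = 3))
  expect_equal(max(modelHistory(model)$valAcc), 1.0)
  # prediction interface: length, ordering, reproducibility
  preds <- predictChunks(model, chunks)
  expect_equal(nrow(preds), nChunks(chunks))
  expect_identical(preds$p, predictChunks(model, chunks)$p)
  expect_true(all(preds$p > 0 & preds$p < 1))
  empty <- chunkSubset(chunks, integer(0))
  expect_equal(nrow(predictChunks(model, empty)), 0)
})

test_that("training is reproducible and rejects degenerate inputs", {
  chunks <- toyChunks(n = 24, seed = 5)
  split <- toySplit(chunks, nVal = 8)
  cfgN <- netConfig(filters = 2, denseUnits = 3)
  cfgT <- trainConfig(epochs = 3, batchSize = 8, seed = 9)
  m1 <- trainConvLSTM(chunks, split, cfgN, cfgT)
  m2 <- trainConvLSTM(chunks, split, cfgN, cfgT)
  expect_identical(modelHistory(m1), modelHistory(m2))
  expect_identical(m1@params, m2@params)
  # single-class training set is rejected
  oneClass <- chunkSubset(chunks, chunkMeta(chunks)$classLabel == "clear")
  badSplit <- toySplit(oneClass, nVal = 4)
  expect_error(trainConvLSTM(oneClass, badSplit, cfgN, cfgT),
               "single class")
})
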