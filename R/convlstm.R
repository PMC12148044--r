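#' Network architecture configuration
#'
#' One peephole ConvLSTM layer followed by spatial mean pooling of the final
#' hidden state, batch normalization, dropout, one dense ReLU layer and a
#' single sigmoid output unit. Defaults are the desk-scale architecture
#' (4 filters, 3x3 kernels, 8 dense units).
#'
#' @param filters number of ConvLSTM filters.
#' @param kernelSize odd convolution kernel size.
#' @param denseUnits units in the dense ReLU layer.
#' @param dropout dropout rate on the normalized pooled features, in [0, 1).
#' @param l2 L2 penalty coefficient on weight tensors.
#' @return A list of class `"netConfig"`.
#' @export
netConfig <- function(filters = 4L, kernelSize = 3L, denseUnits = 8L,
                      dropout = 0.3, l2 = 1e-4) {
  stopifnot(kernelSize %% 2 == 1, dropout >= 0, dropout < 1, l2 >= 0,
            filters >= 1, denseUnits >= 1)
  structure(list(filters = as.integer(filters),
                 kernelSize = as.integer(kernelSize),
                 denseUnits = as.integer(denseUnits), dropout = dropout,
                 l2 = l2), class = "netConfig")
}

#' Training configuration
#'
#' Adaptive-moment (Adam) optimization of the binary cross-entropy loss,
#' with the checkpoint of best validation accuracy retained.
#'
#' @param learningRate Adam step size.
#' @param beta1,beta2,epsilon Adam moment decay rates and stabilizer.
#' @param batchSize minibatch size.
#' @param epochs number of passes over the training set.
#' @param seed seed controlling initialization, shuffling and dropout.
#' @return A list of class `"trainConfig"`.
#' @export
trainConfig <- function(learningRate = 3e-3, beta1 = 0.9, beta2 = 0.999,
                        epsilon = 1e-8, batchSize = 32L, epochs = 20L,
                        seed = 1L) {
  stopifnot(learningRate > 0, batchSize >= 1, epochs >= 1)
  structure(list(learningRate = learningRate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "trainConfig")
}

#' Logistic sigmoid
#'
#' \eqn{f(x) = 1 / (1 + e^{-x})}; saturates rather than overflowing.
#'
#' @param x numeric input.
#' @return Values in (0, 1).
#' @examples
#' sigmoid(0)
#' @export
sigmoid <- function(x) {
  stopifnotFinite(x, "x")
  1 / (1 + exp(-x))
}

# Offsets (0-based, mirroring the C++ layout) of each parameter block in the
# flat vector. Gate order: i, f, c (candidate), o.
paramLayout <- function(dims) {
  T <- dims[1]; H <- dims[2]; W <- dims[3]
  F <- dims[4]; K <- dims[5]; Dh <- dims[6]
  kk <- K * K; hw <- H * W
  oWx <- 0
  oWh <- oWx + 4 * F * kk
  oPe <- oWh + 4 * F * F * kk
  oB <- oPe + 3 * F * hw
  oGamma <- oB + 4 * F
  oBeta <- oGamma + F
  oW1 <- oBeta + F
  oB1 <- oW1 + Dh * F
  oW2 <- oB1 + Dh
  oB2 <- oW2 + Dh
  list(oWx = oWx, oWh = oWh, oPe = oPe, oB = oB, oGamma = oGamma,
       oBeta = oBeta, oW1 = oW1, oB1 = oB1, oW2 = oW2, oB2 = oB2,
       n = oB2 + 1, kk = kk, hw = hw, T = T, H = H, W = W, F = F, K = K,
       Dh = Dh)
}

# Seeded parameter initialization: scaled-normal kernels, zero peepholes,
# forget-gate bias +1 (standard LSTM practice), identity batch norm.
initParams <- function(net, dims, seed) {
  L <- paramLayout(dims)
  p <- numeric(L$n)
  withSeed(mixSeed(seed, 101), {
    p[L$oWx + seq_len(4 * L$F * L$kk)] <-
      rnorm(4 * L$F * L$kk, sd = sqrt(1 / L$kk))
    p[L$oWh + seq_len(4 * L$F * L$F * L$kk)] <-
      rnorm(4 * L$F * L$F * L$kk, sd = sqrt(1 / (L$kk * L$F)))
    p[L$oB + L$F + seq_len(L$F)] <- 1  # forget-gate bias
    p[L$oGamma + seq_len(L$F)] <- 1
    p[L$oW1 + seq_len(L$Dh * L$F)] <-
      rnorm(L$Dh * L$F, sd = sqrt(2 / (L$F + L$Dh)))
    p[L$oW2 + seq_len(L$Dh)] <- rnorm(L$Dh, sd = sqrt(2 / (L$Dh + 1)))
  })
  p
}

# Unpack a flat parameter vector into named weight arrays in the cellStep
# convention: Wx* dim (k, k, 1, F); Wh* dim (k, k, F, F) indexed
# [, , fin, fout]; peepholes dim (H, W, F); biases length F.
paramsToWeights <- function(params, dims) {
  L <- paramLayout(dims)
  gateNames <- c("i", "f", "c", "o")
  kmat <- function(off) {
    m <- matrix(0, L$K, L$K)
    for (u in 0:(L$K - 1)) for (v in 0:(L$K - 1))
      m[u + 1, v + 1] <- params[off + u * L$K + v + 1]
    m
  }
  w <- list()
  for (g in 0:3) {
    Wx <- array(0, c(L$K, L$K, 1, L$F))
    for (f in 0:(L$F - 1))
      Wx[, , 1, f + 1] <- kmat(L$oWx + (g * L$F + f) * L$kk)
    w[[paste0("Wx", gateNames[g + 1])]] <- Wx
    Wh <- array(0, c(L$K, L$K, L$F, L$F))
    for (fo in 0:(L$F - 1)) for (fi in 0:(L$F - 1))
      Wh[, , fi + 1, fo + 1] <- kmat(L$oWh + ((g * L$F + fo) * L$F + fi) * L$kk)
    w[[paste0("Wh", gateNames[g + 1])]] <- Wh
    w[[paste0("b", gateNames[g + 1])]] <-
      params[L$oB + g * L$F + seq_len(L$F)]
  }
  for (pp in 0:2) {
    pe <- array(0, c(L$H, L$W, L$F))
    for (f in 0:(L$F - 1))
      pe[, , f + 1] <- matrix(params[L$oPe + (pp * L$F + f) * L$hw +
                                       seq_len(L$hw)], L$H, L$W)
    w[[c("Wci", "Wcf", "Wco")[pp + 1]]] <- pe
  }
  w
}

# Same-padded multichannel 2-d cross-correlation, reference implementation.
# input: (h, w, cin); kernels: (k, k, cin, fout) -> output (h, w, fout).
conv2dSame <- function(input, kernels) {
  h <- dim(input)[1]; w <- dim(input)[2]
  k <- dim(kernels)[1]; cin <- dim(kernels)[3]; fout <- dim(kernels)[4]
  c0 <- (k - 1) / 2
  out <- array(0, c(h, w, fout))
  pad <- array(0, c(h + k - 1, w + k - 1, cin))
  pad[c0 + seq_len(h), c0 + seq_len(w), ] <- input
  for (f in seq_len(fout)) for (ci in seq_len(cin))
    for (u in seq_len(k)) for (v in seq_len(k))
      out[, , f] <- out[, , f] + kernels[u, v, ci, f] *
        pad[u + seq_len(h) - 1, v + seq_len(w) - 1, ci]
  out
}

#' One step of the peephole ConvLSTM recurrence
#'
#' Reference implementation of the cell update with same-padded
#' convolutions and state-shaped elementwise peephole weights. The
#' output-gate peephole acts on the updated cell state:
#' \deqn{i_t = \sigma(W_{xi}*X_t + W_{hi}*H_{t-1} + W_{ci}\odot C_{t-1} + b_i)}
#' \deqn{f_t = \sigma(W_{xf}*X_t + W_{hf}*H_{t-1} + W_{cf}\odot C_{t-1} + b_f)}
#' \deqn{C_t = f_t\odot C_{t-1} + i_t\odot\tanh(W_{xc}*X_t + W_{hc}*H_{t-1} + b_c)}
#' \deqn{o_t = \sigma(W_{xo}*X_t + W_{ho}*H_{t-1} + W_{co}\odot C_t + b_o)}
#' \deqn{H_t = o_t\odot\tanh(C_t)}
#' Gate activations are strictly inside (0, 1) and \eqn{H_t \in (-1, 1)}.
#' The compiled training path is verified against this function (and against
#' a scalar peephole-LSTM recurrence) in the test suite.
#'
#' @param x input tensor, dim (h, w, channels).
#' @param hPrev,cPrev previous hidden and cell state, dim (h, w, filters);
#'   pass zero arrays for the initial step.
#' @param weights named list: `Wxi, Wxf, Wxc, Wxo` dim (k, k, channels,
#'   filters); `Whi, Whf, Whc, Who` dim (k, k, filters, filters);
#'   `Wci, Wcf, Wco` dim (h, w, filters); biases `bi, bf, bc, bo` length
#'   filters.
#' @return List with gate activations `i, f, o`, cell state `C` and output
#'   `H`, each dim (h, w, filters).
#' @export
cellStep <- function(x, hPrev, cPrev, weights) {
  if (!identical(dim(hPrev), dim(cPrev)))
    stop("hPrev and cPrev shapes differ", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(hPrev)) || any(!is.finite(cPrev)))
    stop("non-finite input to cellStep", call. = FALSE)
  F <- dim(weights$Wxi)[4]
  addBias <- function(a, b) {
    for (f in seq_len(F)) a[, , f] <- a[, , f] + b[f]
    a
  }
  pre <- function(Wx, Wh) conv2dSame(x, Wx) + conv2dSame(hPrev, Wh)
  i <- sigmoid(addBias(pre(weights$Wxi, weights$Whi) + weights$Wci * cPrev,
                       weights$bi))
  f <- sigmoid(addBias(pre(weights$Wxf, weights$Whf) + weights$Wcf * cPrev,
                       weights$bf))
  g <- tanh(addBias(pre(weights$Wxc, weights$Whc), weights$bc))
  C <- f * cPrev + i * g
  o <- sigmoid(addBias(pre(weights$Wxo, weights$Who) + weights$Wco * C,
                       weights$bo))
  list(i = i, f = f, o = o, C = C, H = o * tanh(C))
}

# Model dims vector for a chunk geometry and architecture.
modelDims <- function(chunks, net) {
  d <- dim(chunks@data)
  c(d[3], d[1], d[2], net$filters, net$kernelSize, net$denseUnits)
}

chunkLabels <- function(chunks, positiveClass = "clear") {
  as.numeric(chunkMeta(chunks)$classLabel == positiveClass)
}

#' Train the ConvLSTM classifier
#'
#' Minimizes binary cross-entropy (plus the configured L2 penalty) with
#' Adam over minibatches of training chunks, evaluating validation accuracy
#' after every epoch and retaining the checkpoint with the best validation
#' accuracy. Batch-norm running statistics are tracked with momentum 0.9
#' and frozen with the retained checkpoint. Fully seeded: identical data
#' and configurations reproduce the history exactly.
#'
#' @param chunks a [ChunkSet-class] covering the split.
#' @param split a [SplitSpec-class] with non-empty train and validation
#'   sets; the training set must contain both classes.
#' @param net a [netConfig()].
#' @param tc a [trainConfig()].
#' @param positiveClass label mapped to 1 (default `"clear"`).
#' @return A [ConvLSTMModel-class] with the training history.
#' @export
trainConvLSTM <- function(chunks, split, net = netConfig(),
                          tc = trainConfig(), positiveClass = "clear") {
  parts <- splitChunks(chunks, split)
  train <- parts$train; val <- parts$validation
  if (nChunks(train) == 0 || nChunks(val) == 0)
    stop("empty training or validation set", call. = FALSE)
  yTr <- chunkLabels(train, positiveClass)
  yVal <- chunkLabels(val, positiveClass)
  if (length(unique(yTr)) < 2)
    stop("training set contains a single class", call. = FALSE)
  dims <- as.integer(modelDims(chunks, net))
  Fn <- net$filters
  nTr <- nChunks(train)
  hist <- list()
  state <- withSeed(mixSeed(tc$seed, 555), {
    params <- initParams(net, dims, tc$seed)
    mAd <- numeric(length(params)); vAd <- numeric(length(params))
    stepN <- 0
    best <- list(acc = -Inf, params = params, bnMean = numeric(Fn),
                 bnVar = rep(1, Fn), epoch = 0L)
    for (ep in seq_len(tc$epochs)) {
      ord <- sample(nTr)
      epLoss <- 0; epCorrect <- 0
      for (b in seq_len(ceiling(nTr / tc$batchSize))) {
        idx <- ord[((b - 1) * tc$batchSize + 1):min(b * tc$batchSize, nTr)]
        nb <- length(idx)
        mask <- if (net$dropout > 0)
          matrix(stats::rbinom(Fn * nb, 1, 1 - net$dropout), Fn, nb) /
            (1 - net$dropout)
        else matrix(1, Fn, nb)
        res <- clstmLossGradCpp(params,
                                as.numeric(train@data[, , , idx, drop = FALSE]),
                                yTr[idx], dims, as.numeric(mask), net$l2)
        stepN <- stepN + 1
        mAd <- tc$beta1 * mAd + (1 - tc$beta1) * res$grad
        vAd <- tc$beta2 * vAd + (1 - tc$beta2) * res$grad^2
        mHat <- mAd / (1 - tc$beta1^stepN)
        vHat <- vAd / (1 - tc$beta2^stepN)
        params <- params - tc$learningRate * mHat / (sqrt(vHat) + tc$epsilon)
        epLoss <- epLoss + res$loss * nb
        epCorrect <- epCorrect + sum((res$probs >= 0.5) == yTr[idx])
      }
      # Recalibrate batch norm exactly on the training set (the pooled
      # features have a tiny natural scale, so momentum-averaged running
      # statistics would be dominated by their initialization for a long
      # time; exact population statistics make inference consistent).
      poolTr <- clstmPoolCpp(params, as.numeric(train@data), dims)
      bnMean <- rowMeans(poolTr)
      bnVar <- rowMeans((poolTr - bnMean)^2)
      valProbs <- clstmForwardCpp(params,
                                  as.numeric(val@data), dims, bnMean, bnVar)
      pc <- pmin(pmax(valProbs, 1e-12), 1 - 1e-12)
      valLoss <- -mean(yVal * log(pc) + (1 - yVal) * log(1 - pc))
      valAcc <- mean((valProbs >= 0.5) == yVal)
      hist[[ep]] <- data.frame(epoch = ep, trainLoss = epLoss / nTr,
                                trainAcc = epCorrect / nTr,
                                valLoss = valLoss, valAcc = valAcc)
      if (valAcc > best$acc)
        best <- list(acc = valAcc, params = params, bnMean = bnMean,
                     bnVar = bnVar, epoch = ep)
    }
    best
  })
  new("ConvLSTMModel", params = state$params, dims = dims,
      bnMean = state$bnMean, bnVar = state$bnVar,
      netConfig = unclass(net), trainConfig = unclass(tc),
      history = do.call(rbind, hist), bestEpoch = as.integer(state$epoch))
}

#' Score chunks with a trained model
#'
#' Deterministic inference (dropout off, batch norm using the frozen
#' running statistics). Records are ordered by (videoId, startFrame).
#'
#' @param model a [ConvLSTMModel-class].
#' @param chunks a [ChunkSet-class] with matching chunk geometry.
#' @param positiveClass label mapped to `y = 1`.
#' @return Scored predictions: a data.frame with columns `videoId, subject,
#'   session, region, classLabel, chunkIndex, startFrame, y, p`.
#' @export
predictChunks <- function(model, chunks, positiveClass = "clear") {
  m <- chunkMeta(chunks)
  if (nrow(m) == 0)
    return(cbind(m, data.frame(y = numeric(0), p = numeric(0))))
  d <- dim(chunks@data)
  if (!identical(as.integer(d[c(3, 1, 2)]), model@dims[1:3]))
    stop("chunk geometry does not match the model", call. = FALSE)
  p <- clstmForwardCpp(model@params, as.numeric(chunks@data), model@dims,
                       model@bnMean, model@bnVar)
  out <- cbind(m, data.frame(y = as.numeric(m$classLabel == positiveClass),
                             p = p))
  out[order(out$videoId, out$startFrame), , drop = FALSE]
}

#' Training history accessor
#' @param model a [ConvLSTMModel-class].
#' @return Per-epoch history data.frame.
#' @export
modelHistory <- function(model) model@history
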