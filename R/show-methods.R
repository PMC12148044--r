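#' @describeIn OpticalConfig-class compact display
#' @param object the object to display
#' @export
setMethod("show", "OpticalConfig", function(object) {
  cat("OpticalConfig:", sprintf("%g nm", object@wavelength * 1e9),
      sprintf("| spot %g mm", object@spotDiameter * 1e3),
      sprintf("| Z2 %g mm, Z3 %g mm", object@z2 * 1e3, object@z3 * 1e3),
      "\n  frames:", paste(object@frameShape, collapse = "x"),
      sprintf("px @ %g fps, %d-bit | speckle ~%g px | %g px/rad\n",
              object@fps, object@bitDepth, object@targetSpecklePx,
              object@pxPerRadian))
})

#' @describeIn PhaseScreen-class compact display
#' @param object the object to display
#' @export
setMethod("show", "PhaseScreen", function(object) {
  cat("PhaseScreen", paste(dim(object@phase), collapse = "x"),
      sprintf("| aperture fraction %.4f (%d samples) | seed %d\n",
              object@apertureFraction, sum(object@aperture), object@seed))
})

#' @describeIn SpeckleVideo-class compact display
#' @param object the object to display
#' @export
setMethod("show", "SpeckleVideo", function(object) {
  d <- dim(object@frames)
  cat(sprintf("SpeckleVideo %s: %dx%d px, %d frames @ %g fps\n",
              object@videoId, d[1], d[2], d[3], object@fps),
      sprintf(" subject %s | %s | %s | class %s\n", object@subjectId,
              object@sessionTag, object@regionTag, object@classLabel))
})

#' @describeIn ChunkSet-class compact display
#' @param object the object to display
#' @export
setMethod("show", "ChunkSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("ChunkSet: %d chunks of %d x (%dx%d) from %d videos\n",
              d[4], d[3], d[1], d[2], length(unique(object@meta$videoId))))
})

#' @describeIn SplitSpec-class compact display
#' @param object the object to display
#' @export
setMethod("show", "SplitSpec", function(object) {
  cat(sprintf("SplitSpec %s: %d train / %d validation / %d test videos\n",
              object@name, length(object@train), length(object@validation),
              length(object@test)))
  if (length(object@subjects) == 3L)
    cat(" subjects:",
        sprintf("train {%s} val {%s} test {%s}\n",
                paste(object@subjects$train, collapse = ","),
                paste(object@subjects$validation, collapse = ","),
                paste(object@subjects$test, collapse = ",")))
})

#' @describeIn ConvLSTMModel-class compact display
#' @param object the object to display
#' @export
setMethod("show", "ConvLSTMModel", function(object) {
  d <- object@dims
  cat(sprintf(paste0("ConvLSTM classifier: input %dx%dx%d, %d filters ",
                     "(%dx%d), %d dense units, %d parameters\n"),
              d[1], d[2], d[3], d[4], d[5], d[5], d[6],
              length(object@params)),
      sprintf(" best epoch %d (validation accuracy %.3f)\n",
              object@bestEpoch,
              object@history$valAcc[object@bestEpoch]))
})

#' @describeIn ConfusionCounts-class compact display
#' @param object the object to display
#' @export
setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("Confusion @ %.2f: TP %d  FP %d  FN %d  TN %d\n",
              object@threshold, object@TP, object@FP, object@FN, object@TN))
})

#' @describeIn MetricReport-class compact display
#' @param object the object to display
#' @export
setMethod("show", "MetricReport", function(object) {
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.3f", x))
  cat(sprintf(
    "MetricReport (n = %d): acc %s | F1 %s | kappa %s | AUC %s\n",
    object@n, fmt(object@accuracy), fmt(object@f1), fmt(object@kappa),
    fmt(object@auc)),
    sprintf(" precision %s | recall %s\n", fmt(object@precision),
            fmt(object@recall)))
  if (length(object@undefined))
    cat(" undefined:", paste(object@undefined, collapse = ", "), "\n")
})
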