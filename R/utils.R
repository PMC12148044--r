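# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards so corpus generation never perturbs user code.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic integer mixing of a master seed with index coordinates;
# stays below 2^31 so the result is a valid R integer seed.
mixSeed <- function(...) {
  v <- as.numeric(unlist(list(...)))
  s <- 0
  for (x in v) s <- (s * 1664525 + (x + 1) * 1013904223) %% 2147483647
  as.integer(s)
}

stopifnotFinite <- function(x, what) {
  if (any(!is.finite(x))) stop(what, " must be finite", call. = FALSE)
  invisible(x)
}

# 2-d FFT conveniences (stats::fft handles matrices as multidimensional DFT).
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)
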