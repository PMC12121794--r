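# internal helpers shared across modules

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.assert <- function(ok, ...) {
  if (!isTRUE(ok)) stop(..., call. = FALSE)
}

# mean absolute deviation about the median (the dispersion used by the
# line-noise channel detector); distinct from stats::mad (median absolute
# deviation), which is available via type = "median".
.madAboutMedian <- function(x, type = c("mean", "median")) {
  type <- match.arg(type)
  m <- stats::median(x)
  if (type == "mean") mean(abs(x - m)) else stats::median(abs(x - m))
}

.sampleSd <- function(x, type = c("sample", "population")) {
  type <- match.arg(type)
  if (type == "sample") stats::sd(x)
  else sqrt(mean((x - mean(x))^2))
}

.canonicalPair <- function(a, b) {
  swap <- a > b
  list(a = ifelse(swap, b, a), b = ifelse(swap, a, b))
}
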