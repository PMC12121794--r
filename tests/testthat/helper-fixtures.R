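# Shared fixtures and independent oracles for the test suite.

# Minimal session bundle around a given signal matrix.
makeBundle <- function(signals, fs = 500, regions = NULL,
                       events = NULL, exclude = NULL) {
  nch <- nrow(signals)
  ids <- sprintf("ch%02d", seq_len(nch))
  rownames(signals) <- ids
  if (is.null(regions)) regions <- rep("A", nch)
  excl <- rep("", nch)
  if (!is.null(exclude)) excl[exclude] <- "white_matter"
  if (is.null(events))
    events <- data.frame(condition = "baseline", onset_sample = 1L,
                         duration_samples = ncol(signals))
  methods::new("SessionBundle", subjectId = "test", samplingRate = fs,
               signals = signals, channels = data.frame(
                 channel_id = ids, region = regions, exclude_class = excl,
                 stringsAsFactors = FALSE),
               events = events)
}

# EpochSet built directly from a condition -> (channels x samples x epochs)
# array list, all-true mask.
makeEpochSet <- function(arrays, fs = 500) {
  nch <- dim(arrays[[1]])[1]
  methods::new("EpochSet", epochs = arrays,
               keepMask = lapply(arrays, function(a)
                 matrix(TRUE, dim(a)[1], dim(a)[3])),
               samplingRate = fs,
               channelIds = sprintf("ch%02d", seq_len(nch)))
}

# RegionPairDelta built from a plain data.frame (group level by default).
makeDelta <- function(df, level = "group") {
  if (is.null(df$n_pairs)) df$n_pairs <- 1L
  methods::new("RegionPairDelta", table = df, level = level)
}

# ---- independent oracles ----------------------------------------------------

# Wilcoxon signed-rank two-tailed p by full enumeration of all 2^N sign
# assignments (no ties assumed).
oracleWilcoxonExact <- function(x, mu = 0) {
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wall <- as.vector(signs %*% r)
  pLess <- mean(Wall <= W)
  pGreater <- mean(Wall >= W)
  min(1, 2 * min(pLess, pGreater))
}

# Friedman chi-squared from first-principles ranks (tie-corrected).
oracleFriedman <- function(y) {
  n <- nrow(y); k <- ncol(y)
  r <- t(apply(y, 1, rank))
  S <- 12 * sum((colSums(r) - n * (k + 1) / 2)^2) / (n * k * (k + 1))
  ties <- sum(apply(y, 1, function(row) { t <- table(row); sum(t^3 - t) }))
  S / (1 - ties / (n * k * (k^2 - 1)))
}

# Kruskal-Wallis H from first-principles joint ranks (tie-corrected).
oracleKruskal <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  H <- 12 / (n * (n + 1)) * sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (n + 1)
  t <- table(x)
  H / (1 - sum(t^3 - t) / (n^3 - n))
}

# Exact multinomial p via an independent outcome enumeration (expand.grid)
# and stats::dmultinom.
oracleMultinomial <- function(counts, probs = rep(1 / length(counts),
                                                  length(counts))) {
  n <- sum(counts); k <- length(counts)
  grid <- as.matrix(expand.grid(rep(list(0:n), k - 1)))
  grid <- grid[rowSums(grid) <= n, , drop = FALSE]
  outcomes <- cbind(grid, n - rowSums(grid))
  pAll <- apply(outcomes, 1, stats::dmultinom, prob = probs)
  pObs <- stats::dmultinom(counts, prob = probs)
  sum(pAll[pAll <= pObs * (1 + 1e-12)])
}

# Direct (loop-free of package code) MSC estimate for two signals: Welch
# with hamming tapers, used to cross-check the package engine.
oracleMsc <- function(x, y, fs, window = 2.5, overlap = 0.7) {
  L <- round(window * fs)
  hop <- round((1 - overlap) * L)
  starts <- seq(1, length(x) - L + 1, by = hop)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  Pxy <- 0; Pxx <- 0; Pyy <- 0
  for (s in starts) {
    X <- stats::fft(w * x[s:(s + L - 1)])[1:(L %/% 2 + 1)]
    Y <- stats::fft(w * y[s:(s + L - 1)])[1:(L %/% 2 + 1)]
    Pxy <- Pxy + X * Conj(Y); Pxx <- Pxx + Mod(X)^2; Pyy <- Pyy + Mod(Y)^2
  }
  list(freq = (0:(L %/% 2)) * fs / L,
       coherence = Mod(Pxy)^2 / (Pxx * Pyy), K = length(starts))
}
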