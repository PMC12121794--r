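#' Canonical frequency band scheme
#'
#' Named half-open frequency intervals \[low, high) in Hz. The default scheme
#' is theta 4-8, alpha 8-13, beta 13-30 and broadband gamma 70-170 Hz; the
#' half-open convention resolves the shared 8 and 13 Hz edges.
#'
#' @param ... named numeric length-2 vectors c(low, high), Hz.
#' @return named list of validated band intervals.
#' @examples
#' defaultBands()
#' bandScheme(theta = c(4, 8), alpha = c(8, 13))
#' @export
bandScheme <- function(...) {
  bands <- list(...)
  .assert(length(bands) > 0 && !is.null(names(bands)) && all(names(bands) != ""),
          "bands must be named")
  for (nm in names(bands)) {
    b <- bands[[nm]]
    .assert(length(b) == 2 && b[1] >= 0 && b[2] > b[1],
            "band ", nm, " must be c(low, high) with 0 <= low < high")
  }
  lo <- vapply(bands, `[`, numeric(1), 1L)
  hi <- vapply(bands, `[`, numeric(1), 2L)
  o <- order(lo)
  .assert(all(hi[o][-length(o)] <= lo[o][-1L] + 1e-12),
          "bands overlap under the half-open convention")
  bands
}

#' @rdname bandScheme
#' @export
defaultBands <- function() {
  bandScheme(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30),
             gamma = c(70, 170))
}

#' Magnitude-squared coherence spectrum of two signals
#'
#' Welch estimate: tapered overlapping segments, cross- and auto-spectra
#' averaged across the K segments, then
#' \eqn{C_{xy}(f) = |P_{xy}(f)|^2 / (P_{xx}(f) P_{yy}(f))}.
#' With a single segment the estimate is identically 1 for any pair of
#' signals, so K = 1 is refused.
#'
#' @param x,y numeric vectors of equal length.
#' @param fs sampling rate, Hz.
#' @param window segment length in seconds (default 2.5).
#' @param overlap fractional segment overlap (default 0.70).
#' @param taper \code{"hamming"} (default) or \code{"hann"}.
#' @return object of class \code{MscSpectrum}: list with \code{freq} (Hz),
#'   \code{coherence} (values in \[0,1\]), \code{K} (segment count) and the
#'   estimator settings.
#' @examples
#' x <- rnorm(2500)
#' s <- mscSpectrum(x, x, fs = 500)
#' all(abs(s$coherence - 1) < 1e-9)
#' @export
mscSpectrum <- function(x, y, fs, window = 2.5, overlap = 0.70,
                        taper = "hamming") {
  .assert(length(x) == length(y), "x and y must have equal length")
  .assert(fs > 0, "fs must be positive")
  wp <- .welchParams(fs, length(x), window, overlap, taper)
  F <- .segmentFFT(rbind(x, y), wp)
  Pxy <- rowSums(F[, 1L, , drop = FALSE] * Conj(F[, 2L, , drop = FALSE]),
                 dims = 1L)
  Pxx <- rowSums(Mod(F[, 1L, , drop = FALSE])^2, dims = 1L)
  Pyy <- rowSums(Mod(F[, 2L, , drop = FALSE])^2, dims = 1L)
  structure(list(freq = wp$freq, coherence = .cohFromSpectra(Pxy, Pxx, Pyy),
                 K = wp$K, fs = fs, window = window, overlap = overlap),
            class = "MscSpectrum")
}

#' @export
print.MscSpectrum <- function(x, ...) {
  cat(sprintf("MscSpectrum: %d bins, 0-%.1f Hz (res %.3g Hz), K = %d segments\n",
              length(x$freq), max(x$freq), x$freq[2] - x$freq[1], x$K))
  invisible(x)
}

#' Band-averaged coherence
#'
#' Unweighted mean of the coherence spectrum over the bins with
#' low <= f < high for each band of the scheme.
#'
#' @param spectrum an \code{MscSpectrum}.
#' @param scheme a band scheme (see \code{\link{bandScheme}}).
#' @return named numeric vector of band-mean coherence values.
#' @export
bandMsc <- function(spectrum, scheme = defaultBands()) {
  vapply(names(scheme), function(nm) {
    b <- scheme[[nm]]
    idx <- which(spectrum$freq >= b[1] & spectrum$freq < b[2])
    .assert(length(idx) > 0 && b[1] < spectrum$fs / 2,
            "band ", nm, " has no bins on this frequency grid")
    mean(spectrum$coherence[idx])
  }, numeric(1))
}

.bandBins <- function(freq, scheme, fs) {
  lapply(stats::setNames(names(scheme), names(scheme)), function(nm) {
    b <- scheme[[nm]]
    idx <- which(freq >= b[1] & freq < b[2])
    .assert(length(idx) > 0 && b[1] < fs / 2,
            "band ", nm, " has no bins on this frequency grid")
    idx
  })
}

#' Per-epoch band coherence for all electrode pairs
#'
#' Computes, for every unordered electrode pair and every epoch of every
#' condition, the band-averaged magnitude-squared coherence. An epoch enters a
#' pair's record only if the keep mask is true for both channels; masked
#' epochs are NA. With \code{pooled = TRUE} additionally accumulates Welch
#' segments across all epochs valid for the pair and stores a single
#' lower-variance estimate per (pair, condition, band).
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param scheme band scheme.
#' @param window,overlap,taper Welch settings as in \code{\link{mscSpectrum}}.
#' @param pooled also compute pooled cross-epoch estimates.
#' @return a \linkS4class{PairBandTable}.
#' @export
pairConditionTable <- function(epochs, scheme = defaultBands(), window = 2.5,
                               overlap = 0.70, taper = "hamming",
                               pooled = FALSE) {
  nch <- length(epochs@channelIds)
  .assert(nch >= 2, "need at least 2 channels")
  fs <- epochs@samplingRate
  nsamp <- dim(epochs@epochs[[1L]])[2L]
  wp <- .welchParams(fs, nsamp, window, overlap, taper)
  binIdx <- .bandBins(wp$freq, scheme, fs)
  bins <- sort(unique(unlist(binIdx)))
  binPos <- lapply(binIdx, match, bins)
  nb <- length(scheme)

  ut <- which(upper.tri(matrix(0, nch, nch)), arr.ind = TRUE)
  pairs <- data.frame(chan_a = epochs@channelIds[ut[, 1L]],
                      chan_b = epochs@channelIds[ut[, 2L]],
                      stringsAsFactors = FALSE)
  np <- nrow(ut)
  iu <- ut[, 1L]; ju <- ut[, 2L]
  nbin <- length(bins)
  crossIdx <- cbind(rep(iu, times = nbin), rep(ju, times = nbin),
                    rep(seq_len(nbin), each = np))
  autoIdx <- cbind(rep(seq_len(nch), times = nbin),
                   rep(seq_len(nch), times = nbin),
                   rep(seq_len(nbin), each = nch))

  values <- list(); pooledOut <- list()
  absent <- character()
  for (cond in names(epochs@epochs)) {
    arr <- epochs@epochs[[cond]]
    mask <- epochs@keepMask[[cond]]
    ne <- dim(arr)[3L]
    vals <- array(NA_real_, dim = c(np, nb, ne))
    if (pooled) {
      PxyAcc <- matrix(complex(1), np, length(bins))
      PxxAccA <- matrix(0, np, length(bins))
      PxxAccB <- matrix(0, np, length(bins))
    }
    pairValid <- mask[iu, , drop = FALSE] & mask[ju, , drop = FALSE]
    for (e in seq_len(ne)) {
      if (!any(pairValid[, e])) next
      F <- .segmentFFT(arr[, , e, drop = TRUE], wp, bins = bins)
      G <- .crossSpectra(F)                     # nch x nch x bins
      pv <- pairValid[, e]
      Pxy <- matrix(G[crossIdx], np, nbin)
      auto <- matrix(Re(G[autoIdx]), nch, nbin)
      cohBin <- Mod(Pxy)^2 / (auto[iu, , drop = FALSE] * auto[ju, , drop = FALSE])
      cohBin <- pmin(pmax(cohBin, 0), 1)
      for (b in seq_len(nb))
        vals[pv, b, e] <- rowMeans(cohBin[pv, binPos[[b]], drop = FALSE])
      if (pooled) {
        PxyAcc[pv, ] <- PxyAcc[pv, ] + Pxy[pv, ]
        PxxAccA[pv, ] <- PxxAccA[pv, ] + auto[iu[pv], , drop = FALSE]
        PxxAccB[pv, ] <- PxxAccB[pv, ] + auto[ju[pv], , drop = FALSE]
      }
    }
    if (all(is.na(vals))) absent <- c(absent, cond)
    values[[cond]] <- vals
    if (pooled) {
      cohPool <- Mod(PxyAcc)^2 / (PxxAccA * PxxAccB)
      cohPool <- pmin(pmax(cohPool, 0), 1)
      pm <- matrix(NA_real_, np, nb)
      for (b in seq_len(nb))
        pm[, b] <- rowMeans(cohPool[, binPos[[b]], drop = FALSE])
      pm[rowSums(pairValid) == 0, ] <- NA_real_
      pooledOut[[cond]] <- pm
    }
  }
  if (length(absent))
    warning("no valid epochs for condition(s): ", paste(absent, collapse = ", "))
  methods::new("PairBandTable", values = values, pooled = pooledOut,
               pairs = pairs, bands = scheme, channelIds = epochs@channelIds)
}

#' Baseline-subtracted coherence change per electrode pair
#'
#' For each electrode pair, condition and band: mean coherence over the
#' condition's valid epochs minus mean coherence over the pair's valid
#' baseline epochs. Pairs with no valid baseline epoch are excluded and
#' reported in the \code{"excluded"} attribute.
#'
#' @param table a \linkS4class{PairBandTable} containing a
#'   \code{"baseline"} condition.
#' @param use \code{"perEpoch"} (default) subtracts means of per-epoch
#'   estimates; \code{"pooled"} subtracts pooled cross-epoch estimates
#'   (requires \code{pairConditionTable(pooled = TRUE)}).
#' @return data.frame with columns \code{chan_a}, \code{chan_b},
#'   \code{condition}, \code{band}, \code{delta}, \code{n_cond},
#'   \code{n_base}.
#' @export
baselineSubtract <- function(table, use = c("perEpoch", "pooled")) {
  use <- match.arg(use)
  .assert("baseline" %in% names(table@values),
          "table has no 'baseline' condition")
  conds <- setdiff(names(table@values), "baseline")
  nb <- length(table@bands)
  np <- nrow(table@pairs)
  baseArr <- table@values[["baseline"]]
  nBase <- apply(!is.na(baseArr[, 1L, , drop = FALSE]), 1L, sum)
  ok <- nBase >= 1L
  out <- list()
  for (cond in conds) {
    arr <- table@values[[cond]]
    nCond <- apply(!is.na(arr[, 1L, , drop = FALSE]), 1L, sum)
    for (b in seq_len(nb)) {
      if (use == "perEpoch") {
        mCond <- rowMeans(arr[, b, , drop = FALSE], na.rm = TRUE, dims = 1L)
        mBase <- rowMeans(baseArr[, b, , drop = FALSE], na.rm = TRUE, dims = 1L)
      } else {
        .assert(length(table@pooled) > 0,
                "no pooled estimates stored; rerun pairConditionTable(pooled = TRUE)")
        mCond <- table@pooled[[cond]][, b]
        mBase <- table@pooled[["baseline"]][, b]
      }
      keep <- ok & nCond >= 1L
      out[[length(out) + 1L]] <- data.frame(
        chan_a = table@pairs$chan_a[keep], chan_b = table@pairs$chan_b[keep],
        condition = cond, band = names(table@bands)[b],
        delta = (mCond - mBase)[keep],
        n_cond = nCond[keep], n_base = nBase[keep],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  excluded <- table@pairs[!ok, , drop = FALSE]
  if (nrow(excluded))
    warning(nrow(excluded), " pair(s) excluded: no valid baseline epochs")
  attr(res, "excluded") <- excluded
  res
}

#' Aggregate electrode-pair deltas to region pairs (subject level)
#'
#' Region-pair delta = mean of delta over all electrode pairs whose two
#' contacts lie in the two regions. Within-region pairs (distinct contacts,
#' same region) populate the diagonal; channels carrying an exclusion class
#' (white matter, ventricle, unknown) contribute to no region pair.
#'
#' @param deltas data.frame from \code{\link{baselineSubtract}}.
#' @param channels channel table (columns \code{channel_id}, \code{region},
#'   \code{exclude_class}).
#' @return a \linkS4class{RegionPairDelta} at subject level.
#' @export
regionize <- function(deltas, channels) {
  reg <- stats::setNames(channels$region, channels$channel_id)
  excl <- stats::setNames(channels$exclude_class, channels$channel_id)
  .assert(all(deltas$chan_a %in% names(reg)) && all(deltas$chan_b %in% names(reg)),
          "every contributing channel needs a channel-table row")
  keep <- excl[deltas$chan_a] == "" & excl[deltas$chan_b] == ""
  d <- deltas[keep, , drop = FALSE]
  ra <- reg[d$chan_a]; rb <- reg[d$chan_b]
  cp <- .canonicalPair(ra, rb)
  key <- paste(cp$a, cp$b, d$condition, d$band, sep = "\r")
  agg <- tapply(d$delta, key, mean)
  cnt <- tapply(d$delta, key, length)
  parts <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
  tb <- data.frame(region_a = parts[, 1L], region_b = parts[, 2L],
                   condition = parts[, 3L], band = parts[, 4L],
                   delta = as.numeric(agg), n_pairs = as.integer(cnt),
                   stringsAsFactors = FALSE)
  tb <- tb[order(tb$condition, tb$band, tb$region_a, tb$region_b), ]
  rownames(tb) <- NULL
  methods::new("RegionPairDelta", table = tb, level = "subject")
}

#' Group-level aggregation of subject region-pair deltas
#'
#' Per region pair, condition and band: mean of the subject-level deltas
#' across the subjects with coverage of that pair; pairs covered by no
#' subject are absent. Records the contributing-subject count.
#'
#' @param subjectTables list of subject-level \linkS4class{RegionPairDelta}.
#' @return a \linkS4class{RegionPairDelta} at group level.
#' @export
groupAggregate <- function(subjectTables) {
  .assert(length(subjectTables) >= 1, "need at least one subject")
  tb <- do.call(rbind, lapply(subjectTables, deltaTable))
  key <- paste(tb$region_a, tb$region_b, tb$condition, tb$band, sep = "\r")
  agg <- tapply(tb$delta, key, mean)
  nsub <- tapply(tb$delta, key, length)
  npair <- tapply(tb$n_pairs, key, sum)
  parts <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
  out <- data.frame(region_a = parts[, 1L], region_b = parts[, 2L],
                    condition = parts[, 3L], band = parts[, 4L],
                    delta = as.numeric(agg), n_pairs = as.integer(npair),
                    n_subjects = as.integer(nsub), stringsAsFactors = FALSE)
  out <- out[order(out$condition, out$band, out$region_a, out$region_b), ]
  rownames(out) <- NULL
  methods::new("RegionPairDelta", table = out, level = "group")
}
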