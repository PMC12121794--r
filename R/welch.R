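# Welch cross-spectral engine.
#
# All coherence estimates in the package come through here: tapered,
# overlapping segments; per-segment FFT; auto- and cross-spectra accumulated
# across segments. Constant scale factors (window power, fs) cancel in
# magnitude-squared coherence and are omitted.

.taper <- function(n, type = c("hamming", "hann")) {
  type <- match.arg(type)
  k <- 2 * pi * (0:(n - 1)) / (n - 1)
  if (type == "hamming") 0.54 - 0.46 * cos(k) else 0.5 - 0.5 * cos(k)
}

.segmentStarts <- function(nSamples, segLen, hop) {
  .assert(nSamples >= segLen, "signal shorter than one window")
  seq.int(1L, nSamples - segLen + 1L, by = hop)
}

.welchParams <- function(fs, nSamples, window, overlap, taper = "hamming") {
  segLen <- round(window * fs)
  .assert(segLen >= 2, "window too short")
  hop <- max(1L, round((1 - overlap) * segLen))
  starts <- .segmentStarts(nSamples, segLen, hop)
  K <- length(starts)
  .assert(K >= 2,
          "single-segment coherence is identically 1; ",
          "use a window shorter than the epoch (K >= 2 required)")
  nbin <- segLen %/% 2L + 1L
  list(segLen = segLen, hop = hop, starts = starts, K = K,
       freq = (seq_len(nbin) - 1L) * fs / segLen,
       win = .taper(segLen, taper))
}

# FFT of all tapered segments of all channels in one epoch.
# x: channels x samples. Returns complex array (bins x channels x K).
.segmentFFT <- function(x, wp, bins = NULL) {
  nch <- nrow(x)
  nbin <- wp$segLen %/% 2L + 1L
  keep <- if (is.null(bins)) seq_len(nbin) else bins
  out <- array(complex(1), dim = c(length(keep), nch, wp$K))
  for (k in seq_len(wp$K)) {
    seg <- t(x[, wp$starts[k]:(wp$starts[k] + wp$segLen - 1L), drop = FALSE]) *
      wp$win
    F <- stats::mvfft(seg)
    out[, , k] <- F[keep, , drop = FALSE]
  }
  out
}

# Per-bin cross-spectral matrices for one epoch: for each retained bin b,
# G[, , b] = sum_k z_k z_k^H over segments (z = channel FFT vector at bin b).
.crossSpectra <- function(segFFT) {
  d <- dim(segFFT)
  nbin <- d[1L]; nch <- d[2L]
  G <- array(complex(1), dim = c(nch, nch, nbin))
  for (b in seq_len(nbin)) {
    Z <- matrix(segFFT[b, , ], nrow = nch)     # channels x K
    G[, , b] <- Z %*% Conj(t(Z))
  }
  G
}

# Coherence of a single pair from accumulated spectra.
.cohFromSpectra <- function(Pxy, Pxx, Pyy) {
  c <- Mod(Pxy)^2 / (Re(Pxx) * Re(Pyy))
  pmin(pmax(c, 0), 1)
}
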