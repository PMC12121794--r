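#' Zero-phase Butterworth highpass filter
#'
#' Removes DC and slow drift with a 4th-order Butterworth highpass applied
#' forward and backward (zero phase) to every channel.
#'
#' @param bundle a \linkS4class{SessionBundle}.
#' @param cutoff cutoff frequency, Hz (default 0.5).
#' @param order filter order (default 4).
#' @return the filtered \linkS4class{SessionBundle}.
#' @export
highpassFilter <- function(bundle, cutoff = 0.5, order = 4) {
  fs <- bundle@samplingRate
  .assert(cutoff > 0 && cutoff < fs / 2, "cutoff must lie in (0, Nyquist)")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "high")
  bundle@signals <- t(apply(bundle@signals, 1L,
                            function(ch) signal::filtfilt(bf, ch)))
  rownames(bundle@signals) <- bundle@channels$channel_id
  bundle
}

#' Zero-phase IIR notch filter
#'
#' Second-order IIR notch (constrained biquad) at the line frequency,
#' applied forward and backward to every channel.
#'
#' @param bundle a \linkS4class{SessionBundle}.
#' @param freq notch center frequency, Hz (default 60).
#' @param Q quality factor; the -3 dB bandwidth is freq/Q (default 30).
#' @return the filtered \linkS4class{SessionBundle}.
#' @export
notchFilter <- function(bundle, freq = 60, Q = 30) {
  fs <- bundle@samplingRate
  .assert(freq > 0 && freq < fs / 2, "notch frequency must lie in (0, Nyquist)")
  w0 <- 2 * pi * freq / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  bundle@signals <- t(apply(bundle@signals, 1L,
                            function(ch) signal::filtfilt(b, a, ch)))
  rownames(bundle@signals) <- bundle@channels$channel_id
  bundle
}

#' Detect channels with excessive line noise
#'
#' Per channel, line-noise power is the Welch power spectral density
#' integrated over a narrow band around the line frequency (59-61 Hz by
#' default). Channels whose power exceeds the cross-channel median by more
#' than three mean absolute deviations (about the median) are flagged.
#'
#' @param bundle a \linkS4class{SessionBundle}.
#' @param freqBand integration band, Hz (default c(59, 61)).
#' @param nMad flag threshold in deviations above the median (default 3).
#' @param window Welch segment length in seconds for the PSD (default 2).
#' @param dispersion \code{"mean"} (mean absolute deviation about the median,
#'   default) or \code{"median"} (median absolute deviation).
#' @return character vector of flagged channel ids, with the per-channel
#'   power in attribute \code{"power"}.
#' @export
detectLineNoiseChannels <- function(bundle, freqBand = c(59, 61), nMad = 3,
                                    window = 2, dispersion = "mean") {
  fs <- bundle@samplingRate
  nch <- nrow(bundle@signals)
  .assert(nch >= 3, "robust statistics need at least 3 channels")
  .assert(ncol(bundle@signals) >= 2 * window * fs,
          "recording too short for line-noise detection")
  wp <- .welchParams(fs, ncol(bundle@signals), window, 0.5)
  idx <- which(wp$freq >= freqBand[1] & wp$freq <= freqBand[2])
  pow <- numeric(nch)
  # accumulate per-channel auto-spectra over segments, band bins only
  for (k in seq_len(wp$K)) {
    seg <- t(bundle@signals[, wp$starts[k]:(wp$starts[k] + wp$segLen - 1L),
                            drop = FALSE]) * wp$win
    F <- stats::mvfft(seg)[idx, , drop = FALSE]
    pow <- pow + colSums(Mod(F)^2)
  }
  med <- stats::median(pow)
  disp <- .madAboutMedian(pow, dispersion)
  flagged <- bundle@channels$channel_id[pow > med + nMad * disp]
  structure(flagged, power = stats::setNames(pow, bundle@channels$channel_id))
}

#' Common average reference
#'
#' Subtracts the instantaneous mean of the kept channels from each kept
#' channel; channels not kept are dropped from the output bundle.
#'
#' @param bundle a \linkS4class{SessionBundle}.
#' @param keep channel ids to keep (default: all channels).
#' @return the re-referenced \linkS4class{SessionBundle} containing only the
#'   kept channels.
#' @export
applyCAR <- function(bundle, keep = channelIds(bundle)) {
  idx <- match(keep, bundle@channels$channel_id)
  .assert(!anyNA(idx), "unknown channel id in 'keep'")
  .assert(length(idx) >= 2, "CAR needs at least 2 kept channels")
  sig <- bundle@signals[idx, , drop = FALSE]
  ref <- colMeans(sig)
  bundle@signals <- sig - rep(ref, each = nrow(sig))
  bundle@channels <- bundle@channels[idx, , drop = FALSE]
  rownames(bundle@channels) <- NULL
  rownames(bundle@signals) <- bundle@channels$channel_id
  methods::validObject(bundle)
  bundle
}

#' Cut a session into fixed-length condition-labelled epochs
#'
#' The baseline event is split into consecutive non-overlapping epochs of the
#' requested duration; each stimulation event yields one epoch under its
#' condition label. Off-periods (samples covered by no event) are discarded.
#'
#' @param bundle a \linkS4class{SessionBundle}.
#' @param epochDuration epoch length in seconds (default 5).
#' @return an \linkS4class{EpochSet} with an all-true keep mask.
#' @export
epochSession <- function(bundle, epochDuration = 5) {
  fs <- bundle@samplingRate
  len <- round(epochDuration * fs)
  ev <- bundle@events
  .assert(nrow(ev) > 0, "no events")
  ends <- ev$onset_sample + ev$duration_samples - 1
  .assert(all(ends <= ncol(bundle@signals)),
          "event extends past the recording end")
  epochs <- list(); mask <- list()
  base <- ev[ev$condition == "baseline", , drop = FALSE]
  .assert(nrow(base) == 1L, "expected exactly one baseline event")
  nBase <- base$duration_samples %/% len
  .assert(nBase >= 1, "baseline shorter than one epoch")
  starts <- base$onset_sample + (seq_len(nBase) - 1L) * len
  allConds <- c("baseline",
                unique(ev$condition[ev$condition != "baseline"]))
  for (cond in allConds) {
    if (cond == "baseline") {
      s <- starts
    } else {
      s <- ev$onset_sample[ev$condition == cond]
      .assert(all(ev$duration_samples[ev$condition == cond] >= len),
              "stimulation event shorter than the epoch duration")
    }
    arr <- array(NA_real_,
                 dim = c(nrow(bundle@signals), len, length(s)))
    for (e in seq_along(s))
      arr[, , e] <- bundle@signals[, s[e]:(s[e] + len - 1L), drop = FALSE]
    epochs[[cond]] <- arr
    mask[[cond]] <- matrix(TRUE, nrow(bundle@signals), length(s))
  }
  methods::new("EpochSet", epochs = epochs, keepMask = mask,
               samplingRate = fs, channelIds = bundle@channels$channel_id)
}

#' Amplitude-based rejection of spike-contaminated channel-epochs
#'
#' Sets the keep mask to FALSE for every (channel, epoch) whose absolute
#' amplitude strictly exceeds the threshold ("exceeding 500 microvolts":
#' an epoch peaking at exactly the threshold is kept). A per-condition
#' rejection summary is attached as attribute \code{"rejection"}.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param threshold rejection threshold, microvolts (default 500).
#' @return the \linkS4class{EpochSet} with an updated keep mask.
#' @export
rejectSpikeEpochs <- function(epochs, threshold = 500) {
  summ <- list()
  for (cond in names(epochs@epochs)) {
    arr <- epochs@epochs[[cond]]
    peaks <- apply(abs(arr), c(1L, 3L), max)
    bad <- peaks > threshold
    epochs@keepMask[[cond]] <- epochs@keepMask[[cond]] & !bad
    summ[[cond]] <- data.frame(condition = cond,
                               n_channel_epochs = length(bad),
                               n_rejected = sum(bad),
                               proportion = mean(bad),
                               stringsAsFactors = FALSE)
  }
  rej <- do.call(rbind, summ)
  rownames(rej) <- NULL
  if (any(vapply(epochs@keepMask, function(m) any(colSums(m) == 0), logical(1))))
    warning("some epochs have no kept channels")
  attr(epochs, "rejection") <- rej
  epochs
}

#' Downsample an epoch set
#'
#' Anti-alias lowpass (8th-order Butterworth at 0.8 x the new Nyquist,
#' zero-phase) followed by decimation. The native rate must be an integer
#' multiple of the target rate.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param target target sampling rate, Hz (default 500).
#' @param aaOrder anti-alias filter order (default 8).
#' @return the downsampled \linkS4class{EpochSet}.
#' @export
downsampleEpochs <- function(epochs, target = 500, aaOrder = 8) {
  fs <- epochs@samplingRate
  factor <- fs / target
  .assert(abs(factor - round(factor)) < 1e-9,
          "native rate must be an integer multiple of the target rate")
  factor <- as.integer(round(factor))
  if (factor == 1L) return(epochs)
  bf <- signal::butter(aaOrder, 0.8 * (target / 2) / (fs / 2), type = "low")
  pick <- NULL
  for (cond in names(epochs@epochs)) {
    arr <- epochs@epochs[[cond]]
    d <- dim(arr)
    if (is.null(pick)) pick <- seq.int(1L, d[2L], by = factor)
    out <- array(NA_real_, dim = c(d[1L], length(pick), d[3L]))
    for (e in seq_len(d[3L]))
      for (ch in seq_len(d[1L]))
        out[ch, , e] <- signal::filtfilt(bf, arr[ch, , e])[pick]
    epochs@epochs[[cond]] <- out
  }
  epochs@samplingRate <- target
  epochs
}

#' Full preprocessing chain for one session
#'
#' Fixed order: highpass, line-noise channel detection and exclusion,
#' label-based channel exclusion (white matter / ventricle / unknown),
#' common average reference over the kept channels, notch filter, epoching,
#' spike rejection, downsampling.
#'
#' @param bundle a \linkS4class{SessionBundle}.
#' @param config a \code{\link{runConfig}} list of parameters.
#' @return list with elements \code{epochs} (the clean
#'   \linkS4class{EpochSet}), \code{channels} (kept channel table) and
#'   \code{report} (excluded channels and rejection proportions).
#' @export
preprocessSession <- function(bundle, config = runConfig()) {
  bundle <- highpassFilter(bundle, config$highpassCutoff, config$highpassOrder)
  noisy <- detectLineNoiseChannels(bundle, config$lineNoiseBand,
                                   config$lineNoiseMad,
                                   dispersion = config$madDispersion)
  labelExcl <- bundle@channels$channel_id[bundle@channels$exclude_class != ""]
  keep <- setdiff(bundle@channels$channel_id, union(noisy, labelExcl))
  .assert(length(keep) >= 2, "fewer than 2 channels survive exclusion")
  bundle <- applyCAR(bundle, keep)
  bundle <- notchFilter(bundle, config$lineNoiseFreq, config$notchQ)
  epochs <- epochSession(bundle, config$epochDuration)
  if (identical(config$spikeRejectOn, "raw"))
    warning("spike rejection on raw signals is configured via rejectSpikeEpochs ",
            "on an unpreprocessed EpochSet; the chain applies it post-CAR/notch")
  epochs <- rejectSpikeEpochs(epochs, config$spikeThreshold)
  rejection <- attr(epochs, "rejection")
  epochs <- downsampleEpochs(epochs, config$targetRate)
  list(epochs = epochs, channels = bundle@channels,
       report = list(lineNoiseChannels = as.character(noisy),
                     labelExcluded = labelExcl,
                     keptChannels = keep,
                     rejection = rejection))
}
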