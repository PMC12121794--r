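#' Configuration for a synthetic stimulation session
#'
#' Describes a session emulating the study design: a resting baseline
#' followed by randomized fixed-length stimulation trials (five vibration
#' frequencies by default, 30 trials each, 5 s on / 5 s off), recorded from
#' region-grouped channels carrying 1/f background noise, weak within-region
#' shared sources, and optional ground-truth couplings and artifacts.
#'
#' @param samplingRate Hz (default 2000).
#' @param baselineDuration baseline length, s (default 180).
#' @param trialDuration stimulation trial length, s (default 5).
#' @param offDuration inter-trial off period, s (default 5).
#' @param conditions ordered condition labels (default the five vibration
#'   frequencies "2Hz".."40Hz").
#' @param trialsPerCondition trials per condition (default 30).
#' @param regions named integer vector: channels per region label.
#' @param couplings list of \code{\link{couplingSpec}} entries.
#' @param artifacts list with optional \code{lineNoiseChannels} (channel
#'   indices), \code{lineNoiseAmplitude} (microvolts), and \code{spikes}
#'   data.frame (columns \code{channel}, \code{epoch} — stimulation-trial
#'   index — \code{peak} microvolts, \code{width} ms).
#' @param noise list: \code{alpha} 1/f exponent (default 1), \code{sd}
#'   per-channel background SD in microvolts (default 10), \code{sharedSd}
#'   SD of the per-region shared source (default 3).
#' @param seed RNG seed.
#' @return validated list of class \code{SynthConfig}.
#' @export
synthConfig <- function(samplingRate = 2000, baselineDuration = 180,
                        trialDuration = 5, offDuration = 5,
                        conditions = c("2Hz", "6Hz", "12Hz", "20Hz", "40Hz"),
                        trialsPerCondition = 30,
                        regions = c("L-Amygdala" = 3, "L-Hippocampus" = 3,
                                    "L-ACC" = 3, "L-OFC" = 3, "L-PHG" = 3,
                                    "L-Temporal" = 3),
                        couplings = list(), artifacts = list(),
                        noise = list(alpha = 1, sd = 10, sharedSd = 3),
                        seed = 1L) {
  cfg <- list(samplingRate = samplingRate, baselineDuration = baselineDuration,
              trialDuration = trialDuration, offDuration = offDuration,
              conditions = conditions, trialsPerCondition = trialsPerCondition,
              regions = regions, couplings = couplings, artifacts = artifacts,
              noise = utils::modifyList(list(alpha = 1, sd = 10, sharedSd = 3),
                                        noise),
              seed = as.integer(seed))
  .assert(samplingRate > 0 && baselineDuration > 0 && trialDuration > 0 &&
            offDuration >= 0 && trialsPerCondition >= 1,
          "invalid timing configuration")
  .assert(length(regions) >= 1 && !is.null(names(regions)) &&
            all(regions >= 1), "regions must be a named count vector")
  for (cs in couplings) {
    .assert(inherits(cs, "CouplingSpec"), "couplings must be couplingSpec()s")
    .assert(all(c(cs$regionA, cs$regionB) %in% names(regions)),
            "coupling region not in the region list")
    .assert(cs$condition %in% c(conditions, "baseline"),
            "coupling condition not in the condition list")
    .assert(cs$band[2] <= samplingRate / 2,
            "coupling band exceeds the Nyquist frequency")
  }
  class(cfg) <- "SynthConfig"
  cfg
}

#' Ground-truth coupling between two regions
#'
#' A band-limited unit-variance source added, scaled by
#' \code{gain * sqrt(sourcePower)}, to all channels of both regions during
#' the ON epochs of the designated condition. \code{noisePower} is the
#' nominal in-band channel noise power used to compute the expected band
#' coherence (see \code{\link{expectedBandMsc}}).
#'
#' @param regionA,regionB region labels.
#' @param band frequency interval c(low, high), Hz.
#' @param condition condition label (or "baseline").
#' @param gain dimensionless amplitude a >= 0.
#' @param sourcePower source variance, microvolts^2 (default 1).
#' @param noisePower nominal in-band channel noise power, microvolts^2.
#' @return list of class \code{CouplingSpec}.
#' @export
couplingSpec <- function(regionA, regionB, band, condition, gain,
                         sourcePower = 1, noisePower = 1) {
  .assert(gain >= 0, "gain must be >= 0")
  .assert(length(band) == 2 && band[1] > 0 && band[2] > band[1],
          "band must be c(low, high) with 0 < low < high")
  structure(list(regionA = regionA, regionB = regionB, band = band,
                 condition = condition, gain = gain,
                 sourcePower = sourcePower, noisePower = noisePower),
            class = "CouplingSpec")
}

#' Expected band coherence of a coupled pair
#'
#' For x = a s + n1, y = a s + n2 with a shared band-limited source s of
#' power sigmaS2 and independent like-spectrum noises of power sigmaN2, the
#' magnitude-squared coherence in the band is
#' (a^2 sigmaS2 / (a^2 sigmaS2 + sigmaN2))^2.
#'
#' @param a coupling gain.
#' @param sigmaS2 source power.
#' @param sigmaN2 in-band noise power (must be > 0).
#' @return expected coherence in \[0, 1\].
#' @examples
#' expectedBandMsc(0, 1, 1)      # 0
#' expectedBandMsc(1, 1, 1)      # 0.25
#' @export
expectedBandMsc <- function(a, sigmaS2, sigmaN2) {
  .assert(sigmaN2 > 0, "sigmaN2 must be > 0")
  .assert(a >= 0 && sigmaS2 >= 0, "a and sigmaS2 must be >= 0")
  (a^2 * sigmaS2 / (a^2 * sigmaS2 + sigmaN2))^2
}

#' 1/f^alpha Gaussian background noise
#'
#' Spectrally shaped Gaussian noise: white noise filtered in the frequency
#' domain by f^(-alpha/2), standardized to the requested SD.
#'
#' @param n number of samples.
#' @param alpha spectral exponent (0 = white, 1 = pink).
#' @param sd target standard deviation.
#' @return numeric vector of length n.
#' @export
pinkNoise <- function(n, alpha = 1, sd = 1) {
  w <- stats::rnorm(n)
  if (alpha == 0) return(w * sd)
  F <- stats::fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)          # symmetric frequency index, DC guarded
  F <- F * f^(-alpha / 2)
  x <- Re(stats::fft(F, inverse = TRUE)) / n
  sd * (x - mean(x)) / stats::sd(x)
}

#' Band-limited unit-variance Gaussian noise
#'
#' White noise passed through a zero-phase 4th-order Butterworth bandpass,
#' renormalized to unit variance.
#'
#' @param n number of samples.
#' @param band c(low, high), Hz; must lie within (0, Nyquist).
#' @param fs sampling rate, Hz.
#' @param order filter order (default 4).
#' @return numeric vector of length n with SD 1.
#' @export
bandLimitedNoise <- function(n, band, fs, order = 4) {
  .assert(band[1] > 0 && band[2] < fs / 2, "band must lie within (0, Nyquist)")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  x / stats::sd(x)
}

#' Add a shared band-limited source to designated channels during epochs
#'
#' Adds \code{gain * sqrt(sourcePower) * s(t)}, with s band-limited
#' unit-variance noise, to every listed channel, only inside the given
#' epochs; the signal outside the epochs is untouched. With gain 0 the input
#' is returned unchanged.
#'
#' @param signals channels x samples matrix.
#' @param fs sampling rate, Hz.
#' @param channels row indices receiving the source.
#' @param band frequency interval c(low, high), Hz, within (0, Nyquist).
#' @param gain coupling amplitude a.
#' @param sourcePower source variance (default 1).
#' @param onsets epoch onset samples (1-based).
#' @param duration epoch length in samples.
#' @return the signal matrix with the source added.
#' @export
injectCoupling <- function(signals, fs, channels, band, gain, sourcePower = 1,
                           onsets, duration) {
  .assert(band[2] < fs / 2, "coupling band exceeds the Nyquist frequency")
  .assert(all(onsets >= 1) && all(onsets + duration - 1 <= ncol(signals)),
          "epochs must lie within the recording")
  if (gain == 0) return(signals)
  s <- bandLimitedNoise(ncol(signals), band, fs)
  gate <- rep(0, ncol(signals))
  for (on in onsets) gate[on:(on + duration - 1L)] <- 1
  add <- gain * sqrt(sourcePower) * s * gate
  signals[channels, ] <- signals[channels, , drop = FALSE] +
    rep(add, each = length(channels))
  signals
}

# biphasic raised-cosine transient, unit peak
.spikeShape <- function(nSamples) {
  u <- seq(0, 1, length.out = nSamples)
  w <- sin(2 * pi * u) * (0.5 - 0.5 * cos(2 * pi * u))
  w / max(abs(w))
}

#' Inject line-noise and interictal-spike artifacts
#'
#' Adds a 60 Hz sinusoid to designated channels and biphasic raised-cosine
#' transients with exact specified peak amplitude at designated
#' (channel, stimulation-epoch) slots. Returns the modified signals and a
#' log of every injection.
#'
#' @param signals channels x samples matrix.
#' @param fs sampling rate, Hz.
#' @param spec artifact list: \code{lineNoiseChannels}, \code{lineNoiseAmplitude}
#'   (microvolts, default 50), \code{spikes} data.frame with columns
#'   \code{channel}, \code{epoch}, \code{peak} (microvolts) and optional
#'   \code{width} (ms, default 40).
#' @param epochOnsets onset samples of the stimulation epochs that the
#'   \code{epoch} column of \code{spec$spikes} indexes.
#' @param epochDurationSamples epoch length in samples.
#' @return list: \code{signals}, \code{log} (data.frame of injections).
#' @export
injectArtifacts <- function(signals, fs, spec, epochOnsets = integer(),
                            epochDurationSamples = NULL) {
  log <- list()
  if (length(spec$lineNoiseChannels)) {
    amp <- if (is.null(spec$lineNoiseAmplitude)) 50 else spec$lineNoiseAmplitude
    .assert(all(spec$lineNoiseChannels >= 1 &
                  spec$lineNoiseChannels <= nrow(signals)),
            "line-noise channel out of range")
    tt <- seq_len(ncol(signals)) / fs
    wave <- amp * sin(2 * pi * 60 * tt)
    for (ch in spec$lineNoiseChannels) {
      signals[ch, ] <- signals[ch, ] + wave
      log[[length(log) + 1L]] <- data.frame(type = "line_noise", channel = ch,
                                            epoch = NA_integer_, amplitude = amp)
    }
  }
  sp <- spec$spikes
  if (!is.null(sp) && nrow(sp)) {
    .assert(length(epochOnsets) > 0 && !is.null(epochDurationSamples),
            "spike injection needs the epoch schedule")
    .assert(all(sp$epoch >= 1 & sp$epoch <= length(epochOnsets)),
            "spike epoch index out of range")
    .assert(all(sp$channel >= 1 & sp$channel <= nrow(signals)),
            "spike channel out of range")
    for (i in seq_len(nrow(sp))) {
      widthMs <- if (is.null(sp$width)) 40 else sp$width[i]
      nw <- max(8L, round(widthMs / 1000 * fs))
      shape <- .spikeShape(nw) * sp$peak[i]
      center <- epochOnsets[sp$epoch[i]] + epochDurationSamples %/% 2L
      at <- center - nw %/% 2L
      idx <- at:(at + nw - 1L)
      # replace rather than add so the absolute peak equals the spec exactly
      signals[sp$channel[i], idx] <- shape
      log[[length(log) + 1L]] <- data.frame(type = "spike",
                                            channel = sp$channel[i],
                                            epoch = sp$epoch[i],
                                            amplitude = sp$peak[i])
    }
  }
  list(signals = signals,
       log = if (length(log)) do.call(rbind, log) else
         data.frame(type = character(), channel = integer(),
                    epoch = integer(), amplitude = numeric()))
}

#' Build a synthetic session with known ground truth
#'
#' Generates the full recording: randomized trial schedule, per-channel 1/f
#' background, weak per-region shared sources, ground-truth couplings gated
#' by their conditions' ON epochs, and artifacts. The returned ground truth
#' carries the realized schedule, the coupling list with expected band
#' coherence, and the artifact log. A fixed seed makes the output
#' bit-identical.
#'
#' @param config a \code{\link{synthConfig}}.
#' @return list with elements \code{bundle} (a
#'   \linkS4class{SessionBundle}) and \code{truth} (class
#'   \code{GroundTruth}).
#' @export
buildSession <- function(config) {
  .assert(inherits(config, "SynthConfig"), "config must be a synthConfig()")
  .withSeed(config$seed, {
    fs <- config$samplingRate
    nTrials <- config$trialsPerCondition * length(config$conditions)
    trialLen <- round(config$trialDuration * fs)
    offLen <- round(config$offDuration * fs)
    baseLen <- round(config$baselineDuration * fs)
    nSamp <- baseLen + nTrials * (trialLen + offLen)

    sched <- data.frame(
      trial = seq_len(nTrials),
      condition = sample(rep(config$conditions, each = config$trialsPerCondition)),
      onset_sample = baseLen + (seq_len(nTrials) - 1L) * (trialLen + offLen) + 1L,
      stringsAsFactors = FALSE)

    regionOf <- rep(names(config$regions), config$regions)
    nch <- length(regionOf)
    chanIds <- sprintf("ch%02d", seq_len(nch))
    signals <- matrix(0, nch, nSamp)
    for (ch in seq_len(nch))
      signals[ch, ] <- pinkNoise(nSamp, config$noise$alpha, config$noise$sd)
    if (config$noise$sharedSd > 0) {
      for (rg in names(config$regions)) {
        shared <- pinkNoise(nSamp, config$noise$alpha, config$noise$sharedSd)
        idx <- which(regionOf == rg)
        signals[idx, ] <- signals[idx, , drop = FALSE] +
          rep(shared, each = length(idx))
      }
    }

    expected <- list()
    for (cs in config$couplings) {
      chans <- which(regionOf %in% c(cs$regionA, cs$regionB))
      if (cs$condition == "baseline") {
        onsets <- 1L + (seq_len(baseLen %/% trialLen) - 1L) * trialLen
      } else {
        onsets <- sched$onset_sample[sched$condition == cs$condition]
      }
      signals <- injectCoupling(signals, fs, chans, cs$band, cs$gain,
                                cs$sourcePower, onsets, trialLen)
      expected[[length(expected) + 1L]] <- data.frame(
        region_a = cs$regionA, region_b = cs$regionB,
        band_low = cs$band[1], band_high = cs$band[2],
        condition = cs$condition,
        expected_msc = expectedBandMsc(cs$gain, cs$sourcePower, cs$noisePower),
        stringsAsFactors = FALSE)
    }

    art <- injectArtifacts(signals, fs, config$artifacts,
                           epochOnsets = sched$onset_sample,
                           epochDurationSamples = trialLen)
    signals <- art$signals
    rownames(signals) <- chanIds

    events <- rbind(
      data.frame(condition = "baseline", onset_sample = 1L,
                 duration_samples = baseLen, stringsAsFactors = FALSE),
      data.frame(condition = sched$condition, onset_sample = sched$onset_sample,
                 duration_samples = trialLen, stringsAsFactors = FALSE))
    channels <- data.frame(channel_id = chanIds, region = regionOf,
                           exclude_class = "", stringsAsFactors = FALSE)
    bundle <- methods::new("SessionBundle", subjectId = "synthetic",
                           samplingRate = fs, signals = signals,
                           channels = channels, events = events)
    truth <- structure(list(
      schedule = sched,
      couplings = config$couplings,
      artifactLog = art$log,
      expectedMsc = if (length(expected)) do.call(rbind, expected) else
        data.frame(),
      config = config), class = "GroundTruth")
    list(bundle = bundle, truth = truth)
  })
}

#' @export
print.GroundTruth <- function(x, ...) {
  cat(sprintf("GroundTruth: %d trials (%s), %d coupling(s), %d artifact(s)\n",
              nrow(x$schedule),
              paste(sprintf("%s x %d", names(table(x$schedule$condition)),
                            table(x$schedule$condition)), collapse = ", "),
              length(x$couplings), nrow(x$artifactLog)))
  invisible(x)
}
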