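#' SessionBundle: one subject's raw recording, event schedule and channel table
#'
#' Container for a single experimental session: a channels-by-samples signal
#' matrix in microvolts, the event table (condition label, onset sample,
#' duration in samples; the resting baseline appears as one event labelled
#' \code{"baseline"}), and the channel table mapping each contact to an
#' anatomical region label or an exclusion class (\code{"white_matter"},
#' \code{"ventricle"}, \code{"unknown"}).
#'
#' @slot subjectId character scalar.
#' @slot samplingRate sampling rate in Hz.
#' @slot signals numeric matrix, channels x samples, microvolts. Row names are
#'   the channel ids.
#' @slot channels data.frame with columns \code{channel_id}, \code{region},
#'   \code{exclude_class} (empty string for analyzable contacts).
#' @slot events data.frame with columns \code{condition}, \code{onset_sample}
#'   (1-based), \code{duration_samples}.
#' @export
setClass("SessionBundle",
  representation(subjectId = "character", samplingRate = "numeric",
                 signals = "matrix", channels = "data.frame",
                 events = "data.frame"))

setValidity("SessionBundle", function(object) {
  msg <- character()
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a positive scalar")
  if (nrow(object@channels) != nrow(object@signals))
    msg <- c(msg, "channel table must have one row per signal row")
  need <- c("channel_id", "region", "exclude_class")
  if (!all(need %in% names(object@channels)))
    msg <- c(msg, paste("channel table needs columns:",
                        paste(need, collapse = ", ")))
  needEv <- c("condition", "onset_sample", "duration_samples")
  if (!all(needEv %in% names(object@events))) {
    msg <- c(msg, paste("event table needs columns:",
                        paste(needEv, collapse = ", ")))
  } else if (nrow(object@events)) {
    ends <- object@events$onset_sample + object@events$duration_samples - 1
    if (any(object@events$onset_sample < 1) || any(ends > ncol(object@signals)))
      msg <- c(msg, "events extend beyond the recording extent")
    stim <- object@events$condition != "baseline"
    if (is.unsorted(object@events$onset_sample[stim], strictly = TRUE))
      msg <- c(msg, "stimulation event onsets must be strictly increasing")
  }
  if (length(msg)) msg else TRUE
})

#' EpochSet: fixed-length epochs grouped by condition
#'
#' Epoched, condition-labelled data. For each condition (including
#' \code{"baseline"}) an array of dimension channels x samples x epochs, plus
#' a per-(channel, epoch) keep mask set by amplitude-based trial rejection.
#'
#' @slot epochs named list, one array (channels x samples x epochs) per
#'   condition.
#' @slot keepMask named list, one logical matrix (channels x epochs) per
#'   condition.
#' @slot samplingRate effective sampling rate in Hz.
#' @slot channelIds character vector of channel ids (row order of the arrays).
#' @export
setClass("EpochSet",
  representation(epochs = "list", keepMask = "list",
                 samplingRate = "numeric", channelIds = "character"))

setValidity("EpochSet", function(object) {
  msg <- character()
  if (!identical(names(object@epochs), names(object@keepMask)))
    msg <- c(msg, "epochs and keepMask must cover the same conditions")
  nch <- length(object@channelIds)
  lens <- unique(vapply(object@epochs, function(a) dim(a)[2L], integer(1)))
  if (length(lens) > 1L)
    msg <- c(msg, "all epochs must have the same length")
  for (cond in names(object@epochs)) {
    d <- dim(object@epochs[[cond]])
    m <- object@keepMask[[cond]]
    if (d[1L] != nch)
      msg <- c(msg, sprintf("condition %s: channel dimension mismatch", cond))
    if (!all(dim(m) == d[c(1L, 3L)]))
      msg <- c(msg, sprintf("condition %s: mask dimensions mismatch", cond))
  }
  if (length(msg)) msg else TRUE
})

#' PairBandTable: per-epoch, per-electrode-pair, per-band coherence
#'
#' The substrate of all downstream statistics: magnitude-squared coherence of
#' every unordered electrode pair, for every valid epoch of every condition,
#' averaged within named frequency bands. Optionally also carries pooled
#' estimates in which Welch segments are accumulated across all valid epochs
#' of a condition before forming coherence (lower variance, no per-epoch
#' distribution).
#'
#' @slot values named list, one array (pairs x bands x epochs) per condition;
#'   invalid (channel-rejected) epochs are NA.
#' @slot pooled named list (possibly empty), one matrix (pairs x bands) per
#'   condition.
#' @slot pairs data.frame with columns \code{chan_a}, \code{chan_b}.
#' @slot bands named list of c(low, high) frequency intervals, Hz, half-open.
#' @slot channelIds character vector of contributing channel ids.
#' @export
setClass("PairBandTable",
  representation(values = "list", pooled = "list", pairs = "data.frame",
                 bands = "list", channelIds = "character"))

setValidity("PairBandTable", function(object) {
  msg <- character()
  nb <- length(object@bands)
  np <- nrow(object@pairs)
  for (cond in names(object@values)) {
    d <- dim(object@values[[cond]])
    if (d[1L] != np || d[2L] != nb)
      msg <- c(msg, sprintf("condition %s: value array dimensions mismatch", cond))
    v <- object@values[[cond]]
    if (any(v < -1e-9 | v > 1 + 1e-9, na.rm = TRUE))
      msg <- c(msg, sprintf("condition %s: coherence outside [0, 1]", cond))
  }
  if (length(msg)) msg else TRUE
})

#' RegionPairDelta: baseline-subtracted coherence change by region pair
#'
#' Subject-level or group-level table of mean coherence change from baseline,
#' aggregated from electrode pairs to anatomical region pairs. Within-region
#' entries (distinct contacts, same region) populate the diagonal.
#'
#' @slot table data.frame with columns \code{region_a}, \code{region_b}
#'   (canonically ordered), \code{condition}, \code{band}, \code{delta},
#'   \code{n_pairs} and, at group level, \code{n_subjects}.
#' @slot level \code{"subject"} or \code{"group"}.
#' @export
setClass("RegionPairDelta",
  representation(table = "data.frame", level = "character"))

setValidity("RegionPairDelta", function(object) {
  msg <- character()
  need <- c("region_a", "region_b", "condition", "band", "delta", "n_pairs")
  if (!all(need %in% names(object@table)))
    msg <- c(msg, paste("table needs columns:", paste(need, collapse = ", ")))
  if (!object@level %in% c("subject", "group"))
    msg <- c(msg, "level must be 'subject' or 'group'")
  if ("delta" %in% names(object@table) &&
      any(abs(object@table$delta) > 1 + 1e-9, na.rm = TRUE))
    msg <- c(msg, "delta outside [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn SessionBundle compact display
#' @param object a SessionBundle
#' @export
setMethod("show", "SessionBundle", function(object) {
  cat(sprintf("SessionBundle '%s': %d channels x %d samples @ %g Hz (%.1f s)\n",
              object@subjectId, nrow(object@signals), ncol(object@signals),
              object@samplingRate, ncol(object@signals) / object@samplingRate))
  cond <- table(object@events$condition)
  cat("  events:", paste(sprintf("%s=%d", names(cond), cond), collapse = ", "),
      "\n")
  excl <- sum(object@channels$exclude_class != "")
  cat(sprintf("  channels: %d regions, %d excluded by label\n",
              length(unique(object@channels$region[object@channels$exclude_class == ""])),
              excl))
})

#' @describeIn EpochSet compact display
#' @param object an EpochSet
#' @export
setMethod("show", "EpochSet", function(object) {
  cat(sprintf("EpochSet: %d channels @ %g Hz\n", length(object@channelIds),
              object@samplingRate))
  for (cond in names(object@epochs)) {
    d <- dim(object@epochs[[cond]])
    kept <- sum(object@keepMask[[cond]])
    cat(sprintf("  %-10s %3d epochs x %d samples (%d of %d channel-epochs kept)\n",
                cond, d[3L], d[2L], kept, d[1L] * d[3L]))
  }
})

#' @describeIn PairBandTable compact display
#' @param object a PairBandTable
#' @export
setMethod("show", "PairBandTable", function(object) {
  cat(sprintf("PairBandTable: %d electrode pairs x %d bands (%s)\n",
              nrow(object@pairs), length(object@bands),
              paste(names(object@bands), collapse = ", ")))
  for (cond in names(object@values))
    cat(sprintf("  %-10s %d epochs%s\n", cond, dim(object@values[[cond]])[3L],
                if (cond %in% names(object@pooled)) " (+pooled)" else ""))
})

#' @describeIn RegionPairDelta compact display
#' @param object a RegionPairDelta
#' @export
setMethod("show", "RegionPairDelta", function(object) {
  tb <- object@table
  cat(sprintf("RegionPairDelta (%s level): %d region pairs, %d conditions, %d bands\n",
              object@level,
              nrow(unique(tb[, c("region_a", "region_b")])),
              length(unique(tb$condition)), length(unique(tb$band))))
})
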