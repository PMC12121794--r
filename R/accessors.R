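#' @rdname stimCoherence-accessors
#' @export
setMethod("subjectId", "SessionBundle", function(x) x@subjectId)

#' @rdname stimCoherence-accessors
#' @export
setMethod("samplingRate", "SessionBundle", function(x) x@samplingRate)

#' @rdname stimCoherence-accessors
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@samplingRate)

#' @rdname stimCoherence-accessors
#' @export
setMethod("signalMatrix", "SessionBundle", function(x) x@signals)

#' @rdname stimCoherence-accessors
#' @export
setMethod("channelTable", "SessionBundle", function(x) x@channels)

#' @rdname stimCoherence-accessors
#' @export
setMethod("eventTable", "SessionBundle", function(x) x@events)

#' @rdname stimCoherence-accessors
#' @export
setMethod("conditionNames", "EpochSet", function(x) names(x@epochs))

#' @rdname stimCoherence-accessors
#' @export
setMethod("conditionNames", "PairBandTable", function(x) names(x@values))

#' @rdname stimCoherence-accessors
#' @export
setMethod("channelIds", "SessionBundle", function(x) x@channels$channel_id)

#' @rdname stimCoherence-accessors
#' @export
setMethod("channelIds", "EpochSet", function(x) x@channelIds)

#' @rdname stimCoherence-accessors
#' @export
setMethod("channelIds", "PairBandTable", function(x) x@channelIds)

#' @rdname stimCoherence-accessors
#' @param condition condition label.
#' @export
setMethod("epochArray", "EpochSet", function(x, condition) {
  .assert(condition %in% names(x@epochs), "unknown condition: ", condition)
  x@epochs[[condition]]
})

#' @rdname stimCoherence-accessors
#' @export
setMethod("keepMask", "EpochSet", function(x, condition) {
  .assert(condition %in% names(x@keepMask), "unknown condition: ", condition)
  x@keepMask[[condition]]
})

#' @rdname stimCoherence-accessors
#' @export
setMethod("bandNames", "PairBandTable", function(x) names(x@bands))

#' @rdname stimCoherence-accessors
#' @export
setMethod("pairIndex", "PairBandTable", function(x) x@pairs)

#' @rdname stimCoherence-accessors
#' @param band band name.
#' @param pooled return the pooled (cross-epoch) estimate instead of the
#'   per-epoch matrix.
#' @export
setMethod("pairValues", "PairBandTable",
  function(x, condition, band, pooled = FALSE) {
    .assert(condition %in% names(x@values), "unknown condition: ", condition)
    .assert(band %in% names(x@bands), "unknown band: ", band)
    bi <- match(band, names(x@bands))
    if (pooled) {
      .assert(condition %in% names(x@pooled),
              "no pooled estimates stored; rerun pairConditionTable(pooled = TRUE)")
      x@pooled[[condition]][, bi]
    } else {
      x@values[[condition]][, bi, , drop = TRUE]
    }
  })

#' @rdname stimCoherence-accessors
#' @export
setMethod("deltaTable", "RegionPairDelta", function(x) x@table)

#' @rdname stimCoherence-accessors
#' @export
setMethod("deltaMatrix", "RegionPairDelta", function(x, condition, band) {
  tb <- x@table[x@table$condition == condition & x@table$band == band, ]
  .assert(nrow(tb) > 0, "no entries for condition ", condition, ", band ", band)
  regions <- sort(unique(c(tb$region_a, tb$region_b)))
  m <- matrix(NA_real_, length(regions), length(regions),
              dimnames = list(regions, regions))
  ia <- match(tb$region_a, regions); ib <- match(tb$region_b, regions)
  m[cbind(ia, ib)] <- tb$delta
  m[cbind(ib, ia)] <- tb$delta
  m
})
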