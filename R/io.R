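#' Analysis configuration with study defaults
#'
#' All tunable parameters of the pipeline, defaulting to the study's printed
#' values: 0.5 Hz 4th-order highpass, 60 Hz line-noise handling (channel
#' rejection at 3 mean absolute deviations above the median, notch Q = 30),
#' 5-s epochs, 500 microvolt spike rejection, 500 Hz target rate, 2.5 s /
#' 70% Welch windows, the four canonical bands, responder threshold d > 0.2,
#' seed-map threshold 0.01, left-hemisphere ROIs, 10000 permutations.
#'
#' @param ... overrides for any default (validated).
#' @return validated list of class \code{RunConfig}.
#' @export
runConfig <- function(...) {
  cfg <- list(
    highpassCutoff = 0.5, highpassOrder = 4,
    lineNoiseFreq = 60, lineNoiseBand = c(59, 61), lineNoiseMad = 3,
    madDispersion = "mean", notchQ = 30,
    epochDuration = 5, spikeThreshold = 500, spikeRejectOn = "preprocessed",
    targetRate = 500,
    window = 2.5, overlap = 0.70, taper = "hamming",
    bands = defaultBands(), pooled = FALSE,
    responderThreshold = 0.2, seedThreshold = 0.01,
    seedRegions = c("L-OFC", "L-ACC", "L-Amygdala", "L-Hippocampus", "L-PHG"),
    hubSd = 2, sdType = "sample", includeWithinRegion = FALSE,
    nPerm = 10000, permMode = "strict", seed = 1L)
  over <- list(...)
  .assert(all(names(over) %in% names(cfg)),
          "unknown config field(s): ",
          paste(setdiff(names(over), names(cfg)), collapse = ", "))
  cfg <- utils::modifyList(cfg, over)
  .assert(cfg$highpassCutoff > 0 && cfg$overlap >= 0 && cfg$overlap < 1 &&
            cfg$window > 0 && cfg$epochDuration > 0 &&
            cfg$spikeThreshold > 0 && cfg$nPerm >= 1 &&
            cfg$responderThreshold >= 0 && cfg$seedThreshold >= 0,
          "config parameter out of range")
  .assert(cfg$permMode %in% c("strict", "add-one"), "bad permMode")
  .assert(cfg$sdType %in% c("sample", "population"), "bad sdType")
  class(cfg) <- "RunConfig"
  cfg
}

#' The default 28-region anatomical grouping
#'
#' Fourteen bilateral structures grouped from the parcellation labels, left
#' and right: ACC, amygdala, basal ganglia, central cortex, hippocampus,
#' inferior frontal gyrus, insula, occipital lobe, OFC, posterior cingulate
#' cortex, prefrontal cortex, parahippocampal gyrus, temporal lobe,
#' thalamus. User-supplied mappings can replace it via
#' \code{\link{readRegionMapping}}.
#'
#' @return character vector of 28 region labels.
#' @export
defaultRegionScheme <- function() {
  base <- c("ACC", "Amygdala", "BasalGanglia", "CentralCortex", "Hippocampus",
            "IFG", "Insula", "Occipital", "OFC", "PCC", "PFC", "PHG",
            "Temporal", "Thalamus")
  as.vector(t(outer(c("L", "R"), base, paste, sep = "-")))
}

#' Read a parcellation-to-region mapping table
#'
#' Two-column tab-separated file: \code{label} (parcellation label) and
#' \code{region} (region label of the grouping scheme, or an exclusion class
#' \code{white_matter} / \code{ventricle} / \code{unknown}).
#'
#' @param path TSV file path.
#' @return named character vector mapping labels to regions.
#' @export
readRegionMapping <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  .assert(all(c("label", "region") %in% names(tb)),
          "mapping table needs columns 'label' and 'region'")
  stats::setNames(tb$region, tb$label)
}

#' Write a session bundle to a directory
#'
#' Signals as channel-major little-endian 32-bit float binary
#' (\code{signals.f32}), metadata as YAML (\code{meta.yaml}), events and
#' channel table as TSV.
#'
#' @param bundle a \linkS4class{SessionBundle}.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
writeSession <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(dir, "signals.f32"), "wb")
  on.exit(close(con))
  writeBin(as.vector(t(bundle@signals)), con, size = 4L, endian = "little")
  yaml::write_yaml(list(subject_id = bundle@subjectId,
                        sampling_rate = bundle@samplingRate,
                        n_channels = nrow(bundle@signals),
                        n_samples = ncol(bundle@signals),
                        channel_ids = as.list(bundle@channels$channel_id)),
                   file.path(dir, "meta.yaml"))
  utils::write.table(bundle@events, file.path(dir, "events.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(bundle@channels, file.path(dir, "channels.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a session bundle from a directory
#'
#' Counterpart of \code{\link{writeSession}}; validates that the three parts
#' agree on channel identity and that events fit the recording.
#'
#' @param dir session directory.
#' @return a \linkS4class{SessionBundle}.
#' @export
readSession <- function(dir) {
  metaPath <- file.path(dir, "meta.yaml")
  .assert(file.exists(metaPath), "missing file: ", metaPath)
  meta <- yaml::read_yaml(metaPath)
  for (f in c("subject_id", "sampling_rate", "n_channels", "n_samples",
              "channel_ids"))
    .assert(!is.null(meta[[f]]), "meta.yaml: missing field '", f, "'")
  sigPath <- file.path(dir, "signals.f32")
  .assert(file.exists(sigPath), "missing file: ", sigPath)
  n <- meta$n_channels * meta$n_samples
  raw <- readBin(sigPath, numeric(), n = n + 1L, size = 4L, endian = "little")
  .assert(length(raw) == n,
          "signals.f32: expected ", n, " float32 values, found ", length(raw))
  signals <- matrix(raw, nrow = meta$n_channels, byrow = TRUE)
  channels <- utils::read.delim(file.path(dir, "channels.tsv"),
                                stringsAsFactors = FALSE,
                                colClasses = "character")
  channels$exclude_class[is.na(channels$exclude_class)] <- ""
  events <- utils::read.delim(file.path(dir, "events.tsv"),
                              stringsAsFactors = FALSE)
  .assert(identical(channels$channel_id, unlist(meta$channel_ids)),
          "channels.tsv: channel ids disagree with meta.yaml")
  rownames(signals) <- channels$channel_id
  methods::new("SessionBundle", subjectId = meta$subject_id,
               samplingRate = meta$sampling_rate, signals = signals,
               channels = channels, events = events)
}

#' Write ground truth as TSV + YAML
#'
#' @param truth a \code{GroundTruth} from \code{\link{buildSession}}.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
writeGroundTruth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(truth$schedule, file.path(dir, "schedule.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(truth$artifactLog, file.path(dir, "artifacts.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (nrow(truth$expectedMsc))
    utils::write.table(truth$expectedMsc, file.path(dir, "expected_msc.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  yaml::write_yaml(lapply(truth$couplings, unclass),
                   file.path(dir, "couplings.yaml"))
  invisible(dir)
}

.writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Run the full analysis pipeline
#'
#' Per subject: preprocessing, per-epoch pair coherence, baseline
#' subtraction, region aggregation and responder classification. At group
#' level: group aggregation, per-band Friedman test across conditions over
#' region pairs (with Bonferroni pairwise signed-rank post-hocs when
#' significant), one-sample signed-rank tests of the global delta
#' distribution against zero (Bonferroni over conditions), responder
#' matrices with best-frequency ranking, SNR profile and permutation test,
#' hub pairs per condition and band, and thresholded seed maps with
#' condition comparisons. All tables are written as TSV under \code{outDir}
#' together with a run manifest.
#'
#' @param sessions list of \linkS4class{SessionBundle} objects or session
#'   directory paths.
#' @param config a \code{\link{runConfig}}.
#' @param outDir output directory, or NULL to skip writing.
#' @return (invisibly) a list with all per-subject and group results.
#' @export
runPipeline <- function(sessions, config = runConfig(), outDir = NULL) {
  .assert(length(sessions) >= 1, "need at least one session")
  stage <- "setup"
  result <- tryCatch({
    subjects <- list()
    for (i in seq_along(sessions)) {
      s <- sessions[[i]]
      stage <- sprintf("session %d: read", i)
      bundle <- if (is.character(s)) readSession(s) else s
      sid <- if (nzchar(bundle@subjectId) && bundle@subjectId != "synthetic")
        bundle@subjectId else sprintf("S%02d", i)
      stage <- sprintf("session %d: preprocess", i)
      prep <- preprocessSession(bundle, config)
      stage <- sprintf("session %d: coherence", i)
      table <- pairConditionTable(prep$epochs, scheme = config$bands,
                                  window = config$window,
                                  overlap = config$overlap,
                                  taper = config$taper,
                                  pooled = config$pooled)
      stage <- sprintf("session %d: deltas", i)
      deltas <- baselineSubtract(table,
                                 use = if (config$pooled) "pooled" else "perEpoch")
      regional <- regionize(deltas, prep$channels)
      stage <- sprintf("session %d: responders", i)
      responders <- responderMap(table, config$responderThreshold)
      subjects[[sid]] <- list(bundle = sid, preprocessing = prep$report,
                              deltas = deltas, regional = regional,
                              responders = responders)
    }

    stage <- "group aggregation"
    group <- groupAggregate(lapply(subjects, `[[`, "regional"))
    gtb <- deltaTable(group)
    conds <- unique(gtb$condition)
    bands <- unique(gtb$band)

    stage <- "group statistics"
    globalStats <- list()
    for (b in bands) {
      tb <- gtb[gtb$band == b, , drop = FALSE]
      if (!config$includeWithinRegion)
        tb <- tb[tb$region_a != tb$region_b, , drop = FALSE]
      key <- paste(tb$region_a, tb$region_b)
      wide <- tapply(tb$delta, list(key, tb$condition), mean)
      wide <- wide[stats::complete.cases(wide), , drop = FALSE]
      fr <- if (nrow(wide) >= 2) friedmanTest(wide) else NULL
      onesample <- do.call(rbind, lapply(conds, function(cd) {
        v <- tb$delta[tb$condition == cd]
        wt <- suppressWarnings(wilcoxonSignedRank(v, mu = 0))
        data.frame(band = b, condition = cd, statistic = wt$statistic,
                   z = wt$z, effect_r = wt$effect, p_raw = wt$p.value,
                   p_adjusted = bonferroniAdjust(wt$p.value, length(conds)),
                   family_size = length(conds), n = wt$n,
                   stringsAsFactors = FALSE)
      }))
      posthoc <- NULL
      if (!is.null(fr) && !fr$degenerate && fr$p.value < 0.05 &&
          length(conds) >= 2) {
        cmb <- utils::combn(conds, 2)
        m <- ncol(cmb)
        posthoc <- do.call(rbind, lapply(seq_len(m), function(j) {
          wt <- suppressWarnings(
            wilcoxonSignedRank(wide[, cmb[1, j]], wide[, cmb[2, j]]))
          data.frame(band = b, cond_a = cmb[1, j], cond_b = cmb[2, j],
                     statistic = wt$statistic, z = wt$z, effect_r = wt$effect,
                     p_raw = wt$p.value,
                     p_adjusted = bonferroniAdjust(wt$p.value, m),
                     family_size = m, stringsAsFactors = FALSE)
        }))
      }
      globalStats[[b]] <- list(friedman = fr, oneSample = onesample,
                               posthoc = posthoc)
    }

    stage <- "responder statistics"
    responderStats <- list()
    summaries <- lapply(subjects, `[[`, "responders")
    for (b in bands) {
      pm <- responderMatrix(summaries, b, conditions = conds)
      rk <- if (nrow(pm) >= 1) bestFrequencyRanking(pm) else NULL
      sn <- if (nrow(pm) >= 2) suppressWarnings(snrProfile(pm, config$sdType))
        else NULL
      pp <- if (nrow(pm) >= 2)
        suppressWarnings(permutationSnrTest(pm, config$nPerm,
                                            seed = config$seed,
                                            mode = config$permMode,
                                            sdType = config$sdType)) else NULL
      responderStats[[b]] <- list(percentages = pm, ranking = rk, snr = sn,
                                  permutation = pp)
    }

    stage <- "hubs"
    hubs <- list()
    for (cd in conds) for (b in bands)
      hubs[[paste(cd, b, sep = ".")]] <-
        suppressWarnings(hubPairs(group, cd, b, nSd = config$hubSd,
                                  sdType = config$sdType,
                                  includeWithinRegion = config$includeWithinRegion))

    stage <- "seed maps"
    seedMaps <- list(); seedStats <- list()
    covered <- unique(c(gtb$region_a, gtb$region_b))
    for (sr in intersect(config$seedRegions, covered)) {
      sm <- seedMap(group, sr, config$seedThreshold)
      seedMaps[[sr]] <- sm
      seedStats[[sr]] <- suppressWarnings(seedConditionComparison(sm))
    }

    list(subjects = subjects, group = group, globalStats = globalStats,
         responderStats = responderStats, hubs = hubs, seedMaps = seedMaps,
         seedStats = seedStats, config = config)
  }, error = function(e) {
    stop("pipeline failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(outDir)) .writeResults(result, outDir)
  invisible(result)
}

.writeResults <- function(result, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  for (sid in names(result$subjects)) {
    sdir <- file.path(outDir, sid)
    dir.create(sdir, showWarnings = FALSE)
    sub <- result$subjects[[sid]]
    .writeTsv(sub$deltas, file.path(sdir, "pair_deltas.tsv"))
    .writeTsv(deltaTable(sub$regional), file.path(sdir, "region_deltas.tsv"))
    .writeTsv(sub$responders$summary, file.path(sdir, "responders.tsv"))
    .writeTsv(sub$preprocessing$rejection, file.path(sdir, "rejection.tsv"))
  }
  gtb <- deltaTable(result$group)
  .writeTsv(gtb, file.path(outDir, "group_region_deltas.tsv"))
  for (cd in unique(gtb$condition)) for (b in unique(gtb$band)) {
    m <- deltaMatrix(result$group, cd, b)
    utils::write.table(round(m, 8), file.path(outDir,
      sprintf("group_matrix_%s_%s.tsv", cd, b)), sep = "\t", quote = FALSE,
      col.names = NA)
  }
  oneS <- do.call(rbind, lapply(result$globalStats, `[[`, "oneSample"))
  .writeTsv(oneS, file.path(outDir, "global_one_sample.tsv"))
  ph <- do.call(rbind, Filter(Negate(is.null),
                              lapply(result$globalStats, `[[`, "posthoc")))
  if (!is.null(ph)) .writeTsv(ph, file.path(outDir, "global_posthoc.tsv"))
  hubRows <- do.call(rbind, lapply(names(result$hubs), function(nm) {
    h <- result$hubs[[nm]]
    if (!nrow(h$pairs)) return(NULL)
    cbind(h$pairs, threshold = h$threshold)
  }))
  if (!is.null(hubRows)) .writeTsv(hubRows, file.path(outDir, "hub_pairs.tsv"))
  sm <- do.call(rbind, result$seedMaps)
  if (!is.null(sm) && nrow(sm)) .writeTsv(sm, file.path(outDir, "seed_maps.tsv"))
  cfg <- result$config
  manifest <- list(package = "stimCoherence",
                   version = as.character(utils::packageVersion("stimCoherence")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   seed = cfg$seed,
                   config = lapply(unclass(cfg), function(v)
                     if (is.list(v)) lapply(v, as.vector) else as.vector(v)))
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  writeLines(writeReport(result), file.path(outDir, "report.txt"))
  invisible(outDir)
}

#' Human-readable summary report
#'
#' Tabulates group deltas per band and condition, significant conditions
#' after Bonferroni correction (with the family size used), responder
#' percentages, the SNR ranking with permutation p per condition, hub lists
#' and seed maps.
#'
#' @param result the list returned by \code{\link{runPipeline}}.
#' @return character vector of report lines.
#' @export
writeReport <- function(result) {
  ln <- c("Stimulation-evoked coherence analysis", strrep("=", 38), "")
  gtb <- deltaTable(result$group)
  ln <- c(ln, "Group mean coherence change from baseline (region-pair mean):")
  for (b in unique(gtb$band)) {
    for (cd in unique(gtb$condition)) {
      v <- gtb$delta[gtb$band == b & gtb$condition == cd]
      ln <- c(ln, sprintf("  %-6s %-6s mean %+.4f over %d region pairs",
                          b, cd, mean(v), length(v)))
    }
  }
  ln <- c(ln, "", "One-sample signed-rank tests vs 0 (Bonferroni-corrected):")
  for (b in names(result$globalStats)) {
    os <- result$globalStats[[b]]$oneSample
    for (i in seq_len(nrow(os)))
      ln <- c(ln, sprintf("  %-6s %-6s p_adj = %.4g (m = %d)%s",
                          os$band[i], os$condition[i], os$p_adjusted[i],
                          os$family_size[i],
                          if (os$p_adjusted[i] < 0.05) " *" else ""))
  }
  ln <- c(ln, "", "Responder percentages and SNR:")
  for (b in names(result$responderStats)) {
    rs <- result$responderStats[[b]]
    if (is.null(rs$snr)) next
    for (i in seq_len(nrow(rs$snr))) {
      cd <- rs$snr$condition[i]
      pp <- if (is.null(rs$permutation)) NA else rs$permutation[[cd]]
      ln <- c(ln, sprintf("  %-6s %-6s SNR %.3f (rank %d), permutation p = %s",
                          b, cd, rs$snr$snr[i], rs$snr$rank[i],
                          ifelse(is.na(pp), "NA", format(pp, digits = 4))))
    }
    if (!is.null(rs$ranking))
      ln <- c(ln, sprintf("  %-6s best-frequency counts: %s (exact multinomial p = %.4g)",
                          b, paste(sprintf("%s=%d", names(rs$ranking$counts),
                                           rs$ranking$counts), collapse = " "),
                          rs$ranking$p.value))
  }
  ln <- c(ln, "", "Hub pairs (>= 2 SD above the global mean):")
  any <- FALSE
  for (nm in names(result$hubs)) {
    h <- result$hubs[[nm]]
    if (!nrow(h$pairs)) next
    any <- TRUE
    for (i in seq_len(nrow(h$pairs)))
      ln <- c(ln, sprintf("  %-14s %s -- %s (delta %+.4f)", nm,
                          h$pairs$region_a[i], h$pairs$region_b[i],
                          h$pairs$delta[i]))
    if (length(h$hubRegions))
      ln <- c(ln, sprintf("  %-14s hub regions: %s", nm,
                          paste(h$hubRegions, collapse = ", ")))
  }
  if (!any) ln <- c(ln, "  none")
  ln <- c(ln, "", sprintf("Seed maps (|delta| > threshold):"))
  if (length(result$seedMaps) == 0) ln <- c(ln, "  none")
  for (sr in names(result$seedMaps)) {
    sm <- result$seedMaps[[sr]]
    if (!nrow(sm)) { ln <- c(ln, sprintf("  seed %s: none", sr)); next }
    for (i in seq_len(nrow(sm)))
      ln <- c(ln, sprintf("  seed %-14s %-6s %-6s -> %-14s %+.4f", sr,
                          sm$condition[i], sm$band[i], sm$target[i],
                          sm$delta[i]))
  }
  ln
}
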