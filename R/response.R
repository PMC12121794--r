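#' Responder classification for one subject
#'
#' For every electrode pair, stimulation condition and band, Cohen's d of the
#' per-epoch coherence values (stimulation vs baseline) is computed; a pair
#' is a responder iff d > threshold (strict). Pairs lacking at least 2 valid
#' epochs on either side are excluded from numerator and denominator and
#' listed in the \code{excluded} element. Percentages are
#' 100 * responders / total evaluable pairs.
#'
#' @param table a \linkS4class{PairBandTable} with per-epoch values and a
#'   baseline condition.
#' @param threshold responder effect-size threshold (default 0.2).
#' @return list of class \code{ResponderSummary}: \code{pairs} (per-pair d
#'   and responder flag), \code{summary} (per condition x band counts and
#'   percentage), \code{excluded}, \code{threshold}.
#' @export
responderMap <- function(table, threshold = 0.2) {
  .assert("baseline" %in% names(table@values),
          "table has no 'baseline' condition")
  conds <- setdiff(names(table@values), "baseline")
  bands <- names(table@bands)
  baseArr <- table@values[["baseline"]]
  np <- nrow(table@pairs)
  pairRows <- list(); summRows <- list(); exclRows <- list()
  for (cond in conds) {
    arr <- table@values[[cond]]
    for (b in seq_along(bands)) {
      sv <- matrix(arr[, b, ], nrow = np)
      bv <- matrix(baseArr[, b, ], nrow = np)
      nS <- rowSums(!is.na(sv)); nB <- rowSums(!is.na(bv))
      evaluable <- nS >= 2 & nB >= 2
      mS <- rowMeans(sv, na.rm = TRUE); mB <- rowMeans(bv, na.rm = TRUE)
      vS <- apply(sv, 1L, stats::var, na.rm = TRUE)
      vB <- apply(bv, 1L, stats::var, na.rm = TRUE)
      sp <- sqrt(((nS - 1) * vS + (nB - 1) * vB) / (nS + nB - 2))
      d <- ifelse(sp > 0, (mS - mB) / sp, 0)
      d[!evaluable] <- NA_real_
      resp <- evaluable & !is.na(d) & d > threshold
      pairRows[[length(pairRows) + 1L]] <- data.frame(
        chan_a = table@pairs$chan_a, chan_b = table@pairs$chan_b,
        condition = cond, band = bands[b], d = d,
        responder = resp, evaluable = evaluable, stringsAsFactors = FALSE)
      summRows[[length(summRows) + 1L]] <- data.frame(
        condition = cond, band = bands[b],
        n_responders = sum(resp), n_pairs = sum(evaluable),
        percentage = 100 * sum(resp) / max(1L, sum(evaluable)),
        stringsAsFactors = FALSE)
      if (any(!evaluable))
        exclRows[[length(exclRows) + 1L]] <- data.frame(
          chan_a = table@pairs$chan_a[!evaluable],
          chan_b = table@pairs$chan_b[!evaluable],
          condition = cond, band = bands[b], stringsAsFactors = FALSE)
    }
  }
  structure(list(pairs = do.call(rbind, pairRows),
                 summary = do.call(rbind, summRows),
                 excluded = if (length(exclRows)) do.call(rbind, exclRows) else
                   data.frame(),
                 threshold = threshold),
            class = "ResponderSummary")
}

#' @export
print.ResponderSummary <- function(x, ...) {
  cat(sprintf("ResponderSummary (d > %g):\n", x$threshold))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Assemble a subjects x conditions responder-percentage matrix
#'
#' @param summaries list of per-subject \code{ResponderSummary} objects.
#' @param band band name.
#' @param conditions condition order for the columns (default: order of the
#'   first subject's summary).
#' @return numeric matrix, subjects x conditions.
#' @export
responderMatrix <- function(summaries, band,
                            conditions = NULL) {
  .assert(length(summaries) >= 1, "need at least one subject")
  if (is.null(conditions))
    conditions <- unique(summaries[[1L]]$summary$condition)
  m <- t(vapply(summaries, function(s) {
    tb <- s$summary[s$summary$band == band, ]
    .assert(all(conditions %in% tb$condition),
            "summary lacks a condition for band ", band)
    tb$percentage[match(conditions, tb$condition)]
  }, numeric(length(conditions))))
  colnames(m) <- conditions
  rownames(m) <- names(summaries)
  m
}

#' Best-frequency ranking across subjects
#'
#' Per subject, the condition with the highest responder percentage; counts
#' per condition across subjects; exact multinomial p against uniform
#' category probabilities. A tie at the maximum is assigned to the first
#' (lowest-frequency) tied condition with a warning.
#'
#' @param pctMatrix subjects x conditions responder-percentage matrix (see
#'   \code{\link{responderMatrix}}).
#' @return list: \code{best} (per-subject winning condition), \code{counts},
#'   \code{p.value}, \code{ties} (logical, any tie encountered).
#' @export
bestFrequencyRanking <- function(pctMatrix) {
  .assert(is.matrix(pctMatrix) && !anyNA(pctMatrix),
          "percentage matrix must be complete")
  k <- ncol(pctMatrix)
  ties <- FALSE
  best <- apply(pctMatrix, 1L, function(row) {
    w <- which(row == max(row))
    if (length(w) > 1L) ties <<- TRUE
    w[1L]
  })
  if (ties) warning("tie at the maximum; assigned to the lowest frequency")
  counts <- tabulate(best, nbins = k)
  names(counts) <- colnames(pctMatrix)
  list(best = colnames(pctMatrix)[best], counts = counts,
       p.value = as.numeric(exactMultinomial(counts)), ties = ties)
}

.colSnr <- function(m, sdType = "sample") {
  mu <- colMeans(m)
  sg <- apply(m, 2L, .sampleSd, sdType)
  mu / sg
}

#' Signal-to-noise profile of responder percentages
#'
#' SNR = mean / SD of the subjects' responder percentages, per condition;
#' conditions are ranked by descending SNR. A zero SD yields an infinite,
#' flagged SNR.
#'
#' @param pctMatrix subjects x conditions responder-percentage matrix.
#' @param sdType \code{"sample"} (n - 1, default) or \code{"population"}.
#' @return data.frame: condition, mu, sigma, snr, rank (1 = highest SNR),
#'   degenerate flag.
#' @export
snrProfile <- function(pctMatrix, sdType = "sample") {
  .assert(nrow(pctMatrix) >= 2, "need >= 2 subjects")
  mu <- colMeans(pctMatrix)
  sg <- apply(pctMatrix, 2L, .sampleSd, sdType)
  snr <- ifelse(sg > 0, mu / sg, Inf)
  if (any(sg == 0)) warning("zero SD in some condition(s); SNR undefined")
  out <- data.frame(condition = colnames(pctMatrix), mu = mu, sigma = sg,
                    snr = snr, degenerate = sg == 0,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$rank <- rank(-out$snr, ties.method = "min")
  out[order(out$rank), ]
}

#' Permutation test for the SNR profile
#'
#' Each iteration independently permutes every subject's row of the
#' percentage matrix (shuffling the condition labels within subject) and
#' recomputes the per-condition SNR. Under the strict rule (the default),
#' p is the proportion of iterations whose permuted SNR is strictly greater
#' than the observed SNR; \code{mode = "add-one"} returns the
#' bias-corrected (b + 1) / (nPerm + 1), which cannot be exactly zero and is
#' the recommended estimator for downstream thresholding;
#' \code{mode = "gte"} counts ties as exceedances (a constant matrix then
#' yields p = 1 instead of the strict rule's degenerate 0).
#'
#' @param pctMatrix complete subjects x conditions matrix.
#' @param nPerm number of permutations (default 10000).
#' @param seed RNG seed for reproducibility.
#' @param mode \code{"strict"} (default), \code{"add-one"} or \code{"gte"}.
#' @param sdType SD convention, as in \code{\link{snrProfile}}.
#' @return named numeric vector of per-condition p-values, with the observed
#'   SNR in attribute \code{"observed"}.
#' @export
permutationSnrTest <- function(pctMatrix, nPerm = 10000, seed = NULL,
                               mode = c("strict", "add-one", "gte"),
                               sdType = "sample") {
  mode <- match.arg(mode)
  .assert(is.matrix(pctMatrix) && !anyNA(pctMatrix),
          "percentage matrix must be complete")
  .assert(nPerm >= 1, "nPerm must be >= 1")
  n <- nrow(pctMatrix); k <- ncol(pctMatrix)
  obs <- .colSnr(pctMatrix, sdType)
  if (all(pctMatrix == pctMatrix[1L]))
    warning("constant matrix: permuted SNR equals observed in every ",
            "iteration; strict-rule p is 0 by construction")
  .withSeed(seed, {
    exceed <- numeric(k)
    pm <- pctMatrix
    tol <- 1e-12
    for (i in seq_len(nPerm)) {
      for (s in seq_len(n)) pm[s, ] <- pctMatrix[s, sample.int(k)]
      ps <- .colSnr(pm, sdType)
      exceed <- exceed + if (mode == "gte") (ps >= obs - tol) else (ps > obs)
    }
    p <- switch(mode,
                strict = exceed / nPerm,
                gte = exceed / nPerm,
                `add-one` = (exceed + 1) / (nPerm + 1))
    names(p) <- colnames(pctMatrix)
    structure(p, observed = obs)
  })
}

#' Hub region pairs: coherence increases >= 2 SD above the brain-wide mean
#'
#' The global distribution is the set of region-pair deltas for the given
#' condition and band (off-diagonal pairs by default). Pairs with
#' delta >= mean + nSd * SD qualify; hub regions are those appearing in two
#' or more qualifying pairs.
#'
#' @param group a group-level \linkS4class{RegionPairDelta}.
#' @param condition condition label.
#' @param band band name.
#' @param nSd threshold in SDs above the mean (default 2).
#' @param sdType \code{"sample"} (n - 1, default) or \code{"population"}.
#' @param includeWithinRegion include the within-region diagonal in the
#'   global distribution (default FALSE).
#' @return list of class \code{HubResult}: \code{pairs} (qualifying rows),
#'   \code{hubRegions}, \code{threshold}, \code{mean}, \code{sd}.
#' @export
hubPairs <- function(group, condition, band, nSd = 2, sdType = "sample",
                     includeWithinRegion = FALSE) {
  tb <- deltaTable(group)
  tb <- tb[tb$condition == condition & tb$band == band, , drop = FALSE]
  .assert(nrow(tb) > 0, "no entries for condition ", condition, ", band ", band)
  if (!includeWithinRegion)
    tb <- tb[tb$region_a != tb$region_b, , drop = FALSE]
  mu <- mean(tb$delta)
  sg <- .sampleSd(tb$delta, sdType)
  if (is.na(sg) || sg == 0) {
    warning("degenerate global distribution (SD = 0); no hubs")
    return(structure(list(pairs = tb[0, ], hubRegions = character(),
                          threshold = NA_real_, mean = mu, sd = sg),
                     class = "HubResult"))
  }
  thr <- mu + nSd * sg
  qual <- tb[tb$delta >= thr, , drop = FALSE]
  regionCounts <- table(c(qual$region_a, qual$region_b))
  structure(list(pairs = qual,
                 hubRegions = names(regionCounts)[regionCounts >= 2],
                 threshold = thr, mean = mu, sd = sg),
            class = "HubResult")
}

#' @export
print.HubResult <- function(x, ...) {
  cat(sprintf("HubResult: %d pair(s) >= %.4g; hub regions: %s\n",
              nrow(x$pairs), x$threshold,
              if (length(x$hubRegions)) paste(x$hubRegions, collapse = ", ")
              else "none"))
  invisible(x)
}

#' Thresholded seed-region coherence map
#'
#' Coherence change from the seed region to every other covered region, per
#' condition and band, masked to absolute changes strictly greater than the
#' threshold (sign preserved).
#'
#' @param delta a \linkS4class{RegionPairDelta} (subject or group level).
#' @param seedRegion seed region label; must be covered.
#' @param threshold masking threshold on |delta| (default 0.01).
#' @return data.frame of class \code{SeedMap}: seed, condition, band,
#'   target, delta (only surviving entries).
#' @export
seedMap <- function(delta, seedRegion, threshold = 0.01) {
  tb <- deltaTable(delta)
  hit <- tb$region_a == seedRegion | tb$region_b == seedRegion
  .assert(any(hit), "seed region not covered: ", seedRegion)
  tb <- tb[hit & tb$region_a != tb$region_b, , drop = FALSE]
  target <- ifelse(tb$region_a == seedRegion, tb$region_b, tb$region_a)
  out <- data.frame(seed = seedRegion, condition = tb$condition,
                    band = tb$band, target = target, delta = tb$delta,
                    stringsAsFactors = FALSE)
  out <- out[abs(out$delta) > threshold, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  class(out) <- c("SeedMap", "data.frame")
  out
}

#' Compare thresholded seed maps across conditions
#'
#' Kruskal-Wallis omnibus test on the threshold-applied delta distributions
#' across conditions, per band; when the omnibus p is below alpha,
#' Bonferroni-corrected pairwise Wilcoxon rank-sum post-hoc tests are run
#' (family size = number of unordered condition pairs).
#'
#' @param map a \code{SeedMap} spanning several conditions.
#' @param alpha omnibus significance gate for the post-hocs (default 0.05).
#' @return named list per band: \code{omnibus} (a \code{StatResult}) and
#'   \code{posthoc} (data.frame or NULL when not run).
#' @export
seedConditionComparison <- function(map, alpha = 0.05) {
  .assert(inherits(map, "SeedMap"), "map must come from seedMap()")
  out <- list()
  for (b in unique(map$band)) {
    mb <- map[map$band == b, ]
    groups <- split(mb$delta, mb$condition)
    groups <- groups[vapply(groups, length, integer(1)) > 0]
    if (length(groups) < 2) {
      warning("band ", b, ": fewer than 2 conditions with surviving entries")
      out[[b]] <- list(omnibus = .statResult("Kruskal-Wallis test", 0, p = 1,
                                             n = length(unlist(groups)),
                                             degenerate = TRUE),
                       posthoc = NULL)
      next
    }
    om <- kruskalWallis(groups)
    ph <- NULL
    if (!om$degenerate && om$p.value < alpha) {
      cmb <- utils::combn(names(groups), 2)
      m <- ncol(cmb)
      ph <- do.call(rbind, lapply(seq_len(m), function(i) {
        a <- groups[[cmb[1, i]]]; bb <- groups[[cmb[2, i]]]
        wt <- suppressWarnings(stats::wilcox.test(a, bb, exact = FALSE))
        data.frame(band = b, cond_a = cmb[1, i], cond_b = cmb[2, i],
                   statistic = unname(wt$statistic), p_raw = wt$p.value,
                   p_adjusted = bonferroniAdjust(wt$p.value, m),
                   family_size = m, stringsAsFactors = FALSE)
      }))
    }
    out[[b]] <- list(omnibus = om, posthoc = ph)
  }
  out
}
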