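# Responder classification, SNR permutation machinery, hubs, seed maps.

# Pair table with prescribed per-epoch values for one band.
valueTable <- function(baseVals, condVals, conds = names(condVals)) {
  np <- nrow(baseVals)
  pairs <- data.frame(chan_a = sprintf("p%da", seq_len(np)),
                      chan_b = sprintf("p%db", seq_len(np)))
  mk <- function(m) array(m, dim = c(nrow(m), 1, ncol(m)))
  values <- c(list(baseline = mk(baseVals)),
              lapply(condVals, mk))
  methods::new("PairBandTable", values = values, pooled = list(),
               pairs = pairs, bands = list(theta = c(4, 8)),
               channelIds = unique(c(pairs$chan_a, pairs$chan_b)))
}

test_that("responder rule is strict at d = 0.2 and percentages are exact", {
  set.seed(1)
  clamp <- function(x) pmin(pmax(x, 0), 1)
  base <- clamp(matrix(rnorm(3 * 200, 0.3, 0.1), 3))
  mkCond <- function(d) clamp(matrix(rnorm(200, 0.3 + d * 0.1, 0.1), 1))
  # construct pairs with known population d; verify strictness on the
  # *computed* d by direct reuse of the same values
  cond <- rbind(mkCond(3), mkCond(0), mkCond(0.05))
  tab <- valueTable(base, list("20Hz" = cond))
  rm_ <- responderMap(tab, threshold = 0.2)
  d <- rm_$pairs$d
  expect_equal(rm_$pairs$responder, d > 0.2)
  expect_equal(rm_$summary$percentage,
               100 * sum(d > 0.2) / 3)
  # exact boundary: a pair whose computed d is exactly 0.2 is NOT a responder
  b2 <- matrix(rep(c(0.2, 0.4), 50), 1)
  c2 <- b2 + 0.2 * sd(b2)                            # d exactly 0.2
  tab2 <- valueTable(b2, list("20Hz" = c2))
  rm2 <- responderMap(tab2, 0.2)
  expect_equal(rm2$pairs$d, 0.2, tolerance = 1e-12)
  expect_false(rm2$pairs$responder)
})

test_that("pairs lacking valid epochs drop from numerator and denominator", {
  base <- matrix(0.3, 2, 10)
  cond <- matrix(0.5, 2, 10)
  cond[2, 2:10] <- NA                                # only 1 valid epoch
  tab <- valueTable(base, list("6Hz" = cond))
  tab@values[["6Hz"]][2, 1, 2:10] <- NA
  rm_ <- responderMap(tab)
  expect_equal(rm_$summary$n_pairs, 1L)
  expect_equal(nrow(rm_$excluded), 1L)
})

test_that("best-frequency ranking reproduces the printed worked examples", {
  conds <- c("2Hz", "6Hz", "12Hz", "20Hz", "40Hz")
  # seven subjects whose argmax counts are (0,2,1,3,1)
  pm <- matrix(10, 7, 5, dimnames = list(NULL, conds))
  winners <- c("6Hz", "6Hz", "12Hz", "20Hz", "20Hz", "20Hz", "40Hz")
  for (i in 1:7) pm[i, winners[i]] <- 50
  rk <- bestFrequencyRanking(pm)
  expect_equal(unname(rk$counts), c(0, 2, 1, 3, 1))
  expect_equal(round(rk$p.value, 3), 0.624)
  # counts (0,0,0,4,3)
  winners2 <- c(rep("20Hz", 4), rep("40Hz", 3))
  pm2 <- matrix(10, 7, 5, dimnames = list(NULL, conds))
  for (i in 1:7) pm2[i, winners2[i]] <- 50
  rk2 <- bestFrequencyRanking(pm2)
  expect_equal(unname(rk2$counts), c(0, 0, 0, 4, 3))
  expect_equal(round(rk2$p.value, 3), 0.016)
  # unanimous winner: p = 5 * (1/5)^7
  pm3 <- matrix(10, 7, 5, dimnames = list(NULL, conds))
  pm3[, "6Hz"] <- 50
  expect_equal(bestFrequencyRanking(pm3)$p.value, 5 * 0.2^7, tolerance = 1e-12)
})

test_that("argmax ties go to the lowest frequency with a warning", {
  pm <- matrix(c(50, 50, 10, 10, 10), 1, dimnames = list(NULL,
    c("2Hz", "6Hz", "12Hz", "20Hz", "40Hz")))
  pm <- pm[c(1, 1), , drop = FALSE]
  expect_warning(rk <- bestFrequencyRanking(pm), "tie")
  expect_equal(unname(rk$counts[1]), 2)
  expect_true(rk$ties)
})

test_that("SNR profile is mean over sample SD with descending ranks", {
  pm <- matrix(c(10, 20, 30,
                 5, 5, 5), ncol = 2,
               dimnames = list(NULL, c("a", "b")))
  expect_warning(sn <- snrProfile(pm), "zero SD")
  expect_equal(sn$snr[sn$condition == "a"], 20 / 10)
  expect_true(is.infinite(sn$snr[sn$condition == "b"]))
  expect_true(sn$degenerate[sn$condition == "b"])
  # direct mu/sigma oracle on random data
  set.seed(2)
  pm2 <- matrix(runif(21, 0, 50), 7, 3, dimnames = list(NULL, c("x", "y", "z")))
  sn2 <- snrProfile(pm2)
  for (cd in colnames(pm2))
    expect_equal(sn2$snr[sn2$condition == cd],
                 mean(pm2[, cd]) / sd(pm2[, cd]), tolerance = 1e-12)
  expect_equal(sn2$rank, rank(-sn2$snr))
})

test_that("permutation test is seed-reproducible and detects a shifted condition", {
  set.seed(3)
  pm <- matrix(rnorm(35, 20, 3), 7, 5,
               dimnames = list(NULL, c("2Hz", "6Hz", "12Hz", "20Hz", "40Hz")))
  p1 <- permutationSnrTest(pm, nPerm = 500, seed = 11)
  p2 <- permutationSnrTest(pm, nPerm = 500, seed = 11)
  expect_identical(p1, p2)
  p3 <- permutationSnrTest(pm, nPerm = 500, seed = 12)
  expect_false(identical(as.numeric(p1), as.numeric(p3)))
  # one condition consistent and far above the rest -> tiny p
  pm[, "20Hz"] <- rnorm(7, 60, 0.5)
  pS <- permutationSnrTest(pm, nPerm = 2000, seed = 4)
  expect_lt(pS[["20Hz"]], 0.01)
})

test_that("constant matrix triggers the strict-rule degenerate warning", {
  pm <- matrix(25, 4, 5, dimnames = list(NULL, paste0("c", 1:5)))
  expect_warning(p <- permutationSnrTest(pm, nPerm = 50, seed = 1), "strict")
  expect_true(all(p == 0))
  # tie-counting mode yields 1; add-one correction cannot reach exactly 0
  pGte <- suppressWarnings(permutationSnrTest(pm, nPerm = 50, seed = 1,
                                              mode = "gte"))
  expect_true(all(pGte == 1))
  pAdd <- suppressWarnings(permutationSnrTest(pm, nPerm = 50, seed = 1,
                                              mode = "add-one"))
  expect_true(all(pAdd == 1 / 51))
})

test_that("permutation p is uniform under the null (add-one estimator)", {
  set.seed(41)
  nrep <- 500
  ps <- numeric(nrep)
  for (i in seq_len(nrep)) {
    pm <- matrix(rnorm(35, 20, 5), 7, 5,
                 dimnames = list(NULL, paste0("c", 1:5)))
    ps[i] <- permutationSnrTest(pm, nPerm = 199, mode = "add-one")[[1]]
  }
  # p-values are discrete multiples of 1/200, so ties are expected
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("hub thresholding follows the sample-SD arithmetic example", {
  tb <- data.frame(region_a = c("A", "A", "A", "B", "B"),
                   region_b = c("B", "C", "D", "C", "D"),
                   condition = "20Hz", band = "theta",
                   delta = c(0, 0, 0, 0, 1))
  g <- makeDelta(tb)
  # sample SD: mean 0.2, sd ~0.447, threshold ~1.094 -> nothing qualifies
  hSample <- hubPairs(g, "20Hz", "theta")
  expect_equal(nrow(hSample$pairs), 0)
  expect_equal(hSample$threshold, 0.2 + 2 * sd(tb$delta))
  # population SD: threshold 1.0 -> the outlier qualifies (>= rule)
  hPop <- hubPairs(g, "20Hz", "theta", sdType = "population")
  expect_equal(nrow(hPop$pairs), 1)
  expect_equal(hPop$pairs$delta, 1)
})

test_that("hub regions need two or more qualifying pairs", {
  # 18 null pairs at 0 plus A-B and A-C at 1.0: population SD 0.3,
  # threshold mean + 2 SD = 0.7, so exactly the two A pairs qualify
  others <- t(combn(sprintf("N%02d", 1:8), 2))[1:18, ]
  tb <- data.frame(region_a = c("A", "A", others[, 1]),
                   region_b = c("B", "C", others[, 2]),
                   condition = "6Hz", band = "alpha",
                   delta = c(1, 1, rep(0, 18)))
  h <- hubPairs(makeDelta(tb), "6Hz", "alpha", sdType = "population")
  expect_equal(nrow(h$pairs), 2)
  expect_identical(h$hubRegions, "A")          # A in 2 pairs; B, C in 1
  # degenerate: all equal -> no hubs, warning
  tb$delta <- 0.3
  expect_warning(h0 <- hubPairs(makeDelta(tb), "6Hz", "alpha"), "degenerate")
  expect_equal(nrow(h0$pairs), 0)
})

test_that("seed maps mask strictly at |delta| > 0.01 preserving sign", {
  tb <- data.frame(region_a = c("A", "A", "A", "A", "A"),
                   region_b = c("B", "C", "D", "E", "A"),
                   condition = "20Hz", band = "theta",
                   delta = c(0.009, 0.011, -0.02, 0.01, 0.5))
  sm <- seedMap(makeDelta(tb), "A", 0.01)
  expect_setequal(sm$target, c("C", "D"))
  expect_equal(sm$delta[sm$target == "D"], -0.02)   # sign preserved
  expect_false("E" %in% sm$target)                  # exactly 0.01 masked
  expect_false("A" %in% sm$target)                  # diagonal excluded
  expect_error(seedMap(makeDelta(tb), "Z"), "not covered")
})

test_that("seed maps are symmetric in the seed choice", {
  tb <- data.frame(region_a = c("A", "A", "B"), region_b = c("B", "C", "C"),
                   condition = "6Hz", band = "alpha",
                   delta = c(0.3, 0.2, 0.1))
  a <- seedMap(makeDelta(tb), "A")
  b <- seedMap(makeDelta(tb), "B")
  expect_equal(a$delta[a$target == "B"], b$delta[b$target == "A"])
})

test_that("seed condition comparison gates post-hocs on the omnibus test", {
  set.seed(6)
  tb <- do.call(rbind, lapply(c("2Hz", "6Hz", "12Hz", "20Hz", "40Hz"),
    function(cd) data.frame(
      region_a = "A", region_b = sprintf("R%02d", 1:20), condition = cd,
      band = "theta",
      delta = rnorm(20, ifelse(cd == "20Hz", 0.3, 0.05), 0.02))))
  sm <- seedMap(makeDelta(tb), "A")
  res <- seedConditionComparison(sm)
  expect_s3_class(res$theta$omnibus, "StatResult")
  expect_lt(res$theta$omnibus$p.value, 0.05)
  expect_equal(nrow(res$theta$posthoc), choose(5, 2))
  expect_equal(unique(res$theta$posthoc$family_size), 10)
  # identical maps across conditions: H = 0, p = 1, no post-hoc
  tb$delta <- rep(rnorm(20, 0.3, 0.05), 5)
  res0 <- seedConditionComparison(seedMap(makeDelta(tb), "A"))
  expect_equal(res0$theta$omnibus$statistic, 0, tolerance = 1e-9)
  expect_gt(res0$theta$omnibus$p.value, 0.999)
  expect_null(res0$theta$posthoc)
  # omnibus equals the brute-force rank computation
  groups <- split(sm$delta, sm$condition)
  expect_equal(res$theta$omnibus$statistic, oracleKruskal(groups),
               tolerance = 1e-9)
})

test_that("responder percentages are invariant to pair order and subject labels", {
  set.seed(12)
  base <- matrix(rnorm(5 * 30, 0.3, 0.05), 5)
  cond <- base + matrix(rnorm(5 * 30, 0.05, 0.05), 5)
  tab <- valueTable(base, list("6Hz" = cond))
  perm <- sample(5)
  tabP <- valueTable(base[perm, ], list("6Hz" = cond[perm, ]))
  expect_equal(responderMap(tab)$summary$percentage,
               responderMap(tabP)$summary$percentage)
})

test_that("null-session responder rate matches the d-threshold floor", {
  # With no coupling, a pair's per-epoch coherence has equal means under
  # stimulation and baseline, so d-hat > 0.2 fires at the sampling floor
  # P(d-hat > 0.2) = 1 - pnorm(0.2 / se(d)), se(d) ~ sqrt(1/30 + 1/36) for
  # the study's epoch counts: ~0.209. The observed rate over all pairs and
  # conditions must sit near that floor.
  cfg <- synthConfig(samplingRate = 500, baselineDuration = 180,
                     trialsPerCondition = 30, offDuration = 0,
                     regions = setNames(rep(1, 16), sprintf("R%02d", 1:16)),
                     seed = 515)
  ses <- buildSession(cfg)
  prep <- preprocessSession(ses$bundle, runConfig())
  tab <- pairConditionTable(prep$epochs, scheme = bandScheme(theta = c(4, 8)))
  pr <- responderMap(tab)$pairs
  floorP <- 1 - pnorm(0.2 / sqrt(1 / 30 + 1 / 36))
  expect_lt(abs(mean(pr$responder) - floorP), 0.12)
})
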