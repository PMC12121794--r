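# Coherence estimator identities, grid arithmetic, aggregation.

test_that("self-coherence is identically 1 and K = 1 is refused", {
  set.seed(1)
  x <- rnorm(2500)
  s <- mscSpectrum(x, x, fs = 500)
  expect_true(all(abs(s$coherence - 1) < 1e-9))
  expect_error(mscSpectrum(x, rnorm(2500), fs = 500, window = 5),
               "K >= 2")
  expect_error(mscSpectrum(x[1:100], rnorm(100), fs = 500), "shorter")
})

test_that("study Welch settings give K = 4 segments and a 0.4 Hz grid", {
  set.seed(2)
  s <- mscSpectrum(rnorm(2500), rnorm(2500), fs = 500)
  expect_equal(s$K, 4)                       # hop 375: starts 0/375/750/1125
  expect_equal(s$freq[2] - s$freq[1], 0.4)
  expect_equal(max(s$freq), 250)
})

test_that("estimator matches an independent direct-FFT oracle bin-wise", {
  set.seed(3)
  x <- rnorm(2500); y <- rnorm(2500)
  s <- mscSpectrum(x, y, fs = 500)
  o <- oracleMsc(x, y, fs = 500)
  expect_equal(s$coherence, o$coherence, tolerance = 1e-10)
  expect_equal(s$K, o$K)
})

test_that("MSC is symmetric, bounded, and scale invariant", {
  set.seed(4)
  for (i in 1:20) {
    x <- rnorm(1500); y <- rnorm(1500) + 0.3 * x
    a <- mscSpectrum(x, y, fs = 300)
    b <- mscSpectrum(y, x, fs = 300)
    expect_equal(a$coherence, b$coherence, tolerance = 1e-12)
    expect_true(all(a$coherence >= 0 & a$coherence <= 1))
    sc <- mscSpectrum(5.7 * x, 0.03 * y, fs = 300)
    expect_equal(a$coherence, sc$coherence, tolerance = 1e-9)
  }
})

test_that("white-noise coherence matches a Monte-Carlo oracle of the estimator", {
  # K = 4 on a 5-s epoch: the estimator has a positive bias of order 1/K;
  # the mean over bins must agree with an independent Monte-Carlo replicate
  # set of the same estimator within 2 SE.
  set.seed(5)
  nrep <- 1000
  est <- numeric(nrep); orc <- numeric(nrep)
  for (i in seq_len(nrep)) {
    x <- rnorm(2500); y <- rnorm(2500)
    est[i] <- mean(mscSpectrum(x, y, fs = 500)$coherence)
    x2 <- rnorm(2500); y2 <- rnorm(2500)
    orc[i] <- mean(oracleMsc(x2, y2, fs = 500)$coherence)
  }
  se <- sqrt(var(est) / nrep + var(orc) / nrep)
  expect_lt(abs(mean(est) - mean(orc)), 2 * se)
})

test_that("band averaging follows the half-open grid convention", {
  set.seed(6)
  s <- mscSpectrum(rnorm(2500), rnorm(2500), fs = 500)
  # constant spectrum -> every band equals the constant
  s$coherence[] <- 0.42
  bands <- bandMsc(s, defaultBands())
  expect_true(all(abs(bands - 0.42) < 1e-12))
  # theta [4, 8): bins 4.0, 4.4, ..., 7.6 = 10 bins on the 0.4 Hz grid
  idx <- which(s$freq >= 4 & s$freq < 8)
  expect_length(idx, 10)
  s$coherence[] <- 0; s$coherence[idx] <- 1
  expect_equal(unname(bandMsc(s, bandScheme(theta = c(4, 8)))["theta"]), 1)
  expect_error(bandMsc(s, bandScheme(high = c(300, 400))), "no bins")
})

test_that("band schemes must not overlap under the half-open convention", {
  expect_error(bandScheme(a = c(4, 9), b = c(8, 13)), "overlap")
  ok <- bandScheme(a = c(4, 8), b = c(8, 13))
  expect_equal(names(ok), c("a", "b"))
})

test_that("pair table enumerates C(n,2) pairs and propagates masks", {
  set.seed(7)
  arr <- array(rnorm(4 * 1500 * 3), dim = c(4, 1500, 3))
  ep <- makeEpochSet(list(baseline = arr, "20Hz" = arr + 0), fs = 300)
  ep@keepMask[["20Hz"]][2, 3] <- FALSE        # channel 2 rejected in epoch 3
  tab <- pairConditionTable(ep, scheme = bandScheme(theta = c(4, 8)))
  expect_equal(nrow(pairIndex(tab)), 6)
  v <- pairValues(tab, "20Hz", "theta")       # pairs x epochs
  withCh2 <- pairIndex(tab)$chan_a == "ch02" | pairIndex(tab)$chan_b == "ch02"
  expect_true(all(is.na(v[withCh2, 3])))
  expect_true(all(!is.na(v[!withCh2, 3])))
  expect_true(all(!is.na(v[, 1:2])))
})

test_that("per-epoch pair values agree with single-pair mscSpectrum", {
  set.seed(8)
  arr <- array(rnorm(3 * 2500 * 2), dim = c(3, 2500, 2))
  ep <- makeEpochSet(list(baseline = arr), fs = 500)
  scheme <- bandScheme(theta = c(4, 8), alpha = c(8, 13))
  tab <- pairConditionTable(ep, scheme = scheme)
  for (e in 1:2) {
    direct <- bandMsc(mscSpectrum(arr[1, , e], arr[3, , e], fs = 500), scheme)
    row <- which(pairIndex(tab)$chan_a == "ch01" &
                   pairIndex(tab)$chan_b == "ch03")
    expect_equal(unname(pairValues(tab, "baseline", "theta")[row, e]),
                 unname(direct["theta"]), tolerance = 1e-10)
    expect_equal(unname(pairValues(tab, "baseline", "alpha")[row, e]),
                 unname(direct["alpha"]), tolerance = 1e-10)
  }
})

test_that("baseline subtraction is exact arithmetic on the epoch means", {
  np <- 3
  mk <- function(vals, ne) {
    a <- array(NA_real_, dim = c(np, 1, ne))
    for (p in 1:np) a[p, 1, ] <- vals[p]
    a
  }
  tab <- methods::new("PairBandTable",
    values = list(baseline = mk(c(0.20, 0.5, 0.5), 4),
                  "20Hz" = mk(c(0.35, 0.5, 0.9), 5)),
    pooled = list(),
    pairs = data.frame(chan_a = c("c1", "c1", "c2"),
                       chan_b = c("c2", "c3", "c3")),
    bands = list(theta = c(4, 8)), channelIds = c("c1", "c2", "c3"))
  d <- baselineSubtract(tab)
  expect_equal(d$delta, c(0.15, 0, 0.4), tolerance = 1e-12)
  expect_equal(d$n_cond, c(5L, 5L, 5L))
  expect_equal(d$n_base, c(4L, 4L, 4L))
})

test_that("pairs without baseline epochs are excluded with a warning", {
  np <- 2
  base <- array(NA_real_, dim = c(np, 1, 2)); base[1, 1, ] <- 0.3
  cond <- array(0.4, dim = c(np, 1, 2))
  tab <- methods::new("PairBandTable",
    values = list(baseline = base, "6Hz" = cond), pooled = list(),
    pairs = data.frame(chan_a = c("c1", "c1"), chan_b = c("c2", "c3")),
    bands = list(theta = c(4, 8)), channelIds = c("c1", "c2", "c3"))
  expect_warning(d <- baselineSubtract(tab), "excluded")
  expect_equal(nrow(d), 1)
  expect_equal(nrow(attr(d, "excluded")), 1)
})

test_that("regionize averages electrode pairs into region pairs", {
  deltas <- data.frame(
    chan_a = c("a1", "a1", "a2", "a2"), chan_b = c("b1", "b2", "b1", "b2"),
    condition = "20Hz", band = "theta", delta = c(0.1, 0.2, 0.3, 0.4),
    n_cond = 5L, n_base = 5L)
  channels <- data.frame(channel_id = c("a1", "a2", "b1", "b2"),
                         region = c("A", "A", "B", "B"), exclude_class = "")
  rp <- regionize(deltas, channels)
  tb <- deltaTable(rp)
  expect_equal(tb$delta[tb$region_a == "A" & tb$region_b == "B"], 0.25)
  expect_equal(tb$n_pairs[tb$region_a == "A" & tb$region_b == "B"], 4L)
})

test_that("single-contact regions pass through and excluded contacts drop out", {
  deltas <- data.frame(
    chan_a = c("a1", "a1", "w1"), chan_b = c("b1", "w1", "b1"),
    condition = "6Hz", band = "alpha", delta = c(0.12, 0.5, 0.5),
    n_cond = 5L, n_base = 5L)
  channels <- data.frame(channel_id = c("a1", "b1", "w1"),
                         region = c("A", "B", "W"),
                         exclude_class = c("", "", "white_matter"))
  tb <- deltaTable(regionize(deltas, channels))
  expect_equal(nrow(tb), 1)                       # only A-B survives
  expect_equal(tb$delta, 0.12)
  expect_false("W" %in% c(tb$region_a, tb$region_b))
})

test_that("within-region pairs populate the diagonal, never self-pairs", {
  deltas <- data.frame(
    chan_a = c("a1", "a1", "a2"), chan_b = c("a2", "b1", "b1"),
    condition = "6Hz", band = "alpha", delta = c(0.3, 0.1, 0.2),
    n_cond = 5L, n_base = 5L)
  channels <- data.frame(channel_id = c("a1", "a2", "b1"),
                         region = c("A", "A", "B"), exclude_class = "")
  m <- deltaMatrix(regionize(deltas, channels), "6Hz", "alpha")
  expect_equal(m["A", "A"], 0.3)
  expect_equal(m["A", "B"], 0.15)
  expect_true(is.na(m["B", "B"]))
})

test_that("group aggregation averages across covering subjects only", {
  mk <- function(delta) makeDelta(data.frame(
    region_a = "A", region_b = "B", condition = "20Hz", band = "theta",
    delta = delta, n_pairs = 2L), level = "subject")
  g <- groupAggregate(list(mk(0.1), mk(0.2), mk(0.3)))
  tb <- deltaTable(g)
  expect_equal(tb$delta, 0.2)
  expect_equal(tb$n_subjects, 3L)
  # a pair covered by a single subject passes through
  extra <- makeDelta(data.frame(
    region_a = c("A", "A"), region_b = c("B", "C"), condition = "20Hz",
    band = "theta", delta = c(0.4, 0.9), n_pairs = 1L), level = "subject")
  g2 <- groupAggregate(list(mk(0.1), extra))
  tb2 <- deltaTable(g2)
  expect_equal(tb2$delta[tb2$region_b == "C"], 0.9)
  expect_equal(tb2$n_subjects[tb2$region_b == "C"], 1L)
  expect_equal(tb2$delta[tb2$region_b == "B"], 0.25)
  # order invariance
  g3 <- groupAggregate(list(extra, mk(0.1)))
  expect_equal(deltaTable(g3), tb2)
  expect_error(groupAggregate(list()), "at least one")
})

test_that("injected coupling uplift is recovered through the pair table", {
  # one coupled pair among independent channels; ON-epoch band coherence
  # exceeds baseline by the analytic uplift (pooled estimator)
  set.seed(9)
  fs <- 500; len <- 2500; nOn <- 30; nBase <- 30
  mkArr <- function(ne, coupled) {
    arr <- array(0, dim = c(3, len, ne))
    for (e in seq_len(ne)) {
      s <- bandLimitedNoise(len, c(8, 13), fs)
      arr[1, , e] <- bandLimitedNoise(len, c(8, 13), fs) + if (coupled) s else 0
      arr[2, , e] <- bandLimitedNoise(len, c(8, 13), fs) + if (coupled) s else 0
      arr[3, , e] <- bandLimitedNoise(len, c(8, 13), fs)
    }
    arr
  }
  ep <- makeEpochSet(list(baseline = mkArr(nBase, FALSE),
                          "20Hz" = mkArr(nOn, TRUE)), fs = fs)
  tab <- pairConditionTable(ep, scheme = bandScheme(alpha = c(8, 13)),
                            pooled = TRUE)
  d <- baselineSubtract(tab, use = "pooled")
  coupled <- d$chan_a == "ch01" & d$chan_b == "ch02"
  expect_lt(abs(d$delta[coupled] - expectedBandMsc(1, 1, 1)), 0.05)
  expect_lt(max(abs(d$delta[!coupled])), 0.15)
})
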