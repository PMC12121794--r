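# Self-contained nonparametric test implementations. Each returns a
# "StatResult": statistic, df (where defined), two-tailed p, effect size
# r = |Z|/sqrt(N) where defined, N used, and the correction applied.

.statResult <- function(method, statistic, df = NA_real_, p, n,
                        effect = NA_real_, z = NA_real_,
                        correction = "none", degenerate = FALSE) {
  structure(list(method = method, statistic = statistic, df = df,
                 p.value = p, n = n, effect = effect, z = z,
                 correction = correction, degenerate = degenerate),
            class = "StatResult")
}

#' @export
print.StatResult <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g%s, p = %.4g (N = %d%s%s)%s\n",
              x$method, x$statistic,
              if (is.na(x$df)) "" else sprintf(", df = %g", x$df),
              x$p.value, x$n,
              if (is.na(x$effect)) "" else sprintf(", r = %.3f", x$effect),
              if (identical(x$correction, "none")) "" else
                paste0(", ", x$correction),
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Friedman rank test for repeated measures
#'
#' Nonparametric alternative to a repeated-measures ANOVA: blocks are ranked
#' within themselves, and the tie-corrected chi-squared statistic on the
#' column rank sums is referred to a chi-squared distribution with k - 1
#' degrees of freedom. Complete ties (every block constant) yield statistic
#' 0 and p 1 with a warning.
#'
#' @param y numeric matrix, blocks x conditions, no missing cells.
#' @return a \code{StatResult}.
#' @examples
#' friedmanTest(matrix(rep(c(1, 2, 3), 5), 5, byrow = TRUE))  # chi2 = 10
#' @export
friedmanTest <- function(y) {
  y <- as.matrix(y)
  .assert(!anyNA(y), "missing cells are not allowed")
  n <- nrow(y); k <- ncol(y)
  .assert(n >= 2 && k >= 2, "need >= 2 blocks and >= 2 conditions")
  r <- t(apply(y, 1L, rank))
  Rj <- colSums(r)
  S <- 12 * sum((Rj - n * (k + 1) / 2)^2) / (n * k * (k + 1))
  ties <- sum(apply(y, 1L, function(row) {
    t <- table(row); sum(t^3 - t)
  }))
  corr <- 1 - ties / (n * k * (k^2 - 1))
  if (corr <= 0) {
    warning("all blocks completely tied; returning statistic 0, p 1")
    return(.statResult("Friedman test", 0, df = k - 1, p = 1, n = n,
                       degenerate = TRUE))
  }
  stat <- S / corr
  .statResult("Friedman test", stat, df = k - 1,
              p = stats::pchisq(stat, k - 1, lower.tail = FALSE), n = n)
}

#' Wilcoxon signed-rank test (paired or one-sample)
#'
#' Two-tailed signed-rank test on x - y (paired) or x - mu (one sample).
#' Zero differences are dropped by default (classic treatment; Pratt's
#' method keeps them in the ranking). For N <= 25 without ties the exact
#' null distribution of the rank sum is used; otherwise a tie-corrected
#' normal approximation without continuity correction. The effect size is
#' r = |Z|/sqrt(N) with N the number of pairs entering the test.
#'
#' @param x numeric vector.
#' @param y optional paired vector.
#' @param mu null location for the one-sample test (default 0).
#' @param zeroes \code{"drop"} (default) or \code{"pratt"}.
#' @param exactLimit largest N for the exact path (default 25).
#' @param continuity apply a 0.5 continuity correction in the normal
#'   approximation (default FALSE).
#' @return a \code{StatResult}.
#' @examples
#' wilcoxonSignedRank(1:5)$p.value   # exact: 2/32 = 0.0625
#' @export
wilcoxonSignedRank <- function(x, y = NULL, mu = 0,
                               zeroes = c("drop", "pratt"),
                               exactLimit = 25, continuity = FALSE) {
  zeroes <- match.arg(zeroes)
  d <- if (is.null(y)) x - mu else {
    .assert(length(x) == length(y), "paired vectors must have equal length")
    x - y
  }
  nzero <- sum(d == 0)
  if (zeroes == "drop") d <- d[d != 0]
  N <- length(d)
  if (N == 0 || all(d == 0)) {
    warning("all differences zero; degenerate result")
    return(.statResult("Wilcoxon signed-rank test", 0, p = 1,
                       n = length(d), effect = 0, z = 0, degenerate = TRUE))
  }
  absd <- abs(d)
  r <- rank(absd)
  if (zeroes == "pratt") {
    W <- sum(r[d > 0])
    # Pratt: zeros ranked but removed from the statistic; moments adjusted
    nz <- nzero
    muW <- (N * (N + 1) - nz * (nz + 1)) / 4
    tieSum <- sum(vapply(unique(absd[absd > 0]),
                         function(v) { t <- sum(absd == v); t^3 - t },
                         numeric(1)))
    sigW <- sqrt((N * (N + 1) * (2 * N + 1) - nz * (nz + 1) * (2 * nz + 1)) / 24 -
                   tieSum / 48)
  } else {
    W <- sum(r[d > 0])
    muW <- N * (N + 1) / 4
    tieSum <- sum(vapply(unique(absd), function(v) {
      t <- sum(absd == v); t^3 - t
    }, numeric(1)))
    sigW <- sqrt(N * (N + 1) * (2 * N + 1) / 24 - tieSum / 48)
  }
  hasTies <- tieSum > 0
  if (sigW == 0) {
    warning("zero variance; degenerate result")
    return(.statResult("Wilcoxon signed-rank test", W, p = 1, n = N,
                       effect = 0, z = 0, degenerate = TRUE))
  }
  cc <- if (continuity) sign(W - muW) * 0.5 else 0
  Z <- (W - muW - cc) / sigW
  if (zeroes == "drop" && !hasTies && N <= exactLimit) {
    pLess <- stats::psignrank(W, N)
    pGreater <- stats::psignrank(W - 1, N, lower.tail = FALSE)
    p <- min(1, 2 * min(pLess, pGreater))
    method <- "Wilcoxon signed-rank test (exact)"
  } else {
    p <- 2 * stats::pnorm(-abs(Z))
    method <- "Wilcoxon signed-rank test (normal approximation)"
  }
  .statResult(method, W, p = p, n = N, effect = abs(Z) / sqrt(N), z = Z)
}

#' Kruskal-Wallis rank test for independent groups
#'
#' Tie-corrected H statistic on the joint ranks, referred to a chi-squared
#' distribution with k - 1 degrees of freedom.
#'
#' @param groups list of numeric vectors, each non-empty.
#' @return a \code{StatResult}.
#' @examples
#' kruskalWallis(list(c(1, 2, 3), c(4, 5, 6)))$statistic  # 3.857
#' @export
kruskalWallis <- function(groups) {
  .assert(is.list(groups) && length(groups) >= 2, "need >= 2 groups")
  .assert(all(vapply(groups, length, integer(1)) > 0),
          "every group must be non-empty")
  x <- unlist(groups)
  g <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  n <- length(x); k <- length(groups)
  r <- rank(x)
  Rj <- tapply(r, g, sum)
  nj <- tabulate(g)
  H <- 12 / (n * (n + 1)) * sum(Rj^2 / nj) - 3 * (n + 1)
  t <- table(x)
  corr <- 1 - sum(t^3 - t) / (n^3 - n)
  if (corr <= 0) {
    warning("all observations tied; returning statistic 0, p 1")
    return(.statResult("Kruskal-Wallis test", 0, df = k - 1, p = 1, n = n,
                       degenerate = TRUE))
  }
  H <- H / corr
  .statResult("Kruskal-Wallis test", H, df = k - 1,
              p = stats::pchisq(H, k - 1, lower.tail = FALSE), n = n)
}

#' Exact multinomial goodness-of-fit test by full enumeration
#'
#' Enumerates every composition of n into k categories and sums the
#' multinomial probabilities of all outcomes whose probability does not
#' exceed that of the observed outcome (probability-ordering extremeness,
#' with a relative float guard of 1e-12).
#'
#' @param counts non-negative integer category counts.
#' @param probs category probabilities summing to 1 (default uniform).
#' @return the exact p-value; the total probability of the enumerated
#'   outcome space is in attribute \code{"totalProbability"} and the number
#'   of enumerated outcomes in \code{"outcomes"}.
#' @examples
#' exactMultinomial(c(0, 2, 1, 3, 1))  # 0.624 (n = 7, uniform fifths)
#' exactMultinomial(c(0, 0, 0, 4, 3))  # 0.016
#' @export
exactMultinomial <- function(counts, probs = rep(1 / length(counts),
                                                 length(counts))) {
  .assert(all(counts >= 0) && all(counts == round(counts)),
          "counts must be non-negative integers")
  .assert(length(probs) == length(counts), "probs/counts length mismatch")
  .assert(abs(sum(probs) - 1) <= 1e-9, "probs must sum to 1")
  n <- sum(counts); k <- length(counts)
  .assert(choose(n + k - 1, k - 1) <= 2e6, "outcome space too large to enumerate")
  logp <- log(probs)
  compositions <- function(n, k) {
    if (k == 1L) return(matrix(n, 1L))
    do.call(rbind, lapply(0:n, function(i)
      cbind(i, compositions(n - i, k - 1L))))
  }
  out <- compositions(n, k)
  lp <- lgamma(n + 1) - rowSums(lgamma(out + 1)) +
    as.vector(out %*% logp)
  pAll <- exp(lp)
  pObs <- exp(lgamma(n + 1) - sum(lgamma(counts + 1)) + sum(counts * logp))
  p <- sum(pAll[pAll <= pObs * (1 + 1e-12)])
  structure(min(1, p), totalProbability = sum(pAll), outcomes = nrow(out))
}

#' Cohen's d with pooled standard deviation
#'
#' d = (mean(a) - mean(b)) / s_pooled with the (n-1)-weighted pooled SD. If
#' the pooled SD is zero, equal means give d = 0 and unequal means are an
#' error.
#'
#' @param a,b numeric vectors with at least 2 values each.
#' @return Cohen's d.
#' @export
cohensD <- function(a, b) {
  .assert(length(a) >= 2 && length(b) >= 2, "each sample needs >= 2 values")
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  if (sp == 0) {
    .assert(isTRUE(all.equal(mean(a), mean(b))),
            "zero pooled SD with unequal means")
    return(0)
  }
  (mean(a) - mean(b)) / sp
}

#' Bonferroni adjustment
#'
#' Multiplies p-values by the family size m and caps at 1.
#'
#' @param p numeric vector of p-values.
#' @param m family size, >= 1.
#' @return adjusted p-values.
#' @export
bonferroniAdjust <- function(p, m) {
  .assert(m >= 1, "family size m must be >= 1")
  pmin(1, p * m)
}
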