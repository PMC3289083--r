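# Confusion measures, ROC/AUC, per-sequence comparison, confidence bins.

test_that("confusion measures follow their formulas and the MCC conventions", {
  y <- c(rep(1L, 10), rep(0L, 20))
  # all predicted binding: MCC 0 by the zero-denominator convention
  m <- confusionMetrics(rep(1L, 30), y)
  expect_equal(unname(m["MCC"]), 0)
  expect_equal(unname(m["SENS"]), 1)
  expect_equal(unname(m["SPEC"]), 0)
  # all predicted non-binding likewise
  expect_equal(unname(confusionMetrics(rep(0L, 30), y)["MCC"]), 0)
  # perfect prediction
  mp <- confusionMetrics(y, y)
  expect_equal(unname(mp[c("SENS", "SPEC", "ACC", "MCC")]), c(1, 1, 1, 1))
  # fixed table against direct formula evaluation
  calls <- c(rep(1L, 50), rep(0L, 20), rep(1L, 10), rep(0L, 100))
  labs <- c(rep(1L, 70), rep(0L, 110))
  m2 <- confusionMetrics(calls, labs)
  expect_equal(unname(m2[c("TP", "FN", "FP", "TN")]), c(50, 20, 10, 100))
  expect_equal(unname(m2["MCC"]),
               (50 * 100 - 10 * 20) / sqrt(60 * 70 * 110 * 120))
  expect_error(confusionMetrics(1L, c(1L, 0L)), "length")
})

test_that("ROC sweep matches the rank-sum oracle and its invariances", {
  # perfect ordering
  expect_equal(rocAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # all scores equal: a single diagonal segment
  expect_equal(rocAuc(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)
  # tie-corrected Mann-Whitney oracle on random instances
  set.seed(14)
  for (i in 1:20) {
    s <- sample(seq(0, 1, by = 0.05), 50, replace = TRUE)  # heavy ties
    y <- rbinom(50, 1, 0.4)
    if (length(unique(y)) < 2) next
    r <- rank(s)
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    oracle <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    expect_equal(rocAuc(s, y), oracle, tolerance = 1e-12)
  }
  # invariance under strictly monotone transforms
  set.seed(15)
  s <- runif(60); y <- rbinom(60, 1, 0.3)
  expect_equal(rocAuc(qlogis(s * 0.98 + 0.01), y), rocAuc(s, y))
  expect_equal(rocAuc(s^3, y), rocAuc(s, y))
  # curve endpoints and the label-flip identity (tie-free scores)
  s2 <- sample(seq_len(40)) / 41
  y2 <- rbinom(40, 1, 0.5)
  rc <- rocCurve(s2, y2)
  expect_equal(unlist(rc$points[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(rc$points[nrow(rc$points), c("fpr", "tpr")]),
               c(fpr = 1, tpr = 1))
  expect_true(all(diff(rc$points$fpr) >= 0) && all(diff(rc$points$tpr) >= 0))
  expect_equal(rocAuc(s2, 1 - y2), 1 - rocAuc(s2, y2))
  expect_error(rocAuc(s2, rep(1, 40)), "positive and one negative")
})

test_that("pooled metrics equal metrics recomputed from per-chain counts", {
  sim <- makeSmallSim(nChains = 5L, seed = 27L)
  tracks <- lapply(sim$chains, function(ch) makeRandomTrack(ch, seed = 1))
  names(tracks) <- names(sim$chains)
  rep <- evaluateTracks(tracks, sim$chains)
  pooledCalls <- unlist(lapply(names(tracks), function(i) bindingCalls(tracks[[i]])))
  pooledLabs <- unlist(lapply(names(tracks), function(i) bindingLabels(sim$chains[[i]])))
  expect_equal(rep$pooled$MCC,
               unname(confusionMetrics(pooledCalls, pooledLabs)["MCC"]))
  expect_identical(rep$n, length(pooledLabs))
  expect_identical(nrow(rep$perChain), 5L)
})

test_that("per-sequence comparison uses the exact signed-rank distribution", {
  sim <- makeSmallSim(nChains = 10L, seed = 29L)
  chains <- sim$chains
  # method A: probabilities correlated with the labels; method B: noise
  mkTracks <- function(quality, seed) {
    set.seed(seed)
    out <- lapply(chains, function(ch) {
      y <- bindingLabels(ch)
      p <- pmin(pmax(quality * y + runif(length(y), 0, 0.55), 0), 1)
      predictionTrack(chainId(ch), chainSequence(ch), p,
                      as.integer(p >= 0.5), threshold = 0.5, method = "m")
    })
    names(out) <- names(chains)
    out
  }
  A <- mkTracks(0.45, 1)
  B <- mkTracks(0, 2)
  ps <- perSequenceCompare(A, B, chains)
  expect_lt(ps$tests$AUC$p.value, 0.01)   # A strictly better on every chain
  expect_identical(nrow(ps$perChain), 10L)
  # identical tracks: statistic at the null center, p = 1
  psSame <- perSequenceCompare(A, A, chains)
  expect_equal(psSame$tests$AUC$p.value, 1)
  expect_equal(psSame$tests$MCC$p.value, 1)
  # n = 6 difference vector against enumeration of all 2^6 sign assignments
  d <- c(0.31, -0.12, 0.24, 0.05, 0.17, 0.09)
  w <- ATPbindR:::.pairedWilcoxon(d, rep(0, length(d)))
  ranks <- rank(abs(d))
  obs <- sum(ranks[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 6))
  null <- apply(signs, 1, function(s) sum(ranks[s == 1]))
  exact2sided <- min(1, 2 * min(mean(null >= obs), mean(null <= obs)))
  expect_equal(w$p.value, exact2sided, tolerance = 1e-12)
  # too few valid pairs: both metric tests are skipped with warnings
  expect_warning(expect_warning(
    few <- perSequenceCompare(A[1:3], B[1:3], chains[1:3]), "skipped"),
    "skipped")
  expect_true(is.na(few$tests$MCC$p.value))
})

test_that("confidence bins use half-open intervals with a closed top bin", {
  p <- c(0, 0.049, 0.05, 0.5, 0.949, 0.95, 1.0)
  calls <- as.integer(p >= 0.5)
  labs <- c(0L, 0L, 1L, 1L, 1L, 1L, 1L)
  cb <- confidenceBins(p, calls, labs)
  expect_identical(nrow(cb), 20L)
  expect_equal(cb$n[1], 2L)         # 0 and 0.049
  expect_equal(cb$n[2], 1L)         # 0.05 opens bin 2
  expect_equal(cb$n[20], 2L)        # 0.95 and the closed-top 1.0
  expect_equal(sum(cb$fraction), 1)
  expect_true(is.na(cb$accuracy[5]))  # empty bin reported as missing
  # constructed high-confidence correctness
  expect_equal(cb$accuracy[20], 1)
  # all residues in one bin
  cb2 <- confidenceBins(rep(0.3, 8), rep(0L, 8), rep(0L, 8))
  expect_equal(cb2$fraction[7], 1)
  expect_equal(sum(cb2$n), 8L)
})
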