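# Alignment transfer, conservation baseline, consensus.

test_that("alignment transfer copies labels across the best local alignment", {
  sim <- makeSmallSim(nChains = 6L, seed = 33L)
  db <- sim$chains
  # query identical to an annotated chain (under a different id): the track
  # equals that chain's labels exactly
  q <- db[[2]]
  tr <- alignmentTransfer(chainSequence(q), db, queryId = "query")
  expect_identical(bindingCalls(tr), bindingLabels(q))
  expect_true(all(is.na(probabilities(tr))))
  expect_identical(tr@meta$template, chainId(q))
  # self-exclusion: the chain itself is never its own template
  trSelf <- alignmentTransfer(q, db)
  expect_false(identical(trSelf@meta$template, chainId(q)))
  # random query with no similarity: all-zero flagged track
  set.seed(1)
  rnd <- paste(sample(c("A", "G", "S", "P"), 30, replace = TRUE), collapse = "")
  trR <- alignmentTransfer(rnd, db, queryId = "rnd")
  expect_true(trR@meta$noHit)
  expect_identical(sum(bindingCalls(trR)), 0L)
  expect_error(alignmentTransfer(q, db["syn002"]), "empty")
})

test_that("an insertion in the template shifts transferred labels by the indel", {
  # hand-made 15-mers: template = query with one extra residue inserted at
  # position 8; template labels after the insertion map back one position
  qSeq <- "MKVLRAGHEWDNSTC"
  tSeq <- paste0(substr(qSeq, 1, 7), "G", substr(qSeq, 8, 15))  # insert at 8
  tLab <- integer(16)
  tLab[c(3, 12)] <- 1L    # position 12 in template = position 11 in query
  db <- list(tmpl = labeledChain("tmpl", tSeq, tLab))
  tr <- alignmentTransfer(qSeq, db, queryId = "q")
  expect_identical(which(bindingCalls(tr) == 1L), c(3L, 11L))
})

test_that("conservation baseline orients, normalizes and thresholds scores", {
  sim <- makeSmallSim(nChains = 4L, seed = 37L)
  chains <- sim$chains
  # scores = -labels with low = conserved orientation: after inversion the
  # normalized score equals the label, so thresholding is perfect
  scores <- lapply(chains, function(ch)
    list(score = -as.numeric(bindingLabels(ch)), lowIsConserved = TRUE))
  tracks <- conservationBaseline(scores, chains)
  for (id in names(chains)) {
    expect_identical(bindingCalls(tracks[[id]]), bindingLabels(chains[[id]]))
    expect_equal(unname(confusionMetrics(bindingCalls(tracks[[id]]),
                                         bindingLabels(chains[[id]]))["MCC"]), 1)
  }
  # min-max endpoints
  s2 <- list(c1 = list(score = c(3, 7, 11), lowIsConserved = FALSE))
  ch2 <- list(c1 = labeledChain("c1", "AKV", c(0L, 0L, 1L)))
  tr2 <- conservationBaseline(s2, ch2)
  expect_equal(probabilities(tr2$c1), c(0, 0.5, 1))
  # threshold equals the exhaustive scan oracle on a 20-residue toy
  set.seed(5)
  sc <- round(runif(20), 2)
  y <- rbinom(20, 1, 0.4)
  ch3 <- list(t1 = labeledChain("t1", strrep("A", 20), y))
  tr3 <- conservationBaseline(list(t1 = list(score = sc, lowIsConserved = FALSE)),
                              ch3)
  p <- (sc - min(sc)) / diff(range(sc))
  cand <- sort(unique(p))
  mccs <- vapply(cand, function(t)
    unname(confusionMetrics(as.integer(p >= t), y)["MCC"]), numeric(1))
  expect_equal(threshold(tr3$t1), cand[which(mccs == max(mccs))[1]])
  # constant scores: threshold undefined, all calls 0 with warning
  expect_warning(
    tr4 <- conservationBaseline(list(c1 = list(score = rep(2, 3),
                                               lowIsConserved = TRUE)), ch2),
    "undefined")
  expect_identical(sum(bindingCalls(tr4$c1)), 0L)
})

test_that("consensus is the max/OR disjunction with binary components as 0/1", {
  ch <- labeledChain("c", "MKVA", c(0L, 1L, 0L, 1L))
  t1 <- predictionTrack("c", "MKVA", c(0.3, 0.7, 0.1, 0.2),
                        c(1L, 0L, 0L, 0L), method = "a")
  t2 <- predictionTrack("c", "MKVA", c(0.7, 0.3, 0.2, 0.1),
                        c(0L, 1L, 0L, 1L), method = "b")
  cons <- consensusTrack(t1, t2)
  expect_identical(bindingCalls(cons), c(1L, 1L, 0L, 1L))
  expect_equal(probabilities(cons), c(0.7, 0.7, 0.2, 0.2))
  # binary-only component contributes its calls as probabilities
  tb <- predictionTrack("c", "MKVA", rep(NA_real_, 4), c(0L, 0L, 1L, 0L),
                        method = "alignment")
  consB <- consensusTrack(t1, tb)
  expect_equal(probabilities(consB), c(0.3, 0.7, 1.0, 0.2))
  expect_identical(bindingCalls(consB), c(1L, 0L, 1L, 0L))
  # idempotence
  expect_equal(probabilities(consensusTrack(t1, t1)), probabilities(t1))
  expect_identical(bindingCalls(consensusTrack(t1, t1)), bindingCalls(t1))
  expect_error(consensusTrack(t1), "at least two")
  t3 <- predictionTrack("other", "MKVA", rep(0.5, 4), rep(0L, 4))
  expect_error(consensusTrack(t1, t3), "same chain")
})

test_that("consensus algebra holds on random track pairs", {
  sim <- makeSmallSim(nChains = 2L, seed = 41L)
  ch <- sim$chains[[1]]
  y <- bindingLabels(ch)
  for (i in 1:25) {
    a <- makeRandomTrack(ch, seed = i)
    b <- makeRandomTrack(ch, seed = 1000 + i)
    c3 <- makeRandomTrack(ch, seed = 2000 + i)
    ab <- consensusTrack(a, b)
    ba <- consensusTrack(b, a)
    # commutative, associative
    expect_equal(probabilities(ab), probabilities(ba))
    expect_identical(bindingCalls(ab), bindingCalls(ba))
    expect_equal(probabilities(consensusTrack(ab, c3)),
                 probabilities(consensusTrack(a, consensusTrack(b, c3))))
    # disjunction bounds: sensitivity never below a component, specificity
    # never above
    mAB <- confusionMetrics(bindingCalls(ab), y)
    mA <- confusionMetrics(bindingCalls(a), y)
    mB <- confusionMetrics(bindingCalls(b), y)
    expect_gte(mAB["SENS"], max(mA["SENS"], mB["SENS"]))
    expect_lte(mAB["SPEC"], min(mA["SPEC"], mB["SPEC"]))
  }
})

test_that("a complementary pair's consensus beats both components", {
  # each method is perfect on half the chain and uninformative (0.5) on the
  # other half: the max-consensus recovers the full signal
  set.seed(7)
  L <- 120L
  y <- as.integer(runif(L) < 0.3)
  half <- seq_len(L) <= L / 2
  seqStr <- strrep("A", L)
  pa <- ifelse(half, 0.98 * y + 0.01, 0.5)
  pb <- ifelse(!half, 0.98 * y + 0.01, 0.5)
  a <- predictionTrack("c", seqStr, pa, as.integer(pa >= 0.5), method = "a")
  b <- predictionTrack("c", seqStr, pb, as.integer(pb >= 0.5), method = "b")
  cons <- consensusTrack(a, b)
  expect_gt(rocAuc(probabilities(cons), y), rocAuc(probabilities(a), y))
  expect_gt(rocAuc(probabilities(cons), y), rocAuc(probabilities(b), y))
})
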