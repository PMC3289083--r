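# Fold construction, biserial ranking, best-first forward selection.

test_that("chain-level folds partition the chains deterministically", {
  ids <- sprintf("c%02d", 1:23)
  f1 <- makeFolds(ids, k = 5, seed = 9)
  f2 <- makeFolds(ids, k = 5, seed = 9)
  expect_identical(as.integer(f1), as.integer(f2))
  expect_setequal(names(f1), ids)
  expect_true(all(f1 %in% 1:5))
  expect_true(all(table(f1) >= 4))   # balanced round-robin deal
  expect_false(identical(as.integer(makeFolds(ids, k = 5, seed = 10)),
                         as.integer(f1)))
  expect_error(makeFolds(c("a", "a", "b"), k = 2), "unique")
})

test_that("biserial correlation equals the Pearson correlation with 0/1 labels", {
  y <- c(rep(1L, 6), rep(0L, 6))
  expect_equal(biserialCorrelation(as.numeric(y), y), 1)
  # constructed orthogonality: same mean in both classes
  x <- c(1, 2, 3, 1, 2, 3, 1, 2, 3, 1, 2, 3)
  expect_equal(biserialCorrelation(x, y), 0)
  # random instances against the independent Pearson oracle
  set.seed(12)
  for (i in 1:20) {
    xi <- rnorm(20)
    yi <- sample(c(0L, 1L), 20, replace = TRUE)
    if (length(unique(yi)) < 2) next
    expect_equal(biserialCorrelation(xi, yi), cor(xi, yi), tolerance = 1e-12)
  }
  expect_warning(r <- biserialCorrelation(rep(1, 10), y[1:10]), "zero-variance")
  expect_equal(r, 0)
  expect_error(biserialCorrelation(rnorm(5), rep(1L, 5)), "both label classes")
})

# small labeled FeatureMatrix over several chains with one informative column
makeRankingFixture <- function(nChains = 10L, perChain = 30L, seed = 3L) {
  set.seed(seed)
  ids <- sprintf("c%02d", seq_len(nChains))
  n <- nChains * perChain
  y <- rbinom(n, 1, 0.3)
  X <- cbind(signal = y + rnorm(n, 0, 0.3),
             noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n))
  groups <- setNames(rep("pssm", ncol(X)), colnames(X))
  fm <- new("FeatureMatrix", features = X,
            chain = rep(ids, each = perChain),
            position = rep(seq_len(perChain), nChains),
            labels = as.integer(y), groups = groups)
  list(fm = fm, ids = ids)
}

test_that("ranking puts label-aligned features first and is order-invariant", {
  fx <- makeRankingFixture()
  folds <- makeFolds(fx$ids, k = 5, seed = 1)
  rk <- rankFeatures(fx$fm, folds)
  expect_identical(rk$feature[1], "signal")
  # permuting the column order does not change the ranking content
  perm <- c(3, 1, 4, 2)
  fmP <- new("FeatureMatrix", features = fx$fm@features[, perm],
             chain = fx$fm@chain, position = fx$fm@position,
             labels = fx$fm@labels, groups = fx$fm@groups[perm])
  rkP <- rankFeatures(fmP, folds)
  expect_identical(rkP$feature, rk$feature)
  expect_equal(rkP$meanAbsCorrelation, rk$meanAbsCorrelation)
  # brute-force recomputation oracle on the per-fold training sets
  rowFold <- as.integer(folds[fx$fm@chain])
  manual <- sapply(colnames(fx$fm@features), function(cn) {
    mean(sapply(1:5, function(f) {
      tr <- rowFold != f
      abs(cor(fx$fm@features[tr, cn], fx$fm@labels[tr]))
    }))
  })
  expect_equal(setNames(rk$meanAbsCorrelation, rk$feature),
               manual[rk$feature], tolerance = 1e-12)
})

test_that("best-first forward accepts separating features and rejects noise", {
  fx <- makeRankingFixture(seed = 5L)
  folds <- makeFolds(fx$ids, k = 5, seed = 2)
  # make the first feature perfectly separating
  X <- fx$fm@features
  X[, "signal"] <- fx$fm@labels * 2 - 1
  fm <- new("FeatureMatrix", features = X, chain = fx$fm@chain,
            position = fx$fm@position, labels = fx$fm@labels,
            groups = fx$fm@groups)
  tr <- bestFirstForward(fm, folds)
  expect_true("signal" %in% tr$selected)
  expect_identical(tr$trace$feature[1], "signal")
  expect_true(tr$trace$accepted[1])
  expect_equal(tr$trace$auc[1], 1.0)
  # the accepted-AUC path is non-decreasing
  expect_true(all(diff(tr$trace$bestAuc) >= 0))

  # pure-noise features: the selected set stays small and the final AUC
  # hovers at chance
  set.seed(31)
  Xn <- matrix(rnorm(1500 * 4), 1500, 4,
               dimnames = list(NULL, paste0("n", 1:4)))
  yn <- rbinom(1500, 1, 0.3)
  fmN <- new("FeatureMatrix", features = Xn,
             chain = rep(sprintf("c%02d", 1:10), each = 150),
             position = rep(1:150, 10), labels = as.integer(yn),
             groups = setNames(rep("pssm", 4), colnames(Xn)))
  foldsN <- makeFolds(sprintf("c%02d", 1:10), k = 5, seed = 3)
  trN <- bestFirstForward(fmN, foldsN)
  expect_lte(length(trN$selected), 2L)
  expect_lt(trN$finalAuc, 0.6)
})

test_that("selection and screening are blind to held-out chains", {
  sim <- makeSmallSim(nChains = 10L, seed = 17L)
  ids <- names(sim$chains)
  trainIds <- ids[1:8]
  testIds <- ids[9:10]
  opts <- pipelineOptions(selectTopN = 6, selectSample = 600)
  ref <- suppressMessages(suppressWarnings(
    selectForTraining(sim$chains, sim$bundles, trainIds, seed = 5, opts = opts)))
  # poison the held-out chains' labels completely
  poisoned <- sim$chains
  for (id in testIds) {
    flipped <- 1L - bindingLabels(poisoned[[id]])
    poisoned[[id]] <- labeledChain(id, chainSequence(poisoned[[id]]), flipped)
  }
  alt <- suppressMessages(suppressWarnings(
    selectForTraining(poisoned, sim$bundles, trainIds, seed = 5, opts = opts)))
  expect_identical(ref$ranking, alt$ranking)
  expect_identical(ref$trace$feature, alt$trace$feature)
  expect_identical(ref$trace$accepted, alt$trace$accepted)
  expect_equal(ref$trace$auc, alt$trace$auc)
  expect_identical(ref$colloc$selected, alt$colloc$selected)
  expect_identical(ref$selected, alt$selected)
})
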