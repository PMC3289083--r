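# End-to-end cross-validated pipeline: collocation screening, ranking,
# best-first selection, optional kernel parameterization, threshold
# calibration and prediction, all confined to the training chains of each
# outer fold so held-out labels can never influence model building.

#' Computational options of the cross-validated pipeline
#'
#' Scientific constants (window size 17, collocation p-cutoff 1e-6, 5 folds,
#' linear C = 1 selection classifier) keep their standard defaults; the
#' remaining knobs bound the computation: ranking considers all features but
#' only the top `selectTopN` enter the forward-selection pass, and SVM fits
#' run on a seeded residue subsample of the training rows (`selectSample`
#' rows during selection, `trainSample` for the final model). `fallbackTopN`
#' features (by rank) are used when forward selection accepts nothing, as
#' happens on signal-free data.
#'
#' @param window window size (default 17).
#' @param k folds, outer and inner (default 5).
#' @param collocPCut collocation survival threshold (default 1e-6).
#' @param selectTopN ranked candidates examined by forward selection.
#' @param selectSample residue subsample size for selection SVM fits.
#' @param trainSample residue subsample size for the final model fit.
#' @param kernel final-model kernel when not parameterizing.
#' @param cost final-model cost when not parameterizing.
#' @param parameterize run the two-stage kernel/cost search (default FALSE).
#' @param fallbackTopN features used when selection accepts none.
#' @return List of class `PipelineOptions`.
#' @export
pipelineOptions <- function(window = 17L, k = 5L, collocPCut = 1e-6,
                            selectTopN = 25L, selectSample = 2500L,
                            trainSample = 3500L, kernel = "radial",
                            cost = 1, parameterize = FALSE,
                            fallbackTopN = 5L) {
  structure(list(window = as.integer(window), k = as.integer(k),
                 collocPCut = collocPCut, selectTopN = as.integer(selectTopN),
                 selectSample = as.integer(selectSample),
                 trainSample = as.integer(trainSample), kernel = kernel,
                 cost = cost, parameterize = isTRUE(parameterize),
                 fallbackTopN = as.integer(fallbackTopN)),
            class = "PipelineOptions")
}

# seeded residue subsample of a row index set
.subsampleRows <- function(rows, size, seed) {
  if (length(rows) <= size) return(rows)
  set.seed(seed)
  sort(sample(rows, size))
}

#' Screen, rank and select features on a training chain set
#'
#' Everything here sees only the chains named in `trainIds`: the collocation
#' screen, the inner chain-level folds, the biserial ranking and the
#' best-first forward pass. Held-out chains (and their labels) cannot
#' influence the result — the package's leakage guarantee.
#'
#' @param chains named list of [LabeledChain-class].
#' @param bundles named list of [ProfileBundle-class].
#' @param trainIds chain ids forming the training set.
#' @param seed integer seed for inner folds and subsampling.
#' @param opts a [pipelineOptions()].
#' @param baseFm optional precomputed [FeatureMatrix-class] of base (non-
#'   collocation) features over at least the training chains.
#' @return List with `colloc` (the `CollocationScreen`), `ranking`, `trace`
#'   (the `SelectionTrace`), `selected` (feature names, with fallback
#'   applied), `innerFolds`, `fm` (the training FeatureMatrix incl.
#'   collocation columns) and `selRows` (the subsample used for SVM fits).
#' @export
selectForTraining <- function(chains, bundles, trainIds, seed,
                              opts = pipelineOptions(), baseFm = NULL) {
  trainChains <- chains[trainIds]
  win <- windowSpec(opts$window)
  colloc <- screenCollocations(trainChains, pCut = opts$collocPCut)
  if (is.null(baseFm))
    baseFm <- encodeDataset(trainChains, bundles[trainIds], collocPairs = NULL,
                            window = win)
  keep <- baseFm@chain %in% trainIds
  fm <- subsetFeatureMatrix(baseFm, rows = keep)
  if (nrow(colloc$selected)) {
    cm <- do.call(rbind, lapply(trainIds, function(id)
      collocationFeatures(chains[[id]]@sequence, colloc)))
    feat <- cbind(fm@features, cm)
    groups <- c(fm@groups, stats::setNames(rep("colloc", ncol(cm)), colnames(cm)))
    fm <- new("FeatureMatrix", features = feat, chain = fm@chain,
              position = fm@position, labels = fm@labels, groups = groups)
  }
  innerFolds <- makeFolds(trainIds, k = opts$k, seed = seed)
  ranking <- rankFeatures(fm, innerFolds)
  selRows <- .subsampleRows(seq_len(nrow(fm@features)), opts$selectSample,
                            seed = seed + 1L)
  fmSel <- subsetFeatureMatrix(fm, rows = selRows)
  trace <- bestFirstForward(fmSel, innerFolds, ranking = ranking,
                            maxFeatures = opts$selectTopN)
  selected <- trace$selected
  if (!length(selected)) {
    selected <- utils::head(ranking$feature, opts$fallbackTopN)
    message("forward selection accepted no feature; falling back to the top-ranked features")
  }
  list(colloc = colloc, ranking = ranking, trace = trace,
       selected = selected, innerFolds = innerFolds, fm = fm,
       selRows = selRows)
}

#' Run the full cross-validated prediction pipeline
#'
#' Chains are split into `k` chain-level outer folds. For each outer fold,
#' collocation screening, feature ranking, best-first forward selection,
#' (optionally) kernel/cost parameterization and threshold calibration run
#' inside the training chains; the trained model then predicts the held-out
#' chains. The pooled out-of-fold predictions yield the cross-validated AUC
#' and, at each fold's calibrated threshold, the binary metrics.
#'
#' @param sim a list with `chains` and `bundles` (e.g. from
#'   [simulateDataset()] or [readFixtures()]).
#' @param seed integer seed governing folds, subsampling and selection.
#' @param opts a [pipelineOptions()].
#' @return An object of class `PipelineResult`: list with `tracks`
#'   (out-of-fold [PredictionTrack-class] per chain), `evaluation` (an
#'   `EvalReport`), `auc`, `mcc`, `folds`, `perFold` (selection size, kernel,
#'   threshold per fold) and `manifest` (seed, options, feature counts and
#'   the key numbers, for reproducibility checks).
#' @export
runPipeline <- function(sim, seed = 1L, opts = pipelineOptions()) {
  chains <- sim$chains
  bundles <- sim$bundles
  ids <- names(chains)
  win <- windowSpec(opts$window)
  outer <- makeFolds(ids, k = opts$k, seed = seed)
  baseFm <- encodeDataset(chains, bundles, collocPairs = NULL, window = win)
  tracks <- list()
  perFold <- list()
  for (f in seq_len(opts$k)) {
    testIds <- ids[outer == f]
    trainIds <- setdiff(ids, testIds)
    foldSeed <- seed * 1000L + f
    sel <- selectForTraining(chains, bundles, trainIds, seed = foldSeed,
                             opts = opts, baseFm = baseFm)
    kernel <- opts$kernel
    params <- list(cost = opts$cost)
    if (opts$parameterize) {
      fmPar <- subsetFeatureMatrix(sel$fm, rows = sel$selRows)
      ps <- svmParameterize(fmPar, sel$innerFolds, features = sel$selected)
      kernel <- ps$kernel
      params <- ps$params
    }
    trainRows <- .subsampleRows(seq_len(nrow(sel$fm@features)),
                                opts$trainSample, seed = foldSeed + 2L)
    fmTrain <- subsetFeatureMatrix(sel$fm, rows = trainRows,
                                   columns = sel$selected)
    model <- trainBindingModel(fmTrain, sel$innerFolds,
                               features = sel$selected, kernel = kernel,
                               params = params, seed = foldSeed)
    testFm <- encodeDataset(chains[testIds], bundles[testIds],
                            collocPairs = sel$colloc, window = win)
    testFm <- subsetFeatureMatrix(testFm, columns = sel$selected)
    preds <- predictBinding(model, testFm,
                            sequences = lapply(chains[testIds], chainSequence))
    tracks[testIds] <- preds[testIds]
    perFold[[f]] <- list(fold = f, nSelected = length(sel$selected),
                         nColloc = nrow(sel$colloc$selected),
                         kernel = kernel, params = params,
                         threshold = model@threshold,
                         selected = sel$selected)
  }
  tracks <- tracks[ids]
  evaluation <- evaluateTracks(tracks, chains)
  manifest <- list(seed = seed, options = unclass(opts),
                   nChains = length(ids),
                   nResidues = evaluation$n,
                   positiveFraction = mean(unlist(lapply(chains, bindingLabels))),
                   auc = evaluation$pooled$AUC,
                   mcc = evaluation$pooled$MCC,
                   thresholds = vapply(perFold, `[[`, numeric(1), "threshold"),
                   nSelected = vapply(perFold, `[[`, numeric(1), "nSelected"))
  structure(list(tracks = tracks, evaluation = evaluation,
                 auc = evaluation$pooled$AUC, mcc = evaluation$pooled$MCC,
                 folds = outer, perFold = perFold, manifest = manifest),
            class = "PipelineResult")
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat(sprintf("PipelineResult: %d chains, %d residues; cross-validated AUC %.4f, MCC %.4f\n",
              x$manifest$nChains, x$manifest$nResidues, x$auc, x$mcc))
  cat(sprintf("  mean threshold %.4f; features selected per fold: %s\n",
              mean(x$manifest$thresholds),
              paste(x$manifest$nSelected, collapse = ", ")))
  invisible(x)
}
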