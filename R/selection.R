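# Chain-level cross-validation folds, point-biserial feature ranking and
# best-first forward selection.

#' Assign chains to cross-validation folds
#'
#' Splits are always by chain, never by residue: a seeded shuffle of the
#' chain ids is dealt round-robin into `k` folds.
#'
#' @param chainIds character vector of chain ids.
#' @param k number of folds (default 5).
#' @param seed integer seed for the shuffle.
#' @return Named integer vector (chain id to fold in 1..k) of class
#'   `FoldSplit`, with `k` and `seed` attributes.
#' @export
makeFolds <- function(chainIds, k = 5L, seed = 1L) {
  chainIds <- as.character(chainIds)
  if (anyDuplicated(chainIds)) .stopf("chain ids must be unique")
  if (length(chainIds) < k) .stopf("need at least k=%d chains", k)
  set.seed(seed)
  ord <- sample(chainIds)
  folds <- stats::setNames(rep(seq_len(k), length.out = length(ord)), ord)
  folds <- folds[chainIds]
  structure(folds, k = as.integer(k), seed = as.integer(seed),
            class = c("FoldSplit", "integer"))
}

#' Point-biserial correlation between a feature and binary labels
#'
#' `(mean1 - mean0) / sd * sqrt(n1 * n0 / n^2)` with the population standard
#' deviation, which equals the Pearson correlation between the feature and
#' the 0/1 labels.
#'
#' @param x numeric feature values.
#' @param y 0/1 labels of the same length.
#' @return Correlation in \[-1, 1\]; 0 with a warning for a zero-variance
#'   feature. Single-class labels are an error.
#' @export
biserialCorrelation <- function(x, y) {
  if (length(x) != length(y)) .stopf("x and y must have equal length")
  if (length(x) < 2L) .stopf("need at least 2 samples")
  y <- as.integer(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) .stopf("both label classes must be present")
  sdp <- sqrt(sum((x - mean(x))^2) / length(x))
  if (sdp == 0) {
    .warnf("zero-variance feature; correlation set to 0")
    return(0)
  }
  (mean(x[y == 1L]) - mean(x[y == 0L])) / sdp * sqrt(n1 * n0) / length(x)
}

# vectorized point-biserial over all columns (no per-column warnings;
# zero-variance columns map to 0)
.biserialAll <- function(X, y) {
  y <- as.integer(y)
  n <- length(y)
  n1 <- sum(y == 1L); n0 <- n - n1
  if (n1 == 0L || n0 == 0L) .stopf("both label classes must be present")
  m <- colMeans(X)
  m1 <- colMeans(X[y == 1L, , drop = FALSE])
  m0 <- colMeans(X[y == 0L, , drop = FALSE])
  sdp <- sqrt(colMeans(X^2) - m^2)
  r <- (m1 - m0) / sdp * sqrt(n1 * n0) / n
  r[!is.finite(r)] <- 0
  r
}

#' Rank features by averaged absolute biserial correlation
#'
#' For each fold, correlations are computed on that fold's training set (the
#' union of the other folds); absolute values are averaged over folds and
#' sorted descending, ties broken by column name for determinism. Absolute
#' correlation is used because negatively associated features are equally
#' useful to a linear SVM.
#'
#' @param fm a [FeatureMatrix-class] with labels.
#' @param folds a [makeFolds()] assignment covering the matrix's chains.
#' @return Data frame of class `FeatureRanking` with columns `feature` and
#'   `meanAbsCorrelation`, in rank order.
#' @export
rankFeatures <- function(fm, folds) {
  X <- fm@features
  y <- fm@labels
  if (any(is.na(y))) .stopf("rankFeatures requires labeled rows")
  rowFold <- as.integer(folds[fm@chain])
  if (any(is.na(rowFold))) .stopf("folds must cover every chain in the matrix")
  k <- attr(folds, "k") %||% max(rowFold)
  acc <- matrix(0, ncol(X), k)
  for (f in seq_len(k)) {
    tr <- rowFold != f
    acc[, f] <- abs(.biserialAll(X[tr, , drop = FALSE], y[tr]))
  }
  avg <- rowMeans(acc)
  ord <- order(-avg, colnames(X))
  structure(data.frame(feature = colnames(X)[ord],
                       meanAbsCorrelation = avg[ord],
                       stringsAsFactors = FALSE),
            class = c("FeatureRanking", "data.frame"))
}

# fit an SVM on training rows and return decision scores oriented so that
# larger = more likely class "1"
.svmDecision <- function(Xtr, ytr, Xte, kernel = "linear", cost = 1,
                         gamma = NULL, degree = 3L, coef0 = 1) {
  yf <- factor(ytr, levels = c("0", "1"))
  args <- list(x = Xtr, y = yf, kernel = kernel, cost = cost, scale = FALSE,
               coef0 = coef0)
  if (!is.null(gamma)) args$gamma <- gamma
  if (kernel == "polynomial") args$degree <- degree
  fit <- do.call(e1071::svm, args)
  pr <- stats::predict(fit, Xte, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  sgn <- if (startsWith(colnames(dv)[1L], "1")) 1 else -1
  as.numeric(dv[, 1L]) * sgn
}

# mean held-out AUC of a feature subset under chain-level CV
.cvAuc <- function(X, y, rowFold, cols, kernel = "linear", cost = 1,
                   gamma = NULL, degree = 3L) {
  k <- max(rowFold)
  aucs <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    te <- rowFold == f
    if (length(unique(y[te])) < 2L || length(unique(y[!te])) < 2L) {
      .warnf("fold %d has a single label class; its AUC is skipped", f)
      next
    }
    dv <- .svmDecision(X[!te, cols, drop = FALSE], y[!te],
                       X[te, cols, drop = FALSE], kernel = kernel,
                       cost = cost, gamma = gamma, degree = degree)
    aucs[f] <- rocAuc(dv, y[te])
  }
  mean(aucs, na.rm = TRUE)
}

#' Best-first forward feature selection under cross-validated AUC
#'
#' A single pass over the ranked feature list: each candidate is added to the
#' selected set, a linear-kernel SVM with cost `C = 1` is evaluated by
#' chain-level cross-validation, and the candidate is retained only when the
#' mean held-out AUC improves strictly (tolerance 1e-6 against float-noise
#' acceptances) over the best so far. The starting baseline is the
#' no-information AUC of 0.5.
#'
#' @param fm a [FeatureMatrix-class] with labels (training chains only).
#' @param folds a [makeFolds()] assignment over the matrix's chains.
#' @param ranking optional [rankFeatures()] result (computed when NULL).
#' @param maxFeatures cap on the number of ranked candidates examined
#'   (default all).
#' @param classifier list with `kernel` and `cost` of the evaluation
#'   classifier (default linear, C = 1).
#' @param tol strict-improvement tolerance (default 1e-6).
#' @return An object of class `SelectionTrace`: list with `selected`
#'   (accepted features in acceptance order), `trace` (data frame: feature,
#'   candidate AUC, accepted flag, best AUC after the decision), `baseline`,
#'   and the fold attributes.
#' @export
bestFirstForward <- function(fm, folds, ranking = NULL, maxFeatures = Inf,
                             classifier = list(kernel = "linear", cost = 1),
                             tol = 1e-6) {
  if (is.null(ranking)) ranking <- rankFeatures(fm, folds)
  X <- fm@features
  y <- fm@labels
  rowFold <- as.integer(folds[fm@chain])
  cand <- utils::head(ranking$feature, maxFeatures)
  selected <- character(0)
  best <- 0.5
  trace <- data.frame(feature = character(0), auc = numeric(0),
                      accepted = logical(0), bestAuc = numeric(0),
                      stringsAsFactors = FALSE)
  for (f in cand) {
    auc <- .cvAuc(X, y, rowFold, c(selected, f),
                  kernel = classifier$kernel %||% "linear",
                  cost = classifier$cost %||% 1)
    ok <- is.finite(auc) && auc > best + tol
    if (ok) {
      selected <- c(selected, f)
      best <- auc
    }
    trace <- rbind(trace, data.frame(feature = f, auc = auc, accepted = ok,
                                     bestAuc = best, stringsAsFactors = FALSE))
  }
  structure(list(selected = selected, trace = trace, baseline = 0.5,
                 finalAuc = best, k = attr(folds, "k"),
                 seed = attr(folds, "seed")),
            class = "SelectionTrace")
}

#' @export
print.SelectionTrace <- function(x, ...) {
  cat(sprintf("SelectionTrace: %d of %d candidates accepted; CV AUC %.4f (baseline %.2f)\n",
              length(x$selected), nrow(x$trace), x$finalAuc, x$baseline))
  invisible(x)
}
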