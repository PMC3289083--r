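# SVM training, kernel/cost parameterization, probability calibration and
# threshold calibration.
#
# Probabilities are obtained by a Platt-type sigmoid: a binomial glm of the
# labels on cross-validated SVM decision values. This is the same sigmoid
# libsvm fits internally for its probability outputs, but fitted explicitly
# here so the whole pipeline is deterministic under a fixed seed.

#' Default parameter grids for SVM parameterization
#'
#' Cost values are consecutive powers of 2 between 2^-3 and 2^5. The
#' polynomial degree grid is the integer range 1..5 (the backend's polynomial
#' degree is integral). The RBF gamma grid defaults to powers of 2 in
#' \[2^-7, 2^1\].
#'
#' @return List with elements `degree`, `gamma`, `cost`.
#' @export
svmGrids <- function() {
  list(degree = 1:5, gamma = 2^seq(-7, 1), cost = 2^seq(-3, 5))
}

#' Two-stage SVM kernel and cost parameterization
#'
#' For each kernel the shape parameter is swept first at `C = 1` (degree for
#' the polynomial kernel, gamma for RBF), then the cost is swept with the
#' chosen shape. Every candidate is scored by mean held-out AUC under the
#' given chain-level folds; the kernel with the best AUC wins, ties broken by
#' the order of `kernels`. The full search log is retained.
#'
#' @param fm a labeled [FeatureMatrix-class] (training chains only).
#' @param folds a [makeFolds()] assignment over its chains.
#' @param features feature columns to use (default all).
#' @param kernels kernels to try, in tie-break order.
#' @param grids parameter grids, see [svmGrids()].
#' @return An object of class `ParamSearch`: list with `kernel`, `params`
#'   (named list with `cost` and `degree`/`gamma`), `auc`, and `log` (data
#'   frame of every evaluation).
#' @export
svmParameterize <- function(fm, folds, features = NULL,
                            kernels = c("polynomial", "radial"),
                            grids = svmGrids()) {
  X <- fm@features
  if (any(!is.finite(X))) .stopf("feature matrix contains non-finite values")
  if (is.null(features)) features <- colnames(X)
  y <- fm@labels
  rowFold <- as.integer(folds[fm@chain])
  log <- data.frame(kernel = character(0), stage = character(0),
                    shape = numeric(0), cost = numeric(0), auc = numeric(0),
                    stringsAsFactors = FALSE)
  best <- list(auc = -Inf)
  for (kern in kernels) {
    shapeGrid <- if (kern == "polynomial") grids$degree else grids$gamma
    shapeName <- if (kern == "polynomial") "degree" else "gamma"
    shapeAuc <- vapply(shapeGrid, function(s) {
      .cvAuc(X, y, rowFold, features, kernel = kern, cost = 1,
             gamma = if (kern == "radial") s else 1 / length(features),
             degree = if (kern == "polynomial") s else 3L)
    }, numeric(1))
    log <- rbind(log, data.frame(kernel = kern, stage = shapeName,
                                 shape = shapeGrid, cost = 1, auc = shapeAuc,
                                 stringsAsFactors = FALSE))
    shape <- shapeGrid[which.max(shapeAuc)]
    costAuc <- vapply(grids$cost, function(co) {
      .cvAuc(X, y, rowFold, features, kernel = kern, cost = co,
             gamma = if (kern == "radial") shape else 1 / length(features),
             degree = if (kern == "polynomial") shape else 3L)
    }, numeric(1))
    log <- rbind(log, data.frame(kernel = kern, stage = "cost",
                                 shape = shape, cost = grids$cost,
                                 auc = costAuc, stringsAsFactors = FALSE))
    kBest <- max(costAuc)
    if (kBest > best$auc) {
      params <- list(cost = grids$cost[which.max(costAuc)])
      params[[shapeName]] <- shape
      best <- list(kernel = kern, params = params, auc = kBest)
    }
  }
  structure(c(best, list(log = log)), class = "ParamSearch")
}

#' @export
print.ParamSearch <- function(x, ...) {
  ps <- paste(sprintf("%s=%g", names(x$params), unlist(x$params)), collapse = ", ")
  cat(sprintf("ParamSearch: kernel %s (%s), CV AUC %.4f over %d evaluations\n",
              x$kernel, ps, x$auc, nrow(x$log)))
  invisible(x)
}

# exhaustive MCC-maximizing threshold scan over the unique probabilities
# (>= convention; smallest maximizer on ties)
.mccThresholdScan <- function(p, y) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) return(list(threshold = NA_real_, mcc = NA_real_))
  cand <- sort(unique(p))
  ord <- order(p, decreasing = TRUE)
  ps <- p[ord]; ys <- y[ord]
  nPos <- sum(ys == 1L); nNeg <- sum(ys == 0L)
  # at threshold t, predictions are p >= t: counts via cumulative sums over
  # the descending order, evaluated at the last index of each unique value
  tp <- cumsum(as.numeric(ys == 1L)); fp <- cumsum(as.numeric(ys == 0L))
  idx <- length(ps) + 1L - match(cand, rev(ps))     # last occurrence
  TP <- tp[idx]; FP <- fp[idx]
  FN <- nPos - TP; TN <- nNeg - FP
  den <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  mcc <- ifelse(den == 0, 0, (TP * TN - FP * FN) / den)
  bestIdx <- which(mcc == max(mcc))
  bi <- bestIdx[which.min(cand[bestIdx])]
  list(threshold = cand[bi], mcc = mcc[bi])
}

#' Calibrate the binarization threshold from per-fold probabilities
#'
#' For each fold, the unique predicted probabilities are scanned as candidate
#' thresholds under the `>=` convention and the MCC-maximizing one is taken
#' (smallest on ties); the calibrated threshold is the mean of the per-fold
#' maximizers. Folds with a single label class are skipped with a warning.
#'
#' @param foldProbs list of per-fold probability vectors.
#' @param foldLabels list of matching 0/1 label vectors.
#' @return List with `threshold` (the mean), `perFold` (the per-fold
#'   maximizers) and `mcc` (per-fold maximal MCC).
#' @export
calibrateThreshold <- function(foldProbs, foldLabels) {
  stopifnot(length(foldProbs) == length(foldLabels))
  thr <- rep(NA_real_, length(foldProbs))
  mcc <- rep(NA_real_, length(foldProbs))
  for (f in seq_along(foldProbs)) {
    scan <- .mccThresholdScan(foldProbs[[f]], foldLabels[[f]])
    if (is.na(scan$threshold)) {
      .warnf("fold %d has a single label class; skipped in threshold calibration", f)
      next
    }
    thr[f] <- scan$threshold
    mcc[f] <- scan$mcc
  }
  if (all(is.na(thr))) .stopf("no fold admitted a threshold")
  list(threshold = mean(thr, na.rm = TRUE), perFold = thr, mcc = mcc)
}

# fit the final SVM plus its Platt sigmoid from cross-validated decision
# values; returns the pieces used by trainBindingModel
.fitSvmWithPlatt <- function(X, y, rowFold, kernel, params) {
  k <- max(rowFold)
  cvDv <- rep(NA_real_, length(y))
  for (f in seq_len(k)) {
    te <- rowFold == f
    if (length(unique(y[!te])) < 2L) next
    cvDv[te] <- .svmDecision(X[!te, , drop = FALSE], y[!te],
                             X[te, , drop = FALSE], kernel = kernel,
                             cost = params$cost %||% 1,
                             gamma = params$gamma,
                             degree = params$degree %||% 3L)
  }
  ok <- !is.na(cvDv)
  platt <- .plattFit(cvDv[ok], y[ok])
  yf <- factor(y, levels = c("0", "1"))
  args <- list(x = X, y = yf, kernel = kernel, cost = params$cost %||% 1,
               scale = FALSE, coef0 = 1)
  if (!is.null(params$gamma)) args$gamma <- params$gamma
  if (kernel == "polynomial") args$degree <- params$degree %||% 3L
  fit <- do.call(e1071::svm, args)
  list(fit = fit, platt = platt, cvDv = cvDv, cvProb = .plattApply(platt, cvDv))
}

.plattFit <- function(dv, y) {
  df <- data.frame(dv = dv, y = as.integer(y))
  co <- suppressWarnings(
    stats::glm(y ~ dv, family = stats::binomial(), data = df,
               control = list(maxit = 100))$coefficients)
  co[!is.finite(co)] <- 0
  stats::setNames(as.numeric(co), c("a", "b"))
}

.plattApply <- function(platt, dv) stats::plogis(platt[["a"]] + platt[["b"]] * dv)

#' Train the per-residue binding predictor
#'
#' Fits the SVM on the selected features, derives the Platt probability
#' sigmoid from chain-level cross-validated decision values, and calibrates
#' the MCC-maximizing binarization threshold on the cross-validated (held
#' out within training data) probabilities of each fold.
#'
#' @param fm a labeled [FeatureMatrix-class] of training residues.
#' @param folds a [makeFolds()] assignment over its chains.
#' @param features feature columns the model consumes.
#' @param kernel `"linear"`, `"polynomial"` or `"radial"`.
#' @param params named list of kernel parameters (`cost`, and `gamma` or
#'   `degree`); `gamma` defaults to `1/length(features)` for RBF.
#' @param seed integer recorded in the model metadata.
#' @return A [TrainedModel-class].
#' @export
trainBindingModel <- function(fm, folds, features = NULL, kernel = "radial",
                              params = list(cost = 1), seed = NA_integer_) {
  if (is.null(features)) features <- colnames(fm@features)
  miss <- setdiff(features, colnames(fm@features))
  if (length(miss))
    .stopf("training matrix lacks feature column(s): %s",
           paste(utils::head(miss, 5L), collapse = ", "))
  X <- fm@features[, features, drop = FALSE]
  y <- fm@labels
  if (any(is.na(y))) .stopf("training requires labeled rows")
  rowFold <- as.integer(folds[fm@chain])
  if (kernel == "radial" && is.null(params$gamma))
    params$gamma <- 1 / length(features)
  parts <- .fitSvmWithPlatt(X, y, rowFold, kernel, params)
  k <- max(rowFold)
  foldProbs <- lapply(seq_len(k), function(f) parts$cvProb[rowFold == f])
  foldLabels <- lapply(seq_len(k), function(f) y[rowFold == f])
  ok <- !vapply(foldProbs, function(p) all(is.na(p)), logical(1))
  cal <- calibrateThreshold(foldProbs[ok], foldLabels[ok])
  new("TrainedModel", fit = parts$fit, platt = parts$platt,
      featureNames = features, threshold = cal$threshold,
      config = list(kernel = kernel, params = params,
                    k = attr(folds, "k"), seed = seed,
                    thresholdPerFold = cal$perFold))
}

#' Predict per-residue binding probabilities
#'
#' Decision values of the fitted SVM are mapped through the model's Platt
#' sigmoid; a residue is called binding when its probability is greater than
#' or equal to the model threshold.
#'
#' @param model a [TrainedModel-class].
#' @param fm a [FeatureMatrix-class] whose columns cover the model's
#'   features; extra columns are ignored, missing columns are an error
#'   listing them.
#' @return Named list of [PredictionTrack-class], one per chain in `fm`;
#'   chains without sequences recorded get the residue letters `X`.
#' @param sequences optional named list of chain sequences for the tracks.
#' @export
predictBinding <- function(model, fm, sequences = NULL) {
  have <- colnames(fm@features)
  miss <- setdiff(model@featureNames, have)
  extra <- setdiff(have, model@featureNames)
  if (length(miss))
    .stopf("feature matrix is missing model column(s): %s%s",
           paste(utils::head(miss, 8L), collapse = ", "),
           if (length(extra)) sprintf(" (extra columns present: %s)",
                                      paste(utils::head(extra, 4L), collapse = ", ")) else "")
  X <- fm@features[, model@featureNames, drop = FALSE]
  pr <- stats::predict(model@fit, X, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  sgn <- if (startsWith(colnames(dv)[1L], "1")) 1 else -1
  prob <- .plattApply(model@platt, as.numeric(dv[, 1L]) * sgn)
  call <- as.integer(prob >= model@threshold)
  out <- list()
  for (id in unique(fm@chain)) {
    rows <- fm@chain == id
    seqStr <- if (!is.null(sequences) && !is.null(sequences[[id]]))
      as.character(sequences[[id]]) else strrep("X", sum(rows))
    out[[id]] <- predictionTrack(id, seqStr, prob[rows], call[rows],
                                 threshold = model@threshold, method = "svm")
  }
  out
}

#' Persist a trained model to disk
#'
#' Writes the serialized model next to a human-readable JSON sidecar holding
#' the feature names, threshold and training configuration.
#'
#' @param model a [TrainedModel-class].
#' @param path output path (`.rds`); the sidecar is `<path>.json`.
#' @return Invisibly, `path`.
#' @export
saveBindingModel <- function(model, path) {
  saveRDS(model, path)
  sidecar <- list(featureNames = model@featureNames,
                  threshold = model@threshold, config = model@config,
                  package = "ATPbindR", formatVersion = 1L)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a model saved by [saveBindingModel()]
#'
#' @param path path to the `.rds` archive.
#' @return A [TrainedModel-class].
#' @export
loadBindingModel <- function(path) {
  model <- readRDS(path)
  if (!is(model, "TrainedModel")) .stopf("%s does not hold a TrainedModel", path)
  model
}
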