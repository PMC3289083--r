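# Per-residue and per-sequence evaluation: confusion measures, threshold-
# sweep ROC/AUC, paired per-sequence significance tests and confidence bins.

#' Confusion counts and binary classification measures
#'
#' `SENS = TP/(TP+FN)`, `SPEC = TN/(TN+FP)`, `ACC = (TP+TN)/n` and the
#' Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with the
#' convention that MCC is 0 whenever a factor of the denominator vanishes
#' (e.g. all residues predicted binding or non-binding).
#'
#' @param calls 0/1 predicted calls.
#' @param labels 0/1 reference labels of the same length.
#' @return Named numeric vector with `TP`, `TN`, `FP`, `FN`, `SENS`, `SPEC`,
#'   `ACC`, `MCC`. SENS/SPEC are NA when their class is absent.
#' @export
confusionMetrics <- function(calls, labels) {
  if (length(calls) != length(labels)) .stopf("calls and labels differ in length")
  calls <- as.integer(calls); labels <- as.integer(labels)
  TP <- sum(calls == 1L & labels == 1L)
  TN <- sum(calls == 0L & labels == 0L)
  FP <- sum(calls == 1L & labels == 0L)
  FN <- sum(calls == 0L & labels == 1L)
  sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  spec <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  acc <- (TP + TN) / length(labels)
  # counts go to double before the product to dodge integer overflow
  den <- prod(as.numeric(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  mcc <- if (den == 0) 0 else (TP * TN - FP * FN) / sqrt(den)
  c(TP = TP, TN = TN, FP = FP, FN = FN,
    SENS = sens, SPEC = spec, ACC = acc, MCC = mcc)
}

#' Threshold-sweep ROC curve and AUC
#'
#' Sweeps every unique probability (plus a supra-maximal point giving
#' (0, 0)) as a threshold under the `>=` convention: residues with score at
#' least the threshold are called binding, and the TP-rate and FP-rate are
#' recorded. Tied scores share a single threshold point. The AUC is the
#' trapezoidal area under the resulting step curve, which equals the
#' tie-corrected rank-sum (Mann-Whitney) statistic divided by `n1 * n0`.
#'
#' @param scores numeric prediction scores (probabilities or any monotone
#'   transform of them).
#' @param labels 0/1 labels; both classes must be present.
#' @return An object of class `ROCCurve`: list with `points` (data frame of
#'   threshold, fpr, tpr, from (0,0) to (1,1)) and `auc`.
#' @export
rocCurve <- function(scores, labels) {
  if (length(scores) != length(labels)) .stopf("scores and labels differ in length")
  labels <- as.integer(labels)
  nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
  if (nPos == 0L || nNeg == 0L)
    .stopf("ROC requires at least one positive and one negative label")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y == 1L); fp <- cumsum(y == 0L)
  last <- cumsum(rle(s)$lengths)      # one point per unique score
  pts <- data.frame(threshold = c(Inf, s[last]),
                    fpr = c(0, fp[last] / nNeg),
                    tpr = c(0, tp[last] / nPos))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "ROCCurve")
}

#' @export
print.ROCCurve <- function(x, ...) {
  cat(sprintf("ROCCurve: AUC %.4f over %d threshold points\n",
              x$auc, nrow(x$points)))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Convenience wrapper around [rocCurve()] returning only the AUC.
#'
#' @inheritParams rocCurve
#' @return AUC in \[0, 1\].
#' @export
rocAuc <- function(scores, labels) rocCurve(scores, labels)$auc

# paired two-sided Wilcoxon signed-rank; all-zero differences sit exactly at
# the null center (statistic 0, p = 1)
.pairedWilcoxon <- function(a, b) {
  d <- a - b
  if (all(d == 0))
    return(list(statistic = 0, p.value = 1, n = length(d)))
  wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value, n = length(d))
}

#' Compare two methods by per-sequence MCC and AUC
#'
#' Computes MCC and AUC per chain for both methods from their prediction
#' tracks, then compares the paired per-chain values with a two-sided
#' Wilcoxon signed-rank test (the paired analog of the rank-sum test) and
#' reports Shapiro-Wilk normality checks of each metric vector — the
#' non-parametric test is motivated by these typically rejecting normality.
#' Chains where a metric is undefined for either method (single-class
#' chains, binary-only probabilities) are dropped pairwise with counts
#' recorded.
#'
#' @param tracksA,tracksB named lists of [PredictionTrack-class] covering the
#'   same chains.
#' @param chains named list of [LabeledChain-class] with the reference labels.
#' @param alpha significance level recorded in the report (default 0.01).
#' @param minPairs minimum complete pairs for a test (default 6; below it the
#'   test is skipped with a warning).
#' @return An object of class `PerSequenceStats`: list with `perChain` (data
#'   frame of per-chain MCC/AUC for both methods), `tests` (per metric:
#'   statistic, p.value, n, dropped), `normality` (Shapiro-Wilk p-values),
#'   `alpha`.
#' @export
perSequenceCompare <- function(tracksA, tracksB, chains, alpha = 0.01,
                               minPairs = 6L) {
  ids <- intersect(names(chains), intersect(names(tracksA), names(tracksB)))
  if (!length(ids)) .stopf("no common chains between the two methods")
  one <- function(track, chain) {
    y <- chain@labels
    mcc <- unname(confusionMetrics(track@call, y)["MCC"])
    auc <- if (length(unique(y)) < 2L || all(is.na(track@probability)))
      NA_real_ else rocAuc(track@probability, y)
    c(mcc = mcc, auc = auc)
  }
  a <- t(vapply(ids, function(i) one(tracksA[[i]], chains[[i]]), numeric(2)))
  b <- t(vapply(ids, function(i) one(tracksB[[i]], chains[[i]]), numeric(2)))
  perChain <- data.frame(chain = ids,
                         mccA = a[, "mcc"], mccB = b[, "mcc"],
                         aucA = a[, "auc"], aucB = b[, "auc"],
                         stringsAsFactors = FALSE)
  runTest <- function(xa, xb, what) {
    ok <- stats::complete.cases(xa, xb)
    dropped <- sum(!ok)
    if (sum(ok) < minPairs) {
      .warnf("%s: only %d complete pairs (< %d); paired test skipped",
             what, sum(ok), minPairs)
      return(list(statistic = NA_real_, p.value = NA_real_, n = sum(ok),
                  dropped = dropped))
    }
    c(.pairedWilcoxon(xa[ok], xb[ok]), list(dropped = dropped))
  }
  shap <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 3L || length(unique(x)) < 2L) return(NA_real_)
    tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
  }
  structure(list(
    perChain = perChain,
    tests = list(MCC = runTest(perChain$mccA, perChain$mccB, "MCC"),
                 AUC = runTest(perChain$aucA, perChain$aucB, "AUC")),
    normality = c(mccA = shap(perChain$mccA), mccB = shap(perChain$mccB),
                  aucA = shap(perChain$aucA), aucB = shap(perChain$aucB)),
    alpha = alpha), class = "PerSequenceStats")
}

#' @export
print.PerSequenceStats <- function(x, ...) {
  cat(sprintf("PerSequenceStats over %d chains (alpha = %g)\n",
              nrow(x$perChain), x$alpha))
  for (m in names(x$tests)) {
    t <- x$tests[[m]]
    cat(sprintf("  %s: signed-rank p = %s over %d pairs (%d dropped)\n", m,
                format(t$p.value, digits = 4), t$n, t$dropped))
  }
  invisible(x)
}

#' Bin predictions by probability and report per-bin accuracy
#'
#' Residues are binned into `1/width` half-open probability intervals
#' \[0, width), ..., with the final bin closed at 1. Per bin, the accuracy of
#' the binary calls and the fraction of residues falling in the bin are
#' reported; empty bins have NA accuracy.
#'
#' @param probabilities per-residue probabilities in \[0, 1\].
#' @param calls matching 0/1 calls.
#' @param labels matching 0/1 labels.
#' @param width bin width (default 0.05, i.e. twenty bins).
#' @return Data frame with `bin`, `lower`, `upper`, `n`, `fraction`,
#'   `accuracy`.
#' @export
confidenceBins <- function(probabilities, calls, labels, width = 0.05) {
  stopifnot(length(probabilities) == length(calls),
            length(calls) == length(labels))
  if (any(probabilities < 0 | probabilities > 1, na.rm = TRUE))
    .stopf("probabilities must lie in [0,1]")
  nb <- as.integer(round(1 / width))
  # round before floor so boundary values (e.g. 0.95/0.05) open the right bin
  idx <- pmin(floor(round(probabilities / width, 9)) + 1L, nb)
  correct <- as.integer(calls) == as.integer(labels)
  n <- tabulate(idx, nbins = nb)
  acc <- vapply(seq_len(nb), function(b)
    if (n[b] > 0L) mean(correct[idx == b]) else NA_real_, numeric(1))
  data.frame(bin = seq_len(nb), lower = (seq_len(nb) - 1L) * width,
             upper = pmin(seq_len(nb) * width, 1),
             n = n, fraction = n / length(probabilities), accuracy = acc)
}

#' Evaluate prediction tracks against reference labels
#'
#' Pools all residues for residue-level metrics (confusion measures at the
#' tracks' calls plus threshold-sweep AUC where probabilities exist) and also
#' reports per-chain MCC/AUC, since pooled and per-chain-averaged summaries
#' can differ.
#'
#' @param tracks named list of [PredictionTrack-class].
#' @param chains named list of [LabeledChain-class] with reference labels.
#' @return An object of class `EvalReport`: list with `pooled` (confusion
#'   measures and AUC), `perChain` (data frame), `n` (residues evaluated).
#' @export
evaluateTracks <- function(tracks, chains) {
  ids <- intersect(names(tracks), names(chains))
  if (!length(ids)) .stopf("no overlapping chains to evaluate")
  calls <- unlist(lapply(ids, function(i) tracks[[i]]@call))
  labels <- unlist(lapply(ids, function(i) chains[[i]]@labels))
  probs <- unlist(lapply(ids, function(i) tracks[[i]]@probability))
  pooled <- as.list(confusionMetrics(calls, labels))
  pooled$AUC <- if (all(is.na(probs)) || length(unique(labels)) < 2L)
    NA_real_ else rocAuc(probs[!is.na(probs)], labels[!is.na(probs)])
  perChain <- do.call(rbind, lapply(ids, function(i) {
    y <- chains[[i]]@labels
    m <- confusionMetrics(tracks[[i]]@call, y)
    auc <- if (length(unique(y)) < 2L || all(is.na(tracks[[i]]@probability)))
      NA_real_ else rocAuc(tracks[[i]]@probability, y)
    data.frame(chain = i, MCC = unname(m["MCC"]), AUC = auc,
               SENS = unname(m["SENS"]), SPEC = unname(m["SPEC"]),
               stringsAsFactors = FALSE)
  }))
  structure(list(pooled = pooled, perChain = perChain, n = length(labels)),
            class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf("EvalReport: %d residues, %d chains\n", x$n, nrow(x$perChain)))
  cat(sprintf("  pooled: AUC %s  MCC %.3f  SENS %.3f  SPEC %.3f  ACC %.3f\n",
              ifelse(is.na(x$pooled$AUC), "NA", sprintf("%.3f", x$pooled$AUC)),
              x$pooled$MCC, x$pooled$SENS, x$pooled$SPEC, x$pooled$ACC))
  invisible(x)
}
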