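# Accessor generics and show methods.

#' @name accessors
#' @title Accessors for the package's S4 containers
#'
#' @description `chainId()` returns the chain identifier; `chainSequence()`
#' the amino-acid sequence; `bindingLabels()` the 0/1 label vector;
#' `probabilities()` and `bindingCalls()` the per-residue probabilities and
#' binary calls of a [PredictionTrack-class]; `threshold()` the binarization
#' threshold; `featureValues()`, `featureGroups()` and `featureLabels()` the
#' matrix, column groups and row labels of a [FeatureMatrix-class].
#'
#' @param x an object of the documented classes.
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("chainId", function(x) standardGeneric("chainId"))
#' @rdname accessors
#' @export
setGeneric("chainSequence", function(x) standardGeneric("chainSequence"))
#' @rdname accessors
#' @export
setGeneric("bindingLabels", function(x) standardGeneric("bindingLabels"))
#' @rdname accessors
#' @export
setGeneric("probabilities", function(x) standardGeneric("probabilities"))
#' @rdname accessors
#' @export
setGeneric("bindingCalls", function(x) standardGeneric("bindingCalls"))
#' @rdname accessors
#' @export
setGeneric("threshold", function(x) standardGeneric("threshold"))
#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("featureGroups", function(x) standardGeneric("featureGroups"))
#' @rdname accessors
#' @export
setGeneric("featureLabels", function(x) standardGeneric("featureLabels"))

#' @rdname accessors
#' @export
setMethod("chainId", "LabeledChain", function(x) x@chainId)
#' @rdname accessors
#' @export
setMethod("chainId", "ProfileBundle", function(x) x@chainId)
#' @rdname accessors
#' @export
setMethod("chainId", "PredictionTrack", function(x) x@chainId)
#' @rdname accessors
#' @export
setMethod("chainId", "PSSMProfile", function(x) x@chainId)

#' @rdname accessors
#' @export
setMethod("chainSequence", "LabeledChain", function(x) x@sequence)
#' @rdname accessors
#' @export
setMethod("chainSequence", "ProfileBundle", function(x) x@sequence)
#' @rdname accessors
#' @export
setMethod("chainSequence", "PredictionTrack", function(x) x@sequence)

#' @rdname accessors
#' @export
setMethod("bindingLabels", "LabeledChain", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("probabilities", "PredictionTrack", function(x) x@probability)
#' @rdname accessors
#' @export
setMethod("bindingCalls", "PredictionTrack", function(x) x@call)
#' @rdname accessors
#' @export
setMethod("threshold", "PredictionTrack", function(x) x@threshold)
#' @rdname accessors
#' @export
setMethod("threshold", "TrainedModel", function(x) x@threshold)

#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@features)
#' @rdname accessors
#' @export
setMethod("featureGroups", "FeatureMatrix", function(x) x@groups)
#' @rdname accessors
#' @export
setMethod("featureLabels", "FeatureMatrix", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("chainId", "FeatureMatrix", function(x) x@chain)

setMethod("show", "LabeledChain", function(object) {
  cat(sprintf("LabeledChain %s: %d residues, %d binding (source: %s)\n",
              object@chainId, nchar(object@sequence), sum(object@labels),
              object@source))
})

setMethod("show", "PSSMProfile", function(object) {
  cat(sprintf("PSSMProfile %s: %d positions x 20 columns%s\n",
              object@chainId, length(object@residues),
              if (isTRUE(object@degraded)) " (frequencies derived from log-odds)" else ""))
})

setMethod("show", "ProfileBundle", function(object) {
  have <- c(
    pssm = length(object@pssm@residues) > 0,
    ss3 = nrow(object@ss3) > 0, rsa = length(object@rsa) > 0,
    dihedral = length(object@phi) > 0,
    conservation = length(object@conservation) > 0)
  cat(sprintf("ProfileBundle %s: %d residues; tracks: %s\n", object@chainId,
              nchar(object@sequence),
              paste(names(have)[have], collapse = ", ")))
})

setMethod("show", "FeatureMatrix", function(object) {
  g <- table(factor(object@groups, levels = unique(object@groups)))
  cat(sprintf("FeatureMatrix: %d residues (%d chains) x %d features\n",
              nrow(object@features), length(unique(object@chain)),
              ncol(object@features)))
  cat("  groups:", paste(sprintf("%s=%d", names(g), as.integer(g)),
                         collapse = " "), "\n")
})

setMethod("show", "PredictionTrack", function(object) {
  cat(sprintf("PredictionTrack %s [%s]: %d residues, %d called binding (threshold %s)\n",
              object@chainId, object@method, nchar(object@sequence),
              sum(object@call),
              ifelse(is.na(object@threshold), "none",
                     format(object@threshold, digits = 4))))
})

setMethod("show", "TrainedModel", function(object) {
  cat(sprintf("TrainedModel: %s kernel, %d features, threshold %.4f\n",
              object@config$kernel %||% "?", length(object@featureNames),
              object@threshold))
})

#' Stack per-chain FeatureMatrix objects row-wise
#'
#' All inputs must share identical feature columns and groups.
#'
#' @param fms list of [FeatureMatrix-class] objects.
#' @return A single [FeatureMatrix-class].
#' @export
bindFeatureMatrices <- function(fms) {
  stopifnot(length(fms) >= 1L)
  ref <- colnames(fms[[1L]]@features)
  for (fm in fms[-1L])
    if (!identical(colnames(fm@features), ref))
      .stopf("feature matrices have differing columns and cannot be stacked")
  new("FeatureMatrix",
      features = do.call(rbind, lapply(fms, function(f) f@features)),
      chain = unlist(lapply(fms, function(f) f@chain), use.names = FALSE),
      position = unlist(lapply(fms, function(f) f@position), use.names = FALSE),
      labels = unlist(lapply(fms, function(f) f@labels), use.names = FALSE),
      groups = fms[[1L]]@groups)
}

#' Subset a FeatureMatrix by rows and/or feature columns
#'
#' @param fm a [FeatureMatrix-class].
#' @param rows row index (logical or integer); default all.
#' @param columns column names or index; default all.
#' @return A [FeatureMatrix-class].
#' @export
subsetFeatureMatrix <- function(fm, rows = NULL, columns = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(fm@features))
  if (is.null(columns)) columns <- colnames(fm@features)
  feat <- fm@features[rows, columns, drop = FALSE]
  new("FeatureMatrix", features = feat, chain = fm@chain[rows],
      position = fm@position[rows], labels = fm@labels[rows],
      groups = fm@groups[colnames(feat)])
}
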