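# S4 containers for the per-chain data model.

#' PSSMProfile: per-residue evolutionary profile of one chain
#'
#' Holds the raw log-odds block and the weighted observed frequency block of a
#' PSI-BLAST ASCII position-specific scoring matrix, row-checked against the
#' chain sequence. When a matrix file lacks the frequency block the
#' frequencies are derived from the log-odds by the logistic transform and
#' renormalization, and `degraded` is set.
#'
#' @slot chainId chain identifier.
#' @slot residues per-row residue letters (length L).
#' @slot logOdds L x 20 raw log-odds matrix, columns in [aaAlphabet()] order.
#' @slot freqs L x 20 per-position amino-acid frequency matrix, rows sum to 1.
#' @slot degraded TRUE when frequencies were derived rather than read.
#' @exportClass PSSMProfile
setClass("PSSMProfile",
  representation(chainId = "character", residues = "character",
                 logOdds = "matrix", freqs = "matrix", degraded = "logical"))

setValidity("PSSMProfile", function(object) {
  L <- length(object@residues)
  if (nrow(object@logOdds) != L || nrow(object@freqs) != L)
    return("logOdds/freqs row count must equal the number of residues")
  if (ncol(object@logOdds) != 20L || ncol(object@freqs) != 20L)
    return("logOdds/freqs must have 20 columns")
  if (any(!is.finite(object@logOdds)) || any(!is.finite(object@freqs)))
    return("profile values must be finite")
  if (L && any(abs(rowSums(object@freqs) - 1) > 1e-6))
    return("frequency rows must sum to 1")
  TRUE
})

#' LabeledChain: a protein chain with per-residue binding labels
#'
#' @slot chainId chain identifier.
#' @slot sequence amino-acid sequence (20 standard letters plus X).
#' @slot labels integer vector of 0/1 binding labels, one per residue.
#' @slot source provenance of the labels (e.g. a structure id).
#' @exportClass LabeledChain
setClass("LabeledChain",
  representation(chainId = "character", sequence = "character",
                 labels = "integer", source = "character"))

setValidity("LabeledChain", function(object) {
  if (length(object@sequence) != 1L || !nzchar(object@sequence))
    return("sequence must be a non-empty string")
  if (nchar(object@sequence) != length(object@labels))
    return("label length must equal sequence length")
  if (any(!object@labels %in% c(0L, 1L)))
    return("labels must be 0/1")
  bad <- setdiff(unique(.seqLetters(object@sequence)), c(AA20, "X"))
  if (length(bad))
    return(sprintf("illegal sequence letters: %s", paste(bad, collapse = ",")))
  TRUE
})

#' ProfileBundle: all per-residue input tracks for one chain
#'
#' Groups the external per-residue predictions consumed by the feature
#' encoder: the evolutionary profile, three-state secondary-structure
#' probabilities, relative solvent accessibility, backbone dihedrals and
#' (optionally) a conservation score track. Optional tracks are stored empty
#' (length 0 / 0 rows) until read.
#'
#' @slot chainId chain identifier.
#' @slot sequence amino-acid sequence.
#' @slot pssm a [PSSMProfile-class] (0-row when absent).
#' @slot ss3 L x 3 matrix of helix/strand/coil probabilities (columns H, E, C).
#' @slot rsa relative solvent accessibility in \[0, 1\], length L.
#' @slot phi,psi backbone dihedral angles in degrees, \[-180, 180\], length L.
#' @slot conservation external per-residue conservation scores (may be empty).
#' @slot consLowIsConserved TRUE when a lower conservation score means a more
#'   conserved residue (the rate4site convention).
#' @exportClass ProfileBundle
setClass("ProfileBundle",
  representation(chainId = "character", sequence = "character",
                 pssm = "PSSMProfile", ss3 = "matrix", rsa = "numeric",
                 phi = "numeric", psi = "numeric", conservation = "numeric",
                 consLowIsConserved = "logical"))

setValidity("ProfileBundle", function(object) {
  L <- nchar(object@sequence)
  chk <- function(len, what)
    if (len && len != L) sprintf("%s length (%d) != sequence length (%d)", what, len, L) else NULL
  errs <- c(
    chk(length(object@pssm@residues), "pssm"),
    chk(nrow(object@ss3), "ss3"),
    chk(length(object@rsa), "rsa"),
    chk(length(object@phi), "phi"),
    chk(length(object@psi), "psi"),
    chk(length(object@conservation), "conservation"))
  if (length(errs)) return(errs[[1L]])
  if (nrow(object@ss3)) {
    if (!identical(colnames(object@ss3), c("H", "E", "C")))
      return("ss3 columns must be H, E, C")
    if (any(object@ss3 < 0 | object@ss3 > 1))
      return("ss3 probabilities must lie in [0,1]")
  }
  if (length(object@rsa) && any(object@rsa < 0 | object@rsa > 1))
    return("rsa values must lie in [0,1]")
  if (length(object@phi) && any(abs(object@phi) > 180))
    return("phi values must lie in [-180,180]")
  if (length(object@psi) && any(abs(object@psi) > 180))
    return("psi values must lie in [-180,180]")
  TRUE
})

#' FeatureMatrix: per-residue feature vectors with named feature groups
#'
#' Rows are residues (possibly from several chains), columns are named
#' features, each assigned to a feature group (`pssm`, `pss`, `rsa`,
#' `dihedral`, `aagroup`, `terminal`, `segment`, `consA`, `consB`, `consC`,
#' `colloc`).
#'
#' @slot features numeric matrix, one row per residue.
#' @slot chain chain id of each row.
#' @slot position 1-based residue position of each row within its chain.
#' @slot labels 0/1 binding label per row (NA when unlabeled).
#' @slot groups feature-group name of each column, named by column.
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
  representation(features = "matrix", chain = "character",
                 position = "integer", labels = "integer", groups = "character"))

setValidity("FeatureMatrix", function(object) {
  n <- nrow(object@features)
  if (length(object@chain) != n || length(object@position) != n ||
      length(object@labels) != n)
    return("chain/position/labels must have one entry per row")
  if (length(object@groups) != ncol(object@features))
    return("groups must have one entry per column")
  if (!identical(names(object@groups), colnames(object@features)))
    return("groups must be named by the feature columns")
  if (any(!is.finite(object@features)))
    return("feature values must be finite")
  TRUE
})

#' PredictionTrack: per-residue predictions for one chain
#'
#' @slot chainId chain identifier.
#' @slot sequence amino-acid sequence of the chain.
#' @slot probability per-residue binding probability in \[0, 1\]; all-NA for
#'   purely binary predictors (alignment transfer).
#' @slot call per-residue binary call (1 = predicted ATP-binding).
#' @slot threshold the probability threshold used for binarization (NA when
#'   calls do not come from thresholding).
#' @slot method short tag of the generating method.
#' @slot meta free-form metadata (e.g. `noHit` flag of alignment transfer).
#' @exportClass PredictionTrack
setClass("PredictionTrack",
  representation(chainId = "character", sequence = "character",
                 probability = "numeric", call = "integer",
                 threshold = "numeric", method = "character", meta = "list"))

setValidity("PredictionTrack", function(object) {
  L <- nchar(object@sequence)
  if (length(object@probability) != L || length(object@call) != L)
    return("probability/call length must equal sequence length")
  if (any(!object@call %in% c(0L, 1L)))
    return("calls must be 0/1")
  p <- object@probability
  if (any(!is.na(p) & (p < 0 | p > 1)))
    return("probabilities must lie in [0,1]")
  TRUE
})

#' TrainedModel: a fitted per-residue SVM predictor
#'
#' Bundles the fitted support-vector classifier, the Platt-type sigmoid that
#' maps its decision values to probabilities, the selected feature columns and
#' the calibrated binarization threshold.
#'
#' @slot fit fitted `e1071::svm` object.
#' @slot platt intercept and slope of the logistic calibration of decision
#'   values (named `a`, `b`; probability = plogis(a + b * decision)).
#' @slot featureNames feature columns the model consumes, in order.
#' @slot threshold binarization threshold in \[0, 1\] (the `>=` convention).
#' @slot config training metadata (kernel, parameters, folds, seed).
#' @exportClass TrainedModel
setClass("TrainedModel",
  representation(fit = "ANY", platt = "numeric", featureNames = "character",
                 threshold = "numeric", config = "list"))

setValidity("TrainedModel", function(object) {
  if (length(object@threshold) != 1L || is.na(object@threshold) ||
      object@threshold < 0 || object@threshold > 1)
    return("threshold must be a single value in [0,1]")
  if (length(object@platt) != 2L || any(!is.finite(object@platt)))
    return("platt must hold two finite coefficients")
  if (!length(object@featureNames))
    return("featureNames must be non-empty")
  TRUE
})

# ---- constructors ----------------------------------------------------------

#' Create a LabeledChain
#'
#' @param chainId chain identifier.
#' @param sequence amino-acid sequence string.
#' @param labels 0/1 vector of per-residue binding labels.
#' @param source label provenance tag.
#' @return A [LabeledChain-class].
#' @export
labeledChain <- function(chainId, sequence, labels, source = NA_character_) {
  new("LabeledChain", chainId = as.character(chainId),
      sequence = toupper(as.character(sequence)),
      labels = as.integer(labels), source = as.character(source))
}

#' Assemble a ProfileBundle from its tracks
#'
#' @param chainId chain identifier.
#' @param sequence amino-acid sequence string.
#' @param pssm a [PSSMProfile-class], e.g. from [readPssm()].
#' @param ss3 L x 3 matrix of H/E/C probabilities, e.g. from [readSs2()].
#' @param rsa,phi,psi numeric tracks, e.g. from [readStructTracks()].
#' @param conservation optional conservation score track.
#' @param consLowIsConserved orientation of `conservation` (TRUE when low
#'   score = conserved).
#' @return A [ProfileBundle-class].
#' @export
profileBundle <- function(chainId, sequence, pssm = NULL, ss3 = NULL,
                          rsa = NULL, phi = NULL, psi = NULL,
                          conservation = NULL, consLowIsConserved = TRUE) {
  if (is.null(pssm))
    pssm <- new("PSSMProfile", chainId = as.character(chainId),
                residues = character(0),
                logOdds = matrix(0, 0, 20), freqs = matrix(0, 0, 20),
                degraded = FALSE)
  if (is.null(ss3)) {
    ss3 <- matrix(numeric(0), 0, 3)
    colnames(ss3) <- c("H", "E", "C")
  }
  new("ProfileBundle", chainId = as.character(chainId),
      sequence = toupper(as.character(sequence)), pssm = pssm, ss3 = ss3,
      rsa = as.numeric(rsa %||% numeric(0)),
      phi = as.numeric(phi %||% numeric(0)),
      psi = as.numeric(psi %||% numeric(0)),
      conservation = as.numeric(conservation %||% numeric(0)),
      consLowIsConserved = isTRUE(consLowIsConserved))
}

#' Create a PredictionTrack
#'
#' @param chainId chain identifier.
#' @param sequence the chain sequence.
#' @param probability per-residue probabilities (NA for binary-only methods).
#' @param call per-residue 0/1 calls.
#' @param threshold threshold used to produce `call` (NA if none).
#' @param method method tag.
#' @param meta metadata list.
#' @return A [PredictionTrack-class].
#' @export
predictionTrack <- function(chainId, sequence, probability, call,
                            threshold = NA_real_, method = "unknown",
                            meta = list()) {
  new("PredictionTrack", chainId = as.character(chainId),
      sequence = as.character(sequence),
      probability = as.numeric(probability), call = as.integer(call),
      threshold = as.numeric(threshold), method = as.character(method),
      meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
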