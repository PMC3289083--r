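# Reference predictors: annotation transfer by local alignment, conservation
# thresholding, and the inclusive-disjunction consensus.

#' Predict binding residues by annotation transfer from the best local
#' alignment
#'
#' The query is aligned locally (Smith-Waterman via Biostrings, BLOSUM62,
#' gap open 11 / extend 1) against every annotated chain of the database
#' except itself; the best-scoring chain is the template (ties resolved by
#' database order; the raw alignment score is a monotone proxy for the
#' E-value at fixed database). Query residues aligned to binding template
#' residues are called binding; gap columns transfer nothing. The method is
#' binary-only, so the probability track is all-NA.
#'
#' @param query query sequence string, or a [LabeledChain-class] (its id is
#'   excluded from the database).
#' @param db named list of [LabeledChain-class] with binding annotations.
#' @param queryId id of the query (for self-exclusion and the output track).
#' @param gapOpening,gapExtension alignment gap penalties.
#' @param scoreFloor minimum alignment score; below it an all-zero track is
#'   returned with `meta$noHit = TRUE`.
#' @return A [PredictionTrack-class] with method `"alignment"`; `meta`
#'   records the template id and alignment score.
#' @export
alignmentTransfer <- function(query, db, queryId = NULL, gapOpening = 11,
                              gapExtension = 1, scoreFloor = 50) {
  if (is(query, "LabeledChain")) {
    queryId <- queryId %||% query@chainId
    query <- query@sequence
  }
  queryId <- queryId %||% "query"
  db <- db[setdiff(names(db), queryId)]
  if (!length(db)) .stopf("annotated database is empty after self-exclusion")
  qStr <- Biostrings::AAString(query)
  alns <- lapply(db, function(t)
    Biostrings::pairwiseAlignment(qStr, Biostrings::AAString(t@sequence),
                                  substitutionMatrix = .blosum62(),
                                  gapOpening = gapOpening,
                                  gapExtension = gapExtension,
                                  type = "local"))
  scores <- vapply(alns, Biostrings::score, numeric(1))
  bestIdx <- which.max(scores)          # first maximum = db order tie-break
  L <- nchar(query)
  if (scores[bestIdx] < scoreFloor) {
    return(predictionTrack(queryId, query, rep(NA_real_, L), rep(0L, L),
                           method = "alignment",
                           meta = list(noHit = TRUE,
                                       bestScore = unname(scores[bestIdx]))))
  }
  aln <- alns[[bestIdx]]
  template <- db[[bestIdx]]
  pg <- .seqLetters(as.character(Biostrings::alignedPattern(aln)))
  sg <- .seqLetters(as.character(Biostrings::alignedSubject(aln)))
  qi <- Biostrings::start(Biostrings::pattern(aln)) - 1L
  ti <- Biostrings::start(Biostrings::subject(aln)) - 1L
  call <- rep(0L, L)
  for (col in seq_along(pg)) {
    if (pg[col] != "-") qi <- qi + 1L
    if (sg[col] != "-") ti <- ti + 1L
    if (pg[col] != "-" && sg[col] != "-" && template@labels[ti] == 1L)
      call[qi] <- 1L
  }
  predictionTrack(queryId, query, rep(NA_real_, L), call,
                  method = "alignment",
                  meta = list(noHit = FALSE, template = template@chainId,
                              score = unname(scores[bestIdx])))
}

#' Conservation-score baseline predictor
#'
#' Orients external conservation scores so that higher means more likely
#' binding (inverting tracks whose convention is low = conserved), linearly
#' normalizes each chain's scores to \[0, 1\], and binarizes at the
#' MCC-maximizing threshold found on the designated calibration chains only
#' (`>=` convention, exhaustive scan).
#'
#' @param scores named list of per-chain score tracks — either numeric
#'   vectors or [readConservation()] results.
#' @param chains named list of [LabeledChain-class] with reference labels
#'   (used only for the chains in `calibIds`).
#' @param lowIsConserved default orientation for plain numeric tracks.
#' @param calibIds chains whose labels calibrate the threshold (default: all
#'   chains present in both `scores` and `chains`).
#' @return Named list of [PredictionTrack-class] with method
#'   `"conservation"`; when no threshold is admissible (constant scores or
#'   single-class calibration labels) all calls are 0 with a warning.
#' @export
conservationBaseline <- function(scores, chains, lowIsConserved = TRUE,
                                 calibIds = NULL) {
  norm <- lapply(scores, function(s) {
    flag <- lowIsConserved
    if (is.list(s)) {
      flag <- s$lowIsConserved %||% lowIsConserved
      s <- s$score
    }
    v <- if (isTRUE(flag)) -as.numeric(s) else as.numeric(s)
    rng <- range(v)
    if (rng[1L] == rng[2L]) rep(0.5, length(v)) else (v - rng[1L]) / diff(rng)
  })
  calibIds <- calibIds %||% intersect(names(norm), names(chains))
  calP <- unlist(norm[calibIds], use.names = FALSE)
  calY <- unlist(lapply(calibIds, function(i) chains[[i]]@labels))
  scan <- if (length(unique(calP)) < 2L) list(threshold = NA_real_)
          else .mccThresholdScan(calP, calY)
  thr <- scan$threshold
  if (is.na(thr))
    .warnf("conservation threshold undefined (constant scores or single-class labels); all calls set to 0")
  out <- list()
  for (id in names(norm)) {
    p <- norm[[id]]
    call <- if (is.na(thr)) rep(0L, length(p)) else as.integer(p >= thr)
    seqStr <- if (!is.null(chains[[id]])) chains[[id]]@sequence
              else strrep("X", length(p))
    out[[id]] <- predictionTrack(id, seqStr, p, call, threshold = thr,
                                 method = "conservation")
  }
  out
}

#' Inclusive-disjunction consensus of prediction tracks
#'
#' Calls a residue binding when any component does (logical OR) and assigns
#' it the maximum of the component probabilities; binary-only components
#' (all-NA probabilities) contribute their 0/1 calls as probabilities. The
#' operation is commutative, associative and idempotent, so any number of
#' components and any of the method pairings can be combined.
#'
#' @param ... two or more [PredictionTrack-class] objects over the same
#'   chain, or a single list of them.
#' @return A [PredictionTrack-class] with method
#'   `"consensus(<methods>)"`.
#' @export
consensusTrack <- function(...) {
  tracks <- list(...)
  if (length(tracks) == 1L && is.list(tracks[[1L]]) &&
      !is(tracks[[1L]], "PredictionTrack"))
    tracks <- tracks[[1L]]
  if (length(tracks) < 2L) .stopf("consensus needs at least two tracks")
  ref <- tracks[[1L]]
  for (t in tracks[-1L]) {
    if (t@chainId != ref@chainId || nchar(t@sequence) != nchar(ref@sequence))
      .stopf("consensus components must cover the same chain")
  }
  callMat <- vapply(tracks, function(t) t@call, integer(nchar(ref@sequence)))
  probMat <- vapply(tracks, function(t)
    ifelse(is.na(t@probability), as.numeric(t@call), t@probability),
    numeric(nchar(ref@sequence)))
  if (nchar(ref@sequence) == 1L) {
    callMat <- matrix(callMat, 1L)
    probMat <- matrix(probMat, 1L)
  }
  methods <- vapply(tracks, function(t) t@method, character(1))
  predictionTrack(ref@chainId, ref@sequence,
                  probability = apply(probMat, 1L, max),
                  call = as.integer(apply(callMat, 1L, max)),
                  method = sprintf("consensus(%s)", paste(methods, collapse = "+")))
}
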