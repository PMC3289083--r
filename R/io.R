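# Readers and writers for the external file formats consumed by the toolkit.
# All coordinates in files are 1-based; internal row indices are plain R
# indices. Every reader length-checks its track against the chain sequence;
# nothing is silently truncated or padded.

#' Read protein chains from a FASTA file
#'
#' Sequences are uppercased; letters outside the 20 standard amino acids plus
#' `X` that have a conventional meaning (`B`, `Z`, `J`, `U`, `O`) are mapped
#' to `X` with a warning. Other characters, duplicate record ids and empty
#' records are structured parse errors naming the offending line.
#'
#' @param path path to a FASTA file.
#' @return Named list of sequence strings (names are record ids).
#' @export
readFastaChains <- function(path) {
  if (!file.exists(path)) .stopf("FASTA file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(startsWith(trimws(lines), ">")))
    .stopf("%s: not a FASTA file (no '>' header found)", path)
  ids <- character(0); seqs <- character(0)
  curId <- NULL; curSeq <- character(0); headLine <- 0L
  flush <- function() {
    if (is.null(curId)) return()
    s <- paste(curSeq, collapse = "")
    if (!nzchar(s))
      .stopf("%s line %d: record '%s' has an empty sequence", path, headLine, curId)
    if (curId %in% ids)
      .stopf("%s line %d: duplicate record id '%s'", path, headLine, curId)
    ids <<- c(ids, curId); seqs <<- c(seqs, s)
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, ">")) {
      flush()
      curId <- strsplit(sub("^>\\s*", "", ln), "\\s+")[[1L]][1L]
      if (is.na(curId) || !nzchar(curId))
        .stopf("%s line %d: empty FASTA header", path, i)
      curSeq <- character(0); headLine <- i
    } else {
      if (is.null(curId))
        .stopf("%s line %d: sequence data before first header", path, i)
      up <- toupper(gsub("\\s", "", ln))
      bad <- setdiff(.seqLetters(up), LETTERS)
      if (length(bad))
        .stopf("%s line %d: illegal character(s) %s in sequence",
               path, i, paste(sQuote(bad), collapse = ", "))
      mappable <- c("B", "Z", "J", "U", "O")
      odd <- intersect(.seqLetters(up), mappable)
      if (length(odd)) {
        .warnf("%s line %d: non-standard letter(s) %s mapped to X",
               path, i, paste(odd, collapse = ","))
        up <- chartr(paste(mappable, collapse = ""),
                     strrep("X", length(mappable)), up)
      }
      left <- setdiff(.seqLetters(up), c(AA20, "X"))
      if (length(left))
        .stopf("%s line %d: illegal amino-acid letter(s) %s",
               path, i, paste(left, collapse = ","))
      curSeq <- c(curSeq, up)
    }
  }
  flush()
  stats::setNames(as.list(seqs), ids)
}

#' Read a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Accepts both the 40-column dialect (log-odds block plus weighted observed
#' percentages) and the 20-column log-odds-only dialect. In the latter case
#' per-position frequencies are derived from the log-odds by the logistic
#' transform `1/(1+2^-x)` and renormalization, and the profile is flagged as
#' degraded with a message. Row letters are cross-checked against `sequence`
#' (positions where the sequence holds `X` are exempt).
#'
#' @param path path to the ASCII PSSM file.
#' @param sequence the chain sequence the profile belongs to.
#' @param chainId chain identifier stored in the result.
#' @return A [PSSMProfile-class].
#' @export
readPssm <- function(path, sequence, chainId = "chain") {
  if (!file.exists(path)) .stopf("PSSM file not found: %s", path)
  sequence <- toupper(sequence)
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(toks) < 22L) next
    if (!grepl("^[0-9]+$", toks[1L]) || !grepl("^[A-Za-z]$", toks[2L])) next
    vals <- suppressWarnings(as.numeric(toks[3:length(toks)]))
    if (any(is.na(vals[1:20])))
      .stopf("%s: malformed PSSM row %d (line %d)", path, length(rows) + 1L, i)
    rows[[length(rows) + 1L]] <- list(pos = as.integer(toks[1L]),
                                      letter = toupper(toks[2L]), vals = vals)
  }
  L <- length(rows)
  if (!L) .stopf("%s: no PSSM data rows found", path)
  if (L != nchar(sequence))
    .stopf("%s: PSSM has %d rows but sequence has %d residues",
           path, L, nchar(sequence))
  pos <- vapply(rows, `[[`, integer(1), "pos")
  if (!identical(pos, seq_len(L)))
    .stopf("%s: PSSM positions are not consecutive from 1", path)
  letters <- vapply(rows, `[[`, character(1), "letter")
  seqLet <- .seqLetters(sequence)
  mism <- which(letters != seqLet & seqLet != "X")
  if (length(mism))
    .stopf("%s: residue letter mismatch at position %d (PSSM '%s' vs sequence '%s')",
           path, mism[1L], letters[mism[1L]], seqLet[mism[1L]])
  logOdds <- t(vapply(rows, function(r) r$vals[1:20], numeric(20)))
  colnames(logOdds) <- AA20
  hasFreq <- all(vapply(rows, function(r) length(r$vals) >= 40L, logical(1)))
  degraded <- !hasFreq
  if (hasFreq) {
    freqs <- t(vapply(rows, function(r) r$vals[21:40], numeric(20))) / 100
    # percent columns are rounded in the dialect; renormalize rows here so the
    # conservation scores downstream receive proper distributions
    rs <- rowSums(freqs)
    zero <- rs <= 0
    if (any(zero)) freqs[zero, ] <- 1 / 20
    rs[zero] <- 1
    freqs <- freqs / rs
  } else {
    message(sprintf("%s: no frequency block; deriving frequencies from log-odds (degraded mode)", path))
    f <- normalizePssm(logOdds)
    freqs <- f / rowSums(f)
  }
  colnames(freqs) <- AA20
  new("PSSMProfile", chainId = as.character(chainId), residues = letters,
      logOdds = logOdds, freqs = freqs, degraded = degraded)
}

#' Read PSIPRED vertical-format secondary-structure predictions
#'
#' @param path path to a `.ss2` file (columns: position, residue, state, and
#'   coil/helix/strand probabilities).
#' @param sequence the chain sequence, for length and letter cross-checks.
#' @return L x 3 matrix of probabilities with columns `H`, `E`, `C`.
#' @export
readSs2 <- function(path, sequence) {
  if (!file.exists(path)) .stopf("ss2 file not found: %s", path)
  sequence <- toupper(sequence)
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    toks <- strsplit(ln, "\\s+")[[1L]]
    if (length(toks) < 6L) .stopf("%s line %d: malformed ss2 row", path, i)
    p <- suppressWarnings(as.numeric(toks[4:6]))
    if (any(is.na(p))) .stopf("%s line %d: non-numeric ss2 probabilities", path, i)
    rows[[length(rows) + 1L]] <- list(letter = toupper(toks[2L]), p = p)
  }
  L <- length(rows)
  if (L != nchar(sequence))
    .stopf("%s: ss2 has %d rows but sequence has %d residues", path, L, nchar(sequence))
  letters <- vapply(rows, `[[`, character(1), "letter")
  seqLet <- .seqLetters(sequence)
  mism <- which(letters != seqLet & seqLet != "X")
  if (length(mism))
    .stopf("%s: residue letter mismatch at position %d", path, mism[1L])
  # ss2 column order is coil, helix, strand; store as H, E, C
  p <- t(vapply(rows, `[[`, numeric(3), "p"))
  ss3 <- cbind(H = p[, 2L], E = p[, 3L], C = p[, 1L])
  if (any(ss3 < 0 | ss3 > 1))
    .stopf("%s: ss2 probabilities outside [0,1]", path)
  ss3
}

#' Read RSA and dihedral-angle tracks from columnar text
#'
#' Expects whitespace-delimited columns: position, residue letter, RSA, phi,
#' psi. RSA values outside \[0, 1\] are clamped with a warning (external
#' predictors occasionally emit small excursions); dihedrals must lie in
#' \[-180, 180\].
#'
#' @param path path to the track file.
#' @param sequence the chain sequence.
#' @return List with numeric elements `rsa`, `phi`, `psi`.
#' @export
readStructTracks <- function(path, sequence) {
  tab <- .readColumnar(path, sequence, nVals = 3L, what = "structure track")
  rsa <- tab$vals[, 1L]
  out <- rsa < 0 | rsa > 1
  if (any(out)) {
    .warnf("%s: %d RSA value(s) outside [0,1] clamped", path, sum(out))
    rsa <- pmin(pmax(rsa, 0), 1)
  }
  phi <- tab$vals[, 2L]; psi <- tab$vals[, 3L]
  if (any(abs(c(phi, psi)) > 180))
    .stopf("%s: dihedral angle outside [-180,180]", path)
  list(rsa = rsa, phi = phi, psi = psi)
}

#' Read an external per-residue conservation score track
#'
#' @param path path to a columnar file (position, residue letter, score).
#' @param sequence the chain sequence.
#' @param lowIsConserved orientation flag: TRUE when a lower score means a
#'   more conserved residue (the rate4site convention). Recorded for later
#'   inversion by the conservation baseline.
#' @return List with elements `score` (numeric) and `lowIsConserved`.
#' @export
readConservation <- function(path, sequence, lowIsConserved = TRUE) {
  tab <- .readColumnar(path, sequence, nVals = 1L, what = "conservation track")
  list(score = tab$vals[, 1L], lowIsConserved = isTRUE(lowIsConserved))
}

.readColumnar <- function(path, sequence, nVals, what) {
  if (!file.exists(path)) .stopf("%s file not found: %s", what, path)
  sequence <- toupper(sequence)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lines <- lines[keep]
  if (length(lines) != nchar(sequence))
    .stopf("%s: %s has %d rows but sequence has %d residues",
           path, what, length(lines), nchar(sequence))
  seqLet <- .seqLetters(sequence)
  vals <- matrix(NA_real_, length(lines), nVals)
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(toks) < 2L + nVals)
      .stopf("%s: malformed %s row %d", path, what, i)
    if (toupper(toks[2L]) != seqLet[i] && seqLet[i] != "X")
      .stopf("%s: residue letter mismatch at position %d", path, i)
    v <- suppressWarnings(as.numeric(toks[3:(2 + nVals)]))
    if (any(is.na(v))) .stopf("%s: non-numeric value in %s row %d", path, what, i)
    vals[i, ] <- v
  }
  list(vals = vals)
}

#' Write a PredictionTrack to TSV
#'
#' Columns: 1-based position, residue letter, probability (6 decimals, `NA`
#' for binary-only methods), binary call. The threshold, method and chain id
#' are echoed in header comments. A residue is called binding when its
#' probability is greater than or equal to the threshold.
#'
#' @param track a [PredictionTrack-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writePredictions <- function(track, path) {
  stopifnot(is(track, "PredictionTrack"))
  L <- nchar(track@sequence)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# chain: %s", track@chainId),
    sprintf("# method: %s", track@method),
    sprintf("# threshold: %s",
            ifelse(is.na(track@threshold), "NA",
                   sprintf("%.6f", track@threshold))),
    "pos\tres\tprob\tcall"), con)
  prob <- ifelse(is.na(track@probability), "NA",
                 sprintf("%.6f", track@probability))
  writeLines(sprintf("%d\t%s\t%s\t%d", seq_len(L), .seqLetters(track@sequence),
                     prob, track@call), con)
  invisible(path)
}

#' Read a prediction TSV written by [writePredictions()]
#'
#' @param path path to the prediction file.
#' @return A [PredictionTrack-class] (probabilities at the printed 6-decimal
#'   precision).
#' @export
readPredictions <- function(path) {
  if (!file.exists(path)) .stopf("prediction file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  getH <- function(key) {
    ln <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (!length(ln)) NA_character_ else trimws(sub(sprintf("^# %s:", key), "", ln[1L]))
  }
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (!length(body) || !startsWith(body[1L], "pos"))
    .stopf("%s: missing prediction header row", path)
  body <- body[-1L]
  toks <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(vapply(toks, length, integer(1)) != 4L)
  if (length(bad)) .stopf("%s: malformed prediction row %d", path, bad[1L])
  res <- vapply(toks, `[[`, character(1), 2L)
  prob <- suppressWarnings(as.numeric(vapply(toks, `[[`, character(1), 3L)))
  call <- as.integer(vapply(toks, `[[`, character(1), 4L))
  thr <- suppressWarnings(as.numeric(getH("threshold")))
  predictionTrack(chainId = getH("chain") %||% "chain",
                  sequence = paste(res, collapse = ""),
                  probability = prob, call = call, threshold = thr,
                  method = getH("method") %||% "unknown")
}
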