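# Sliding-window feature encoding of residues.
#
# Each residue is represented by a fixed-order vector assembled from a
# size-17 window centered on it: symmetrically averaged normalized PSSM
# columns (180), raw windowed secondary-structure probabilities (51), RSA
# (17), scaled dihedrals (34), symmetrically averaged amino-acid-group
# indicators (36), a terminal indicator (1), secondary-structure segment
# indicators on the window flanks (6), three windowed conservation scores
# (17 each) and screened collocated amino-acid pair indicators.
#
# Window padding at chain ends uses neutral values: 0.5 for normalized PSSM
# (the image of a zero log-odds score), coil for secondary structure, 0 for
# RSA, scaled dihedrals and indicators, the uniform-distribution entropy for
# conservation A and 0 for the background-divergence scores B and C.

.AA_GROUPS <- list(
  hydrophobic = c("A", "C", "I", "L", "M", "V"),
  negative    = c("D", "E"),
  positive    = c("H", "K", "R"),
  carboxamide = c("N", "Q"))

#' Window geometry for the sliding-window encoder
#'
#' @param size odd window size (default 17).
#' @return An object of class `WindowSpec` with elements `size`, `radius`,
#'   `offsets` (k = -radius..radius) and `zOffsets` (z = 0..radius, the
#'   symmetric-averaging offsets).
#' @export
windowSpec <- function(size = 17L) {
  size <- as.integer(size)
  if (is.na(size) || size < 1L || size %% 2L == 0L)
    .stopf("window size must be an odd positive integer")
  r <- (size - 1L) %/% 2L
  structure(list(size = size, radius = r, offsets = seq(-r, r),
                 zOffsets = seq(0L, r)), class = "WindowSpec")
}

#' Normalize raw PSSM log-odds scores
#'
#' Applies the logistic transform `1/(1 + 2^-x)`, mapping raw log-odds scores
#' into (0, 1); `x = 0` maps to 0.5 and `f(-x) = 1 - f(x)`.
#'
#' @param x numeric vector or matrix of raw log-odds scores.
#' @return Transformed values of the same shape.
#' @export
normalizePssm <- function(x) 1 / (1 + 2^(-x))

# value of track at position p, or pad when outside 1..L
.at <- function(track, p, pad) {
  if (is.matrix(track)) {
    ok <- p >= 1L & p <= nrow(track)
    out <- matrix(pad, length(p), ncol(track), byrow = TRUE)
    out[ok, ] <- track[p[ok], , drop = FALSE]
    out
  } else {
    ok <- p >= 1L & p <= length(track)
    out <- rep(pad, length(p))
    out[ok] <- track[p[ok]]
    out
  }
}

.pssmMatrix <- function(profile) {
  if (is(profile, "PSSMProfile")) profile@logOdds else as.matrix(profile)
}

#' Symmetrically averaged PSSM window features for one residue
#'
#' For z = 0..radius and each of the 20 PSSM columns, returns
#' `g = (f(i+z) + f(i-z)) / 2` where `f` are the normalized (logistic) PSSM
#' entries and out-of-chain positions contribute the neutral value 0.5. The
#' z = 0 block equals the residue's own normalized profile row. Output is
#' z-major (20 columns per z), length `20 * (radius+1)` (180 for size 17).
#'
#' @param profile a [PSSMProfile-class] or an L x 20 raw log-odds matrix.
#' @param position 1-based residue position.
#' @param window a [windowSpec()].
#' @return Named numeric vector, names `pssm.z<z>.<AA>`.
#' @export
pssmWindowFeatures <- function(profile, position, window = windowSpec()) {
  m <- .pssmMatrix(profile)
  if (position < 1L || position > nrow(m)) .stopf("position out of range")
  f <- normalizePssm(m)
  out <- numeric(0)
  for (z in window$zOffsets) {
    g <- (.at(f, position + z, 0.5) + .at(f, position - z, 0.5)) / 2
    out <- c(out, stats::setNames(as.numeric(g), sprintf("pssm.z%d.%s", z, AA20)))
  }
  out
}

#' Raw windowed secondary-structure probability features
#'
#' Helix/strand/coil probabilities of every residue in the window, k-major
#' (3 per position, 51 for size 17). Out-of-chain positions are padded with
#' coil (H = 0, E = 0, C = 1).
#'
#' @param ss3 L x 3 matrix with columns `H`, `E`, `C` (or a [ProfileBundle-class]).
#' @param position 1-based residue position.
#' @param window a [windowSpec()].
#' @return Named numeric vector, names `pss.k<k>.<state>`.
#' @export
ss3WindowFeatures <- function(ss3, position, window = windowSpec()) {
  if (is(ss3, "ProfileBundle")) ss3 <- ss3@ss3
  if (position < 1L || position > nrow(ss3)) .stopf("position out of range")
  out <- numeric(0)
  for (k in window$offsets) {
    p <- position + k
    v <- if (p >= 1L && p <= nrow(ss3)) ss3[p, c("H", "E", "C")] else c(H = 0, E = 0, C = 1)
    out <- c(out, stats::setNames(as.numeric(v),
                                  sprintf("pss.k%+d.%s", k, c("H", "E", "C"))))
  }
  out
}

#' Raw windowed relative solvent accessibility features
#'
#' RSA of every residue in the window (17 values for size 17); out-of-chain
#' positions contribute 0.
#'
#' @param rsa numeric RSA track in \[0, 1\] (or a [ProfileBundle-class]).
#' @param position 1-based residue position.
#' @param window a [windowSpec()].
#' @return Named numeric vector, names `rsa.k<k>`.
#' @export
rsaWindowFeatures <- function(rsa, position, window = windowSpec()) {
  if (is(rsa, "ProfileBundle")) rsa <- rsa@rsa
  if (position < 1L || position > length(rsa)) .stopf("position out of range")
  vals <- .at(rsa, position + window$offsets, 0)
  stats::setNames(vals, sprintf("rsa.k%+d", window$offsets))
}

#' Scaled windowed dihedral-angle features
#'
#' Phi and psi of every residue in the window, scaled to \[-1, 1\] by
#' division by 180 (34 values for size 17); out-of-chain positions
#' contribute 0.
#'
#' @param phi,psi dihedral tracks in degrees (or pass a [ProfileBundle-class]
#'   as `phi`).
#' @param position 1-based residue position.
#' @param window a [windowSpec()].
#' @return Named numeric vector, names `dih.k<k>.phi` / `dih.k<k>.psi`.
#' @export
dihedralWindowFeatures <- function(phi, psi = NULL, position, window = windowSpec()) {
  if (is(phi, "ProfileBundle")) {
    psi <- phi@psi
    phi <- phi@phi
  }
  if (position < 1L || position > length(phi)) .stopf("position out of range")
  out <- numeric(0)
  for (k in window$offsets) {
    out <- c(out, stats::setNames(
      c(.at(phi, position + k, 0), .at(psi, position + k, 0)) / 180,
      sprintf("dih.k%+d.%s", k, c("phi", "psi"))))
  }
  out
}

.aaGroupIndicators <- function(sequence) {
  let <- .seqLetters(sequence)
  m <- vapply(.AA_GROUPS, function(g) as.numeric(let %in% g),
              numeric(length(let)))
  if (length(let) == 1L) m <- matrix(m, nrow = 1L,
                                     dimnames = list(NULL, names(.AA_GROUPS)))
  m
}

#' Symmetrically averaged amino-acid-group window features
#'
#' Four binary membership tracks (hydrophobic A/C/I/L/M/V, negatively charged
#' D/E, positively charged H/K/R, carboxamide-containing N/Q) are compressed
#' by the same symmetric z-averaging as the PSSM, yielding
#' `4 * (radius+1)` values (36 for size 17). `X` belongs to no group;
#' out-of-chain positions contribute 0.
#'
#' @param sequence chain sequence string.
#' @param position 1-based residue position.
#' @param window a [windowSpec()].
#' @return Named numeric vector, names `aag.z<z>.<group>`.
#' @export
aaGroupWindowFeatures <- function(sequence, position, window = windowSpec()) {
  L <- nchar(sequence)
  if (position < 1L || position > L) .stopf("position out of range")
  ind <- .aaGroupIndicators(sequence)
  out <- numeric(0)
  for (z in window$zOffsets) {
    g <- (.at(ind, position + z, 0) + .at(ind, position - z, 0)) / 2
    out <- c(out, stats::setNames(as.numeric(g),
                                  sprintf("aag.z%d.%s", z, names(.AA_GROUPS))))
  }
  out
}

#' Terminal indicator
#'
#' 1 for the first and last 3 residues of the chain, 0 elsewhere. Degenerate
#' short chains (length <= 6) are all-terminal.
#'
#' @param sequence chain sequence string (or its length).
#' @param position 1-based residue position.
#' @return 0 or 1.
#' @export
terminalIndicator <- function(sequence, position) {
  L <- if (is.character(sequence)) nchar(sequence) else as.integer(sequence)
  if (position < 1L || position > L) .stopf("position out of range")
  as.numeric(position <= 3L || position >= L - 2L)
}

#' Secondary-structure segment indicators on the window flanks
#'
#' Evaluated on the 8 residues immediately flanking each side of the window
#' (positions i-radius-8 .. i-radius-1 on the left and i+radius+1 ..
#' i+radius+8 on the right; out-of-chain positions count as coil). The helix
#' indicator of a side is 1 when it contains at least 4 consecutive
#' helix-state residues, the strand indicator when at least 3 consecutive
#' strand-state residues; the coil indicator is 1 exactly when both are 0.
#'
#' @param states per-residue argmax secondary-structure states, a character
#'   vector over `"H"`, `"E"`, `"C"`.
#' @param position 1-based residue position.
#' @param window a [windowSpec()].
#' @param flank number of flanking residues per side (default 8).
#' @return Named numeric vector of 6 indicators,
#'   `seg.<left|right>.<H|E|C>`.
#' @export
segmentIndicators <- function(states, position, window = windowSpec(),
                              flank = 8L) {
  L <- length(states)
  if (position < 1L || position > L) .stopf("position out of range")
  r <- window$radius
  side <- function(p) {
    s <- rep("C", length(p))
    ok <- p >= 1L & p <= L
    s[ok] <- states[p[ok]]
    h <- as.numeric(.maxRun(s == "H") >= 4L)
    e <- as.numeric(.maxRun(s == "E") >= 3L)
    c(H = h, E = e, C = as.numeric(h == 0 && e == 0))
  }
  left <- side(seq(position - r - flank, position - r - 1L))
  right <- side(seq(position + r + 1L, position + r + flank))
  stats::setNames(c(left, right),
                  c(sprintf("seg.left.%s", c("H", "E", "C")),
                    sprintf("seg.right.%s", c("H", "E", "C"))))
}

# argmax secondary-structure state per residue (ties resolved H > E > C)
ss3States <- function(ss3) {
  if (is(ss3, "ProfileBundle")) ss3 <- ss3@ss3
  c("H", "E", "C")[apply(ss3[, c("H", "E", "C"), drop = FALSE], 1L, which.max)]
}

#' Per-position conservation scores from a frequency distribution
#'
#' Three scores of a per-position amino-acid distribution `q` against the
#' background `b`: conservation A is the Shannon entropy
#' `-sum(q * log2 q)` (low = conserved); conservation B is the relative
#' entropy (Kullback-Leibler divergence) `sum(q * log2(q/b))`; conservation C
#' is the Jensen-Shannon divergence between `q` and `b` (both B and C are
#' high = conserved-away-from-background). `0 * log 0` is taken as 0.
#'
#' @param q length-20 frequency vector in [aaAlphabet()] order. Renormalized
#'   with a warning when its sum deviates from 1 by more than 1e-3.
#' @param background background frequencies (default
#'   [backgroundFrequencies()]).
#' @return Named numeric vector `c(A=, B=, C=)`.
#' @export
conservationScores <- function(q, background = backgroundFrequencies()) {
  q <- as.numeric(q)
  if (length(q) != 20L) .stopf("q must have 20 elements")
  if (any(q < 0)) .stopf("frequencies must be non-negative")
  s <- sum(q)
  if (s <= 0) .stopf("frequency vector sums to 0")
  if (abs(s - 1) > 1e-3) {
    .warnf("frequency vector sums to %.4f; renormalizing", s)
    q <- q / s
  } else if (s != 1) {
    q <- q / s
  }
  b <- as.numeric(background)
  xlog <- function(p, ref) {
    out <- numeric(length(p))
    nz <- p > 0
    out[nz] <- p[nz] * log2(p[nz] / ref[nz])
    out
  }
  A <- -sum(q[q > 0] * log2(q[q > 0]))
  B <- sum(xlog(q, b))
  m <- (q + b) / 2
  C <- 0.5 * sum(xlog(q, m)) + 0.5 * sum(xlog(b, m))
  c(A = A, B = B, C = C)
}

# per-position conservation score vectors for a whole profile
.conservationTracks <- function(freqs, background = backgroundFrequencies()) {
  sc <- t(apply(freqs, 1L, conservationScores, background = background))
  if (nrow(freqs) == 1L) sc <- matrix(sc, 1L, 3L, dimnames = list(NULL, c("A", "B", "C")))
  colnames(sc) <- c("A", "B", "C")
  sc
}

#' Raw windowed conservation-score features
#'
#' The selected conservation score of every residue in the window (17 values
#' per score for size 17). Out-of-chain padding is the uniform-distribution
#' entropy `log2(20)` for score A (maximally unconserved) and 0 for the
#' divergence scores B and C (background-like).
#'
#' @param profile a [PSSMProfile-class] (frequencies feed the scores).
#' @param position 1-based residue position.
#' @param window a [windowSpec()].
#' @param score which score, `"A"`, `"B"` or `"C"`.
#' @return Named numeric vector, names `cons<score>.k<k>`.
#' @export
conservationWindowFeatures <- function(profile, position,
                                       window = windowSpec(), score = "A") {
  score <- match.arg(score, c("A", "B", "C"))
  tr <- .conservationTracks(profile@freqs)[, score]
  if (position < 1L || position > length(tr)) .stopf("position out of range")
  pad <- if (score == "A") log2(20) else 0
  stats::setNames(.at(tr, position + window$offsets, pad),
                  sprintf("cons%s.k%+d", score, window$offsets))
}

# ---- collocated amino-acid pairs -------------------------------------------

.collocName <- function(center, partner, offset)
  sprintf("colloc.%s%+d%s", center, offset, partner)

#' Screen collocated amino-acid pairs for association with binding
#'
#' Enumerates all `20 x 20 x 10 = 4000` (center, partner, signed offset)
#' combinations with offsets -5..-1 and 1..5. For each candidate, a 2x2
#' contingency table (pair present at a residue vs the residue's binding
#' label, over all residues of the training chains) is tested with a
#' two-sided Fisher exact test; pairs with `p < pCut` survive and become
#' binary presence features. Residues whose partner position falls outside
#' the chain count as pair-absent; `X` residues never form pairs.
#'
#' The screen must only ever see training chains; collocation features for
#' held-out chains are computed from the surviving pair list.
#'
#' @param chains list of [LabeledChain-class] (training chains only).
#' @param maxOffset maximum |offset| considered (default 5).
#' @param pCut survival threshold on the Fisher p-value (default 1e-6).
#' @return An object of class `CollocationScreen`: list with `selected`
#'   (data frame of surviving pairs: center, partner, offset, contingency
#'   counts, p), `candidates` (all combinations with their counts and
#'   p-values), `pCut`, `nPos`, `nNeg`.
#' @export
screenCollocations <- function(chains, maxOffset = 5L, pCut = 1e-6) {
  if (!length(chains)) .stopf("collocation screening needs a non-empty training set")
  offs <- c(seq(-maxOffset, -1L), seq(1L, maxOffset))
  nOff <- length(offs)
  # presence counts per (center, partner, offset, label)
  cnt <- array(0L, dim = c(20L, 20L, nOff, 2L),
               dimnames = list(AA20, AA20, as.character(offs), c("0", "1")))
  nPos <- 0L; nNeg <- 0L
  for (ch in chains) {
    let <- .seqLetters(ch@sequence)
    y <- ch@labels
    L <- length(let)
    nPos <- nPos + sum(y == 1L)
    nNeg <- nNeg + sum(y == 0L)
    for (oi in seq_len(nOff)) {
      d <- offs[oi]
      i <- seq_len(L)
      ok <- i + d >= 1L & i + d <= L
      ci <- let[i[ok]]; pi <- let[i[ok] + d]; yv <- y[i[ok]]
      keep <- ci %in% AA20 & pi %in% AA20
      if (!any(keep)) next
      t3 <- table(factor(ci[keep], AA20), factor(pi[keep], AA20),
                  factor(yv[keep], c(0L, 1L)))
      cnt[, , oi, ] <- cnt[, , oi, ] + t3
    }
  }
  grid <- expand.grid(center = AA20, partner = AA20, offset = offs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n11 <- mapply(function(a, b, d) cnt[a, b, as.character(d), "1"],
                grid$center, grid$partner, grid$offset)
  n10 <- mapply(function(a, b, d) cnt[a, b, as.character(d), "0"],
                grid$center, grid$partner, grid$offset)
  grid$presentPos <- as.integer(n11)
  grid$presentNeg <- as.integer(n10)
  grid$absentPos <- nPos - grid$presentPos
  grid$absentNeg <- nNeg - grid$presentNeg
  grid$p <- vapply(seq_len(nrow(grid)), function(i) {
    if (grid$presentPos[i] + grid$presentNeg[i] == 0L) return(1)
    stats::fisher.test(matrix(c(grid$presentPos[i], grid$presentNeg[i],
                                grid$absentPos[i], grid$absentNeg[i]),
                              2L, 2L))$p.value
  }, numeric(1))
  grid$feature <- .collocName(grid$center, grid$partner, grid$offset)
  sel <- grid[grid$p < pCut, , drop = FALSE]
  sel <- sel[order(sel$p, sel$feature), , drop = FALSE]
  rownames(sel) <- NULL
  structure(list(selected = sel, candidates = grid, pCut = pCut,
                 nPos = nPos, nNeg = nNeg),
            class = "CollocationScreen")
}

#' @export
print.CollocationScreen <- function(x, ...) {
  cat(sprintf("CollocationScreen: %d of %d candidate pairs survive p < %g (%d/%d pos/neg residues)\n",
              nrow(x$selected), nrow(x$candidates), x$pCut, x$nPos, x$nNeg))
  invisible(x)
}

#' Binary collocation presence features for a chain
#'
#' @param sequence chain sequence string.
#' @param pairs data frame with columns `center`, `partner`, `offset` (e.g.
#'   the `selected` element of [screenCollocations()], or the screen object
#'   itself).
#' @return L x nrow(pairs) binary matrix with the screen's feature names;
#'   zero columns when `pairs` is empty.
#' @export
collocationFeatures <- function(sequence, pairs) {
  if (inherits(pairs, "CollocationScreen")) pairs <- pairs$selected
  let <- .seqLetters(sequence)
  L <- length(let)
  if (is.null(pairs) || !nrow(pairs))
    return(matrix(numeric(0), L, 0L))
  m <- matrix(0, L, nrow(pairs))
  colnames(m) <- .collocName(pairs$center, pairs$partner, pairs$offset)
  for (j in seq_len(nrow(pairs))) {
    d <- pairs$offset[j]
    i <- seq_len(L)
    ok <- i + d >= 1L & i + d <= L
    hit <- ok & let == pairs$center[j] &
      .at(let, i + d, "-") == pairs$partner[j]
    m[hit, j] <- 1
  }
  m
}

# ---- whole-chain encoder ---------------------------------------------------

.requireTrack <- function(cond, track, chainId) {
  if (!cond) .stopf("chain %s: required track '%s' is missing", chainId, track)
}

#' Encode every residue of a chain as a feature vector
#'
#' Vectorized assembly of the full fixed-order representation (PSSM 180,
#' secondary structure 51, RSA 17, dihedrals 34, AA groups 36, terminal 1,
#' segment 6, conservation A/B/C 17 each, plus one binary column per
#' surviving collocation pair). Column names are fully qualified
#' (`group.offset.subindex`) and each column carries its feature-group tag.
#'
#' @param bundle a [ProfileBundle-class] with all required tracks present.
#' @param labels optional 0/1 label vector (or a [LabeledChain-class]); NA
#'   when absent.
#' @param collocPairs optional `CollocationScreen` (or its `selected` data
#'   frame) defining the collocation columns.
#' @param window a [windowSpec()].
#' @return A [FeatureMatrix-class] with one row per residue.
#' @export
encodeChain <- function(bundle, labels = NULL, collocPairs = NULL,
                        window = windowSpec()) {
  stopifnot(is(bundle, "ProfileBundle"))
  L <- nchar(bundle@sequence)
  id <- bundle@chainId
  .requireTrack(length(bundle@pssm@residues) > 0, "pssm", id)
  .requireTrack(nrow(bundle@ss3) > 0, "ss3", id)
  .requireTrack(length(bundle@rsa) > 0, "rsa", id)
  .requireTrack(length(bundle@phi) > 0 && length(bundle@psi) > 0, "dihedral", id)
  if (is(labels, "LabeledChain")) labels <- labels@labels
  if (is.null(labels)) labels <- rep(NA_integer_, L)
  if (length(labels) != L) .stopf("chain %s: label length mismatch", id)

  r <- window$radius
  pos <- seq_len(L)
  pad <- function(m, padRow) rbind(matrix(padRow, r, length(padRow), byrow = TRUE),
                                   m,
                                   matrix(padRow, r, length(padRow), byrow = TRUE))
  blocks <- list(); groups <- character(0)
  add <- function(m, group) {
    blocks[[length(blocks) + 1L]] <<- m
    groups <<- c(groups, rep(group, ncol(m)))
  }

  # PSSM: z-averaged normalized log-odds
  f <- pad(normalizePssm(bundle@pssm@logOdds), rep(0.5, 20L))
  pm <- matrix(0, L, 20L * length(window$zOffsets))
  cn <- character(0)
  for (zi in seq_along(window$zOffsets)) {
    z <- window$zOffsets[zi]
    pm[, (zi - 1L) * 20L + 1:20] <-
      (f[pos + r + z, , drop = FALSE] + f[pos + r - z, , drop = FALSE]) / 2
    cn <- c(cn, sprintf("pssm.z%d.%s", z, AA20))
  }
  colnames(pm) <- cn
  add(pm, "pssm")

  # secondary structure: raw windowed probabilities
  s3 <- pad(bundle@ss3[, c("H", "E", "C"), drop = FALSE], c(0, 0, 1))
  sm <- matrix(0, L, 3L * window$size)
  cn <- character(0)
  for (ki in seq_along(window$offsets)) {
    k <- window$offsets[ki]
    sm[, (ki - 1L) * 3L + 1:3] <- s3[pos + r + k, , drop = FALSE]
    cn <- c(cn, sprintf("pss.k%+d.%s", k, c("H", "E", "C")))
  }
  colnames(sm) <- cn
  add(sm, "pss")

  # RSA
  rs <- pad(matrix(bundle@rsa, ncol = 1L), 0)
  rm <- vapply(window$offsets, function(k) rs[pos + r + k, 1L], numeric(L))
  if (L == 1L) rm <- matrix(rm, 1L)
  colnames(rm) <- sprintf("rsa.k%+d", window$offsets)
  add(rm, "rsa")

  # dihedrals scaled to [-1, 1]
  dh <- pad(cbind(bundle@phi, bundle@psi) / 180, c(0, 0))
  dm <- matrix(0, L, 2L * window$size)
  cn <- character(0)
  for (ki in seq_along(window$offsets)) {
    k <- window$offsets[ki]
    dm[, (ki - 1L) * 2L + 1:2] <- dh[pos + r + k, , drop = FALSE]
    cn <- c(cn, sprintf("dih.k%+d.%s", k, c("phi", "psi")))
  }
  colnames(dm) <- cn
  add(dm, "dihedral")

  # AA groups: z-averaged indicators
  ind <- pad(.aaGroupIndicators(bundle@sequence), rep(0, 4L))
  am <- matrix(0, L, 4L * length(window$zOffsets))
  cn <- character(0)
  for (zi in seq_along(window$zOffsets)) {
    z <- window$zOffsets[zi]
    am[, (zi - 1L) * 4L + 1:4] <-
      (ind[pos + r + z, , drop = FALSE] + ind[pos + r - z, , drop = FALSE]) / 2
    cn <- c(cn, sprintf("aag.z%d.%s", z, names(.AA_GROUPS)))
  }
  colnames(am) <- cn
  add(am, "aagroup")

  # terminal indicator
  tm <- matrix(as.numeric(pos <= 3L | pos >= L - 2L), ncol = 1L)
  colnames(tm) <- "term"
  add(tm, "terminal")

  # segment indicators on the window flanks
  states <- ss3States(bundle@ss3)
  gm <- t(vapply(pos, function(p) segmentIndicators(states, p, window),
                 numeric(6L)))
  if (L == 1L) gm <- matrix(gm, 1L, 6L,
                            dimnames = list(NULL, names(segmentIndicators(states, 1L, window))))
  add(gm, "segment")

  # conservation scores, raw windowed
  ct <- .conservationTracks(bundle@pssm@freqs)
  for (sc in c("A", "B", "C")) {
    padVal <- if (sc == "A") log2(20) else 0
    tr <- pad(matrix(ct[, sc], ncol = 1L), padVal)
    cm <- vapply(window$offsets, function(k) tr[pos + r + k, 1L], numeric(L))
    if (L == 1L) cm <- matrix(cm, 1L)
    colnames(cm) <- sprintf("cons%s.k%+d", sc, window$offsets)
    add(cm, paste0("cons", sc))
  }

  # collocation presence
  if (!is.null(collocPairs)) {
    cm <- collocationFeatures(bundle@sequence, collocPairs)
    if (ncol(cm)) add(cm, "colloc")
  }

  feat <- do.call(cbind, blocks)
  names(groups) <- colnames(feat)
  new("FeatureMatrix", features = feat, chain = rep(id, L), position = pos,
      labels = as.integer(labels), groups = groups)
}

#' Encode a set of chains into one stacked FeatureMatrix
#'
#' @param chains named list of [LabeledChain-class] (labels attach to rows);
#'   may be NULL to encode unlabeled bundles.
#' @param bundles named list of [ProfileBundle-class]; names must cover
#'   `chains`.
#' @param collocPairs optional `CollocationScreen` or pair data frame.
#' @param window a [windowSpec()].
#' @return A [FeatureMatrix-class] over all residues of all chains.
#' @export
encodeDataset <- function(chains, bundles, collocPairs = NULL,
                          window = windowSpec()) {
  ids <- if (!is.null(chains)) names(chains) else names(bundles)
  fms <- lapply(ids, function(id) {
    b <- bundles[[id]]
    if (is.null(b)) .stopf("chain %s: no ProfileBundle provided", id)
    encodeChain(b, labels = chains[[id]], collocPairs = collocPairs,
                window = window)
  })
  bindFeatureMatrices(fms)
}
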