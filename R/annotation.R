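# Structure-derived labeling of ATP-binding residues and sequence-redundancy
# reduction.

.isHydrogen <- function(elesy, elety) {
  bySym <- !is.na(elesy) & nzchar(trimws(elesy)) &
    toupper(trimws(elesy)) %in% c("H", "D")
  # fall back to the atom-name heuristic when the element field is absent
  noSym <- is.na(elesy) | !nzchar(trimws(elesy))
  byName <- noSym & grepl("^[0-9]*H", trimws(elety))
  bySym | byName
}

# keep the first alternate conformer; NA/blank altloc rows are always kept
.firstAltloc <- function(atom) {
  alt <- atom$alt
  blank <- is.na(alt) | !nzchar(trimws(alt))
  if (all(blank)) return(atom)
  first <- sort(unique(alt[!blank]))[1L]
  atom[blank | alt == first, , drop = FALSE]
}

#' Annotate ATP-binding residues from a protein-ligand complex
#'
#' A residue is labeled binding (1) when the minimum distance between any of
#' its non-hydrogen atoms and any non-hydrogen atom of the named ligand is
#' strictly below `cutoff` (default 3.9 Angstrom). Hydrogens are excluded on
#' both sides, detected by the element field with an atom-name fallback.
#' All copies of the ligand in the file are measured against every chain.
#'
#' @param x path to a PDB file, or a `bio3d` `pdb` object.
#' @param ligand het-group code of the ligand (default `"ATP"`).
#' @param cutoff distance cutoff in Angstrom; the comparison is strict (`<`).
#' @return Named list of [LabeledChain-class], one per protein chain with
#'   resolved atoms. Chains without resolved atoms are skipped with a warning.
#' @export
annotateBinding <- function(x, ligand = "ATP", cutoff = 3.9) {
  pdb <- if (is.character(x)) bio3d::read.pdb(x, verbose = FALSE) else x
  src <- if (is.character(x)) sub("\\.pdb$", "", basename(x)) else "structure"
  atom <- .firstAltloc(pdb$atom)
  if (any(!is.finite(as.matrix(atom[, c("x", "y", "z")]))))
    .stopf("structure contains non-finite coordinates")
  hyd <- .isHydrogen(atom$elesy, atom$elety)
  lig <- atom[atom$type == "HETATM" & atom$resid == ligand & !hyd, , drop = FALSE]
  if (!nrow(lig))
    .stopf("ligand '%s' not found in the structure", ligand)
  ligXyz <- as.matrix(lig[, c("x", "y", "z")])
  prot <- atom[atom$type == "ATOM" & !hyd, , drop = FALSE]
  chains <- unique(prot$chain)
  out <- list()
  for (ch in chains) {
    pa <- prot[prot$chain == ch, , drop = FALSE]
    if (!nrow(pa)) {
      .warnf("chain %s has no resolved atoms; skipped", ch)
      next
    }
    resno <- unique(pa$resno)        # order of appearance
    resIdx <- match(pa$resno, resno)
    res3 <- pa$resid[match(resno, pa$resno)]
    letters <- suppressWarnings(bio3d::aa321(res3))
    letters[is.na(letters) | !letters %in% AA20] <- "X"
    pXyz <- as.matrix(pa[, c("x", "y", "z")])
    # squared distances from coordinate differences (numerically exact when
    # coordinates coincide, so the strict-< boundary is honored)
    d2 <- outer(pXyz[, 1L], ligXyz[, 1L], "-")^2 +
      outer(pXyz[, 2L], ligXyz[, 2L], "-")^2 +
      outer(pXyz[, 3L], ligXyz[, 3L], "-")^2
    atomMin <- apply(d2, 1L, min)
    resMin <- tapply(atomMin, resIdx, min)
    labels <- as.integer(resMin < cutoff^2)
    id <- paste(src, ch, sep = "_")
    out[[id]] <- labeledChain(id, paste(letters, collapse = ""), labels,
                              source = src)
  }
  if (!length(out)) .warnf("no protein chains with resolved atoms found")
  out
}

#' Global-alignment sequence identity of two chains
#'
#' Needleman-Wunsch global alignment under BLOSUM62 (gap open 10, extend 1);
#' identity is the number of exactly matching aligned positions divided by
#' the length of the shorter sequence.
#'
#' @param s1,s2 amino-acid sequence strings.
#' @return Identity fraction in \[0, 1\].
#' @export
sequenceIdentity <- function(s1, s2) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(s1), Biostrings::AAString(s2),
    substitutionMatrix = .blosum62(), gapOpening = 10, gapExtension = 1,
    type = "global")
  Biostrings::nmatch(aln) / min(nchar(s1), nchar(s2))
}

#' Reduce sequence redundancy by greedy identity clustering
#'
#' Chains are sorted by decreasing length and clustered greedily: a chain
#' joins an existing cluster when its identity to the cluster representative
#' exceeds `maxIdentity`, otherwise it founds a new cluster. Cluster
#' representatives (the longest member of each cluster) are returned, so all
#' pairwise identities among the result are at most `maxIdentity`.
#'
#' @param chains list of [LabeledChain-class], or a named list/vector of
#'   sequence strings.
#' @param maxIdentity identity ceiling (default 0.40).
#' @return The representative subset of `chains`, in the original input order.
#' @export
reduceRedundancy <- function(chains, maxIdentity = 0.40) {
  if (!length(chains)) .stopf("reduceRedundancy needs at least one chain")
  seqs <- vapply(chains, function(x)
    if (is(x, "LabeledChain")) x@sequence else as.character(x), character(1))
  ord <- order(-nchar(seqs), seq_along(seqs))   # length desc, stable
  repIdx <- integer(0)
  for (i in ord) {
    joins <- FALSE
    for (r in repIdx) {
      if (sequenceIdentity(seqs[i], seqs[r]) > maxIdentity) {
        joins <- TRUE
        break
      }
    }
    if (!joins) repIdx <- c(repIdx, i)
  }
  chains[sort(repIdx)]
}
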