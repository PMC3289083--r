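# Synthetic fixtures with planted signal: chains with contiguous binding
# segments, profile tracks carrying a PSSM signal at binding positions, a
# planted collocation motif, and toy protein-ligand complexes exercising the
# distance-cutoff annotation rule.

#' Configuration of the synthetic-data generator
#'
#' The defaults emulate the statistical structure of the real prediction
#' task: about 4% of residues bind, binding residues cluster into a few
#' contiguous segments per chain, and the evolutionary profile carries the
#' dominant signal. Per ~300-residue chain there are 4 binding segments of
#' 2-4 residues (expected positive fraction 4 x 3 / 300 = 4%). The PSSM
#' signal is an additive shift `delta` applied, at binding positions, to the
#' log-odds columns of the designated signal residues; frequencies follow the
#' log-odds, so conservation tracks inherit a weaker version of the signal.
#' A center-partner motif is planted at each binding segment start for
#' collocation screening.
#'
#' @param nChains number of chains (default 60).
#' @param lengthRange inclusive chain-length range (default 280..320).
#' @param nSegments binding segments per chain (default 4).
#' @param segmentLengthRange inclusive segment-length range (default 2..4).
#' @param delta PSSM log-odds shift at binding positions (default 2; 0 gives
#'   the null generator).
#' @param signalResidues PSSM columns receiving the shift (default G/K/S/T,
#'   the phosphate-loop residues).
#' @param motif list with `center`, `partner`, `offset` planted at segment
#'   starts; NULL disables planting.
#' @param pssmSd standard deviation of the baseline log-odds noise (default 1).
#' @param seed mandatory integer seed.
#' @return A list of class `SimConfig`.
#' @export
simConfig <- function(nChains = 60L, lengthRange = c(280L, 320L),
                      nSegments = 4L, segmentLengthRange = c(2L, 4L),
                      delta = 2, signalResidues = c("G", "K", "S", "T"),
                      motif = list(center = "G", partner = "K", offset = 3L),
                      pssmSd = 1, seed) {
  if (missing(seed) || is.na(seed)) .stopf("a seed is mandatory")
  stopifnot(nChains >= 1L, lengthRange[1L] <= lengthRange[2L],
            segmentLengthRange[1L] <= segmentLengthRange[2L],
            all(signalResidues %in% AA20))
  if (!is.null(motif))
    stopifnot(motif$center %in% AA20, motif$partner %in% AA20,
              abs(motif$offset) >= 1L, abs(motif$offset) <= 5L)
  structure(list(nChains = as.integer(nChains),
                 lengthRange = as.integer(lengthRange),
                 nSegments = as.integer(nSegments),
                 segmentLengthRange = as.integer(segmentLengthRange),
                 delta = delta, signalResidues = signalResidues,
                 motif = motif, pssmSd = pssmSd, seed = as.integer(seed)),
            class = "SimConfig")
}

# sample from the values of v (safe when length(v) == 1, unlike sample())
.sampleFrom <- function(v, n, replace = FALSE)
  v[sample.int(length(v), n, replace = replace)]

# non-overlapping segment starts with a minimum inter-segment gap
.placeSegments <- function(L, lens, minGap = 6L) {
  need <- sum(lens) + (length(lens) - 1L) * minGap
  if (need > L - 20L)
    .stopf("segments (total %d + gaps) do not fit a chain of length %d", sum(lens), L)
  for (try in 1:200) {
    starts <- sort(.sampleFrom(10:(L - max(lens) - 9L), length(lens)))
    ends <- starts + lens - 1L
    if (all(diff(starts) >= utils::head(lens, -1L) + minGap))
      return(starts)
  }
  .stopf("could not place %d segments in a chain of length %d", length(lens), L)
}

#' Generate a synthetic labeled dataset with profile tracks
#'
#' Draws chains from the background amino-acid distribution, places
#' contiguous binding segments, plants the collocation motif at segment
#' starts, and builds per-chain [ProfileBundle-class] tracks: integer PSSM
#' log-odds `round(N(0, pssmSd))` with `+delta` added at binding positions in
#' the signal columns, frequencies proportional to `background * 2^x`,
#' run-structured secondary-structure probabilities, Beta-distributed RSA,
#' state-dependent dihedrals, and an entropy-based conservation track in the
#' low-is-conserved orientation.
#'
#' @param config a [simConfig()].
#' @return List with `chains` (named list of [LabeledChain-class]),
#'   `bundles` (named list of [ProfileBundle-class]) and `config`.
#' @export
simulateDataset <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  bg <- backgroundFrequencies()
  chains <- list(); bundles <- list()
  for (ci in seq_len(config$nChains)) {
    id <- sprintf("syn%03d", ci)
    L <- .sampleFrom(config$lengthRange[1L]:config$lengthRange[2L], 1L)
    let <- sample(AA20, L, replace = TRUE, prob = bg)
    lens <- .sampleFrom(config$segmentLengthRange[1L]:config$segmentLengthRange[2L],
                        config$nSegments, replace = TRUE)
    starts <- .placeSegments(L, lens)
    y <- rep(0L, L)
    for (s in seq_along(starts))
      y[starts[s]:(starts[s] + lens[s] - 1L)] <- 1L
    if (!is.null(config$motif)) {
      for (s in starts) {
        let[s] <- config$motif$center
        p <- s + config$motif$offset
        if (p >= 1L && p <= L) let[p] <- config$motif$partner
      }
    }
    seqStr <- paste(let, collapse = "")

    # PSSM log-odds with planted signal, frequencies following the log-odds
    x <- matrix(stats::rnorm(L * 20L, 0, config$pssmSd), L, 20L)
    sig <- match(config$signalResidues, AA20)
    x[y == 1L, sig] <- x[y == 1L, sig] + config$delta
    x <- round(x)
    colnames(x) <- AA20
    q <- sweep(2^x, 2L, bg, `*`)
    q <- q / rowSums(q)
    colnames(q) <- AA20
    pssm <- new("PSSMProfile", chainId = id, residues = let, logOdds = x,
                freqs = q, degraded = FALSE)

    # secondary structure as runs of states with dominant probabilities
    states <- character(0)
    while (length(states) < L) {
      st <- sample(c("H", "E", "C"), 1L, prob = c(0.35, 0.25, 0.40))
      states <- c(states, rep(st, sample(3:10, 1L)))
    }
    states <- states[seq_len(L)]
    ss3 <- matrix(0.08, L, 3L, dimnames = list(NULL, c("H", "E", "C")))
    ss3[cbind(seq_len(L), match(states, c("H", "E", "C")))] <- 0.84
    jit <- matrix(stats::runif(L * 3L, 0, 0.05), L, 3L)
    ss3 <- (ss3 + jit) / rowSums(ss3 + jit)
    colnames(ss3) <- c("H", "E", "C")

    rsa <- stats::rbeta(L, 2, 3)
    phi <- ifelse(states == "H", stats::rnorm(L, -63, 15),
                  ifelse(states == "E", stats::rnorm(L, -120, 20),
                         stats::runif(L, -180, 180)))
    psi <- ifelse(states == "H", stats::rnorm(L, -42, 15),
                  ifelse(states == "E", stats::rnorm(L, 135, 20),
                         stats::runif(L, -180, 180)))
    phi <- pmin(pmax(phi, -180), 180)
    psi <- pmin(pmax(psi, -180), 180)

    ent <- apply(q, 1L, function(r) -sum(r[r > 0] * log2(r[r > 0])))
    cons <- ent + stats::rnorm(L, 0, 0.1)

    chains[[id]] <- labeledChain(id, seqStr, y, source = "synthetic")
    bundles[[id]] <- profileBundle(id, seqStr, pssm = pssm, ss3 = ss3,
                                   rsa = rsa, phi = phi, psi = psi,
                                   conservation = cons,
                                   consLowIsConserved = TRUE)
  }
  list(chains = chains, bundles = bundles, config = config)
}

# ---- fixture writers (exact external dialects) -----------------------------

.writePssmFile <- function(pssm, path) {
  hdr <- paste0("            ",
                paste(sprintf("%3s", AA20), collapse = " "), "  ",
                paste(sprintf("%3s", AA20), collapse = " "))
  lines <- c("", "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts", hdr)
  pct <- round(pssm@freqs * 100)
  for (i in seq_along(pssm@residues)) {
    lines <- c(lines, paste0(
      sprintf("%5d %s  ", i, pssm@residues[i]),
      paste(sprintf("%3d", as.integer(pssm@logOdds[i, ])), collapse = " "),
      "  ",
      paste(sprintf("%3d", as.integer(pct[i, ])), collapse = " "),
      sprintf("  %5.2f %9.2f", 0, 0)))
  }
  writeLines(lines, path)
}

.writeSs2File <- function(bundle, path) {
  let <- .seqLetters(bundle@sequence)
  states <- ss3States(bundle@ss3)
  lines <- c("# PSIPRED VFORMAT (synthetic)", "")
  lines <- c(lines, sprintf("%4d %s %s  %6.3f %6.3f %6.3f",
                            seq_along(let), let, states,
                            bundle@ss3[, "C"], bundle@ss3[, "H"],
                            bundle@ss3[, "E"]))
  writeLines(lines, path)
}

.writeStructFile <- function(bundle, path) {
  let <- .seqLetters(bundle@sequence)
  writeLines(c("# pos res rsa phi psi",
               sprintf("%d\t%s\t%.4f\t%.2f\t%.2f", seq_along(let), let,
                       bundle@rsa, bundle@phi, bundle@psi)), path)
}

.writeConsFile <- function(bundle, path) {
  let <- .seqLetters(bundle@sequence)
  writeLines(c("# pos res score (low = conserved)",
               sprintf("%d\t%s\t%.4f", seq_along(let), let,
                       bundle@conservation)), path)
}

#' Write a simulated dataset as external-format fixture files
#'
#' Emits `chains.fasta`, per-chain `.pssm` (PSI-BLAST ASCII dialect), `.ss2`
#' (PSIPRED vertical format), `.struct.tsv`, `.cons.tsv`, a `labels.tsv`
#' table and a `manifest.json` with the configuration and per-file MD5
#' hashes. Regenerating with the same seed reproduces the files
#' byte-identically.
#'
#' @param sim result of [simulateDataset()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
writeFixtures <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- names(sim$chains)
  fastaLines <- unlist(lapply(ids, function(id)
    c(paste0(">", id), sim$chains[[id]]@sequence)))
  writeLines(fastaLines, file.path(dir, "chains.fasta"))
  for (id in ids) {
    b <- sim$bundles[[id]]
    .writePssmFile(b@pssm, file.path(dir, paste0(id, ".pssm")))
    .writeSs2File(b, file.path(dir, paste0(id, ".ss2")))
    .writeStructFile(b, file.path(dir, paste0(id, ".struct.tsv")))
    .writeConsFile(b, file.path(dir, paste0(id, ".cons.tsv")))
  }
  lab <- do.call(rbind, lapply(ids, function(id)
    data.frame(chain = id,
               pos = seq_len(nchar(sim$chains[[id]]@sequence)),
               label = sim$chains[[id]]@labels)))
  utils::write.table(lab, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- setdiff(list.files(dir), "manifest.json")
  manifest <- list(
    config = unclass(sim$config),
    nChains = length(ids),
    positiveFraction = sum(vapply(sim$chains, function(c) sum(c@labels), numeric(1))) /
      sum(vapply(sim$chains, function(c) length(c@labels), numeric(1))),
    files = as.list(tools::md5sum(file.path(dir, sort(files)))))
  names(manifest$files) <- sort(files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read back a fixture directory written by [writeFixtures()]
#'
#' @param dir fixture directory.
#' @return List with `chains` and `bundles`, as in [simulateDataset()].
#' @export
readFixtures <- function(dir) {
  seqs <- readFastaChains(file.path(dir, "chains.fasta"))
  lab <- utils::read.table(file.path(dir, "labels.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  chains <- list(); bundles <- list()
  for (id in names(seqs)) {
    s <- seqs[[id]]
    y <- lab$label[lab$chain == id]
    chains[[id]] <- labeledChain(id, s, y, source = "fixture")
    pssm <- readPssm(file.path(dir, paste0(id, ".pssm")), s, chainId = id)
    ss3 <- readSs2(file.path(dir, paste0(id, ".ss2")), s)
    st <- readStructTracks(file.path(dir, paste0(id, ".struct.tsv")), s)
    cons <- readConservation(file.path(dir, paste0(id, ".cons.tsv")), s,
                             lowIsConserved = TRUE)
    bundles[[id]] <- profileBundle(id, s, pssm = pssm, ss3 = ss3,
                                   rsa = st$rsa, phi = st$phi, psi = st$psi,
                                   conservation = cons$score,
                                   consLowIsConserved = TRUE)
  }
  list(chains = chains, bundles = bundles)
}

#' Write a toy protein-ligand complex exercising the annotation rule
#'
#' Builds a synthetic extended backbone (CA/CB atoms 3.8 Angstrom apart
#' along x) and places one non-hydrogen ATP-ligand atom at distance
#' `cutoff - 0.1` from the CA of every labeled residue, so that re-annotation
#' with [annotateBinding()] recovers the labels exactly; all other residues
#' stay at least `cutoff + 1` from every non-hydrogen ligand atom. Optional
#' extras probe the boundary conventions: `boundaryPositions` receive a
#' ligand atom at exactly `cutoff` (must stay unlabeled under the strict `<`
#' rule) and `hydrogenDecoyPositions` receive a ligand hydrogen well inside
#' the cutoff (must stay unlabeled under the non-hydrogen rule).
#'
#' @param chain a [LabeledChain-class]; its labels choose the contact
#'   residues.
#' @param path output PDB path.
#' @param cutoff annotation cutoff the file is built for (default 3.9; must
#'   be in (0.1, 6\] for the geometry to guarantee the separation margins).
#' @param boundaryPositions residues given an exact-cutoff contact; must be
#'   unlabeled in `chain`.
#' @param hydrogenDecoyPositions unlabeled residues given a sub-cutoff
#'   hydrogen contact.
#' @return Invisibly, `path`.
#' @export
simulateComplex <- function(chain, path, cutoff = 3.9,
                            boundaryPositions = integer(0),
                            hydrogenDecoyPositions = integer(0)) {
  stopifnot(is(chain, "LabeledChain"))
  if (cutoff <= 0.1 || cutoff > 6)
    .stopf("cutoff %.2f is geometrically infeasible for the toy backbone", cutoff)
  let <- .seqLetters(chain@sequence)
  L <- length(let)
  contact <- which(chain@labels == 1L)
  if (any(boundaryPositions %in% contact) ||
      any(hydrogenDecoyPositions %in% contact))
    .stopf("boundary/hydrogen-decoy positions must be unlabeled residues")
  aa3 <- vapply(let, function(a)
    if (a == "X") "UNK" else bio3d::aa123(a), character(1))
  lines <- character(0)
  serial <- 0L
  atomLine <- function(record, name, resn, chainId, resno, x, y, z, element) {
    serial <<- serial + 1L
    sprintf("%-6s%5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            record, serial, name, resn, chainId, resno, x, y, z, element)
  }
  for (i in seq_len(L)) {
    lines <- c(lines,
               atomLine("ATOM", " CA ", aa3[i], "A", i, 3.8 * i, 0, 0, "C"),
               atomLine("ATOM", " CB ", aa3[i], "A", i, 3.8 * i, -1.4, 0, "C"))
  }
  hetno <- 0L
  for (i in contact) {
    hetno <- hetno + 1L
    lines <- c(lines, atomLine("HETATM", sprintf(" C%-2d", hetno %% 100L),
                               "ATP", "B", 1L, 3.8 * i, cutoff - 0.1, 0, "C"))
  }
  for (i in boundaryPositions) {
    hetno <- hetno + 1L
    lines <- c(lines, atomLine("HETATM", sprintf(" O%-2d", hetno %% 100L),
                               "ATP", "B", 1L, 3.8 * i, cutoff, 0, "O"))
  }
  for (i in hydrogenDecoyPositions) {
    hetno <- hetno + 1L
    lines <- c(lines, atomLine("HETATM", sprintf(" H%-2d", hetno %% 100L),
                               "ATP", "B", 1L, 3.8 * i, max(cutoff - 0.5, 0.5), 0, "H"))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
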