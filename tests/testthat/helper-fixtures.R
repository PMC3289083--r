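# Shared in-code fixtures for the test suite.

# deterministic toy ProfileBundle + LabeledChain with simple tracks
makeToyBundle <- function(L = 30L, seed = 1L, id = "toy") {
  set.seed(seed)
  let <- sample(aaAlphabet(), L, replace = TRUE)
  x <- matrix(round(rnorm(L * 20)), L, 20, dimnames = list(NULL, aaAlphabet()))
  q <- sweep(2^x, 2, backgroundFrequencies(), `*`)
  q <- q / rowSums(q)
  pssm <- new("PSSMProfile", chainId = id, residues = let, logOdds = x,
              freqs = q, degraded = FALSE)
  raw <- matrix(runif(L * 3), L, 3)
  ss3 <- raw / rowSums(raw)
  colnames(ss3) <- c("H", "E", "C")
  labels <- integer(L)
  if (L >= 5L) labels[seq(5L, L, by = 7L)] <- 1L
  bundle <- profileBundle(id, paste(let, collapse = ""), pssm = pssm,
                          ss3 = ss3, rsa = runif(L),
                          phi = runif(L, -180, 180), psi = runif(L, -180, 180),
                          conservation = rnorm(L), consLowIsConserved = TRUE)
  list(bundle = bundle,
       chain = labeledChain(id, paste(let, collapse = ""), labels))
}

# small simulated dataset reused by several files
makeSmallSim <- function(nChains = 8L, seed = 7L, delta = 2,
                         lengthRange = c(90L, 110L)) {
  simulateDataset(simConfig(nChains = nChains, lengthRange = lengthRange,
                            delta = delta, seed = seed))
}

# random prediction track pair over one chain, for consensus properties
makeRandomTrack <- function(chain, seed, method = "rnd") {
  set.seed(seed)
  L <- nchar(chainSequence(chain))
  p <- runif(L)
  predictionTrack(chainId(chain), chainSequence(chain), p,
                  as.integer(p >= 0.5), threshold = 0.5, method = method)
}

# write a PSI-BLAST-style ASCII PSSM for given matrices (40-column dialect)
writeToyPssmFile <- function(path, letters, logOdds, freqPct = NULL) {
  hdr <- paste0("            ", paste(sprintf("%3s", aaAlphabet()), collapse = " "),
                "  ", paste(sprintf("%3s", aaAlphabet()), collapse = " "))
  lines <- c("", "Last position-specific scoring matrix computed", hdr)
  for (i in seq_along(letters)) {
    ln <- paste0(sprintf("%5d %s  ", i, letters[i]),
                 paste(sprintf("%3d", as.integer(logOdds[i, ])), collapse = " "))
    if (!is.null(freqPct))
      ln <- paste0(ln, "  ",
                   paste(sprintf("%3d", as.integer(freqPct[i, ])), collapse = " "),
                   "  0.50      1.00")
    lines <- c(lines, ln)
  }
  writeLines(lines, path)
  path
}
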