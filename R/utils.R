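# Shared constants and small helpers.

# Fixed amino-acid order of PSSM columns (PSI-BLAST convention).
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Amino-acid alphabet used throughout the package
#'
#' The 20 standard amino acids in the fixed column order of PSI-BLAST
#' position-specific scoring matrices. Sequences may additionally contain
#' `X` for unknown/non-standard residues; `X` belongs to no amino-acid group
#' and never participates in collocation pairs.
#'
#' @return Character vector of 20 one-letter codes.
#' @export
aaAlphabet <- function() AA20

# Robinson & Robinson (1991) background amino-acid frequencies, the standard
# background used by profile methods, stored in PSSM column order.
.RR_BACKGROUND <- c(
  A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
  Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
  L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
  S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)

#' Background amino-acid frequencies
#'
#' Robinson-Robinson background frequencies of the 20 standard amino acids,
#' renormalized to sum to exactly 1, in [aaAlphabet()] order. Used by the
#' background-aware conservation scores.
#'
#' @return Named numeric vector of length 20 summing to 1.
#' @export
backgroundFrequencies <- function() .RR_BACKGROUND / sum(.RR_BACKGROUND)

# split a sequence string into its letters
.seqLetters <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# BLOSUM62 loaded once from Biostrings
.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# longest run of TRUE in a logical vector
.maxRun <- function(x) {
  if (!length(x) || !any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}
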