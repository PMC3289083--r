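---
title: "Predicting ATP-binding residues from sequence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting ATP-binding residues from sequence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

ATP binds a large fraction of known protein structures, and the residues that
contact it are valuable annotation targets for function prediction and drug
design. Structures with bound ATP are scarce relative to sequences, so the
task here is sequence-based: given a protein chain plus per-residue tracks
that standard external predictors derive from sequence alone — a PSI-BLAST
evolutionary profile (PSSM), predicted three-state secondary structure,
predicted relative solvent accessibility (RSA) and predicted backbone
dihedrals — classify every residue as ATP-binding or not, with a calibrated
probability.

ATPbindR implements the complete workflow: reference-label generation from
protein–ligand complexes, a windowed feature encoder, correlation-based
feature ranking with best-first forward selection, an SVM with probability
calibration and an MCC-maximizing decision threshold, reference baselines, a
disjunction consensus, the per-residue/per-sequence evaluation protocol, and
a synthetic-data generator that makes every stage testable without any
external download.

## Reference labels

A residue is labeled ATP-binding when the minimum distance between any of
its non-hydrogen atoms and any non-hydrogen atom of a bound ATP molecule is
strictly below 3.9 Å (`annotateBinding()`, PDB input via bio3d). Hydrogens
are excluded on both sides, detected from the element field with an
atom-name fallback; alternate conformations keep the first altloc; modified
residues map to their parent amino acid where a standard mapping exists and
to `X` otherwise. All ATP copies in a file are measured against every chain,
so ligands at chain interfaces annotate both partners.

Dataset redundancy is reduced with greedy identity clustering
(`reduceRedundancy()`): chains sorted by decreasing length join an existing
cluster when their global-alignment identity to its representative exceeds
40% (Needleman–Wunsch under BLOSUM62, gap open 10 / extend 1; identity =
exact matches over the shorter length), otherwise they found a new cluster.
This reproduces the identity ceiling itself rather than any particular
clustering tool's internals.

## The feature representation

Every residue is encoded from a sliding window of size 17 centered on it
(`encodeChain()`), producing these fixed groups:

| group | count | content |
|---|---|---|
| `pssm` | 180 | normalized PSSM, symmetric z-averaging (below) |
| `pss` | 51 | H/E/C probabilities at all 17 positions |
| `rsa` | 17 | RSA at all 17 positions |
| `dihedral` | 34 | phi, psi at all 17 positions, divided by 180 |
| `aagroup` | 36 | four AA-group indicators, z-averaged |
| `terminal` | 1 | 1 for the first/last 3 residues of the chain |
| `segment` | 6 | helix/strand/coil run indicators on the window flanks |
| `consA/B/C` | 17 each | three conservation scores at all 17 positions |
| `colloc` | data-dependent | screened collocated AA-pair presences |

Raw PSSM log-odds scores `x` are mapped into (0, 1) by the base-2 logistic
`1/(1 + 2^-x)`. The 17×20 window values are then compressed by symmetric
averaging: for offsets `z = 0..8`, `g(z) = (f(i+z) + f(i-z)) / 2`, which
halves the dimensionality to 9×20 = 180 while preserving the profile's
symmetric neighborhood information. The four amino-acid groups (hydrophobic
A/C/I/L/M/V, negatively charged D/E, positively charged H/K/R,
carboxamide-containing N/Q) are encoded as binary membership tracks
compressed by the same z-averaging, giving 4×9 = 36 features — the encoding
that reproduces the group's standard dimension; `X` belongs to no group.

Secondary-structure segment indicators are computed on the 8 residues
immediately flanking each side of the window (a literal reading of "left and
right of the window"): a side's helix indicator is set when it contains ≥ 4
consecutive helix-state residues, strand when ≥ 3 consecutive strand-state
residues, and coil exactly when both are 0.

Conservation scores are computed from the PSSM's weighted-frequency block —
the only per-position amino-acid distribution available from sequence input.
Score A is the Shannon entropy; B is the relative entropy (Kullback–Leibler
divergence) against the Robinson–Robinson background; C is the
Jensen–Shannon divergence against the same background. The package treats
the exact choice of the two background-aware scores as a design decision:
any standard background-aware conservation functional behaves near
identically in this role, so relative entropy and JSD were fixed once and
documented.

**Window padding.** Positions outside the chain contribute neutral values:
0.5 for normalized PSSM (the image of a zero log-odds score), coil for
secondary structure, 0 for RSA, scaled dihedrals and indicators, `log2(20)`
(the uniform-distribution entropy, i.e. maximally unconserved) for
conservation A and 0 (background-like) for B and C. Neutral padding avoids
fabricating signal at chain ends.

**Collocated pairs.** All 20×20×10 = 4000 combinations of (central residue,
partner residue, signed offset in ±1..±5) are screened on training chains
only: each candidate's 2×2 contingency of pair presence against the binding
label, over all training residues, is tested with a two-sided Fisher exact
test, and pairs with p < 1e-6 become binary presence features. Fisher's
exact test is used rather than a chi-square approximation because the
surviving pairs live deep in the tail where the approximation is poorest.
Presence (not occurrence count) is used as the feature value — the binary
reading of pair "frequency" at a single residue. The screen is re-run inside
every training partition, never on held-out chains.

## Selection, training, calibration

Folds are always dealt at chain level (`makeFolds()`), never residue level,
so residues of one chain can never straddle a train/test boundary.

**Ranking.** Features are ranked by point-biserial correlation with the
binding labels — computed per fold on that fold's training set and averaged
as |r| over folds (negatively associated features are equally useful to a
linear SVM). Ties break by column name for determinism.

**Best-first forward selection.** A single pass over the ranked list: each
candidate joins the selected set only if the mean held-out AUC of a linear
SVM (C = 1) under chain-level CV improves strictly — with tolerance 1e-6,
so float noise cannot masquerade as improvement — over the best so far,
starting from the no-information baseline of 0.5.

**Parameterization.** `svmParameterize()` performs the two-stage search:
shape first at C = 1 (polynomial degree over 1..5; RBF gamma over powers of
2 in [2^-7, 2^1], a standard range since the shape grid is otherwise
unconstrained), then cost over consecutive powers of 2 in [2^-3, 2^5], each
candidate scored by mean held-out AUC. The SVM backend's polynomial degree
is integral, so the degree grid is the integer range 1..5. The full search
log is retained.

**Probabilities.** The package fits its own Platt-type sigmoid: a binomial
GLM of the labels on chain-level cross-validated SVM decision values. This
is the same sigmoid the SVM library fits internally for probability
output, but fitted explicitly it is deterministic under a fixed seed —
the library's internal calibration shuffles with an unseedable RNG, which
would break exact reproducibility of the pipeline.

**Threshold.** The binarization threshold is calibrated by exhaustive scan:
per fold, every unique cross-validated probability is a candidate cut under
the `>=` convention and the MCC-maximizing one is taken (smallest on ties);
the final threshold is the mean of the per-fold maximizers. Calibration uses
the held-out predictions within the training data (cross-validated, not
in-sample), avoiding the optimism of calibrating on fitted values. Class
imbalance (~4% positives) is handled by this calibrated threshold, not by
resampling: training sees the natural class distribution.

**Leakage guarantee.** In `runPipeline()`, every training-side computation —
collocation screening, ranking, selection, parameterization, Platt fit and
threshold calibration — is confined to the training chains of the current
outer fold, with its own inner chain-level folds. Altering held-out labels
provably changes nothing on the training side; the test suite asserts this
by poisoning held-out labels and comparing the full selection state.

## Baselines and consensus

*Alignment transfer*: the query is aligned locally (Smith–Waterman via
Biostrings, BLOSUM62, gap open 11 / extend 1) against every annotated chain
except itself; the best-scoring chain is the template (raw score is a
monotone proxy for E-value at fixed database; ties take the first in
database order) and its binding labels transfer across aligned columns.
Below a score floor (default 50) the method abstains with an all-zero
flagged track. The method is binary-only: its probability track is NA.

*Conservation baseline*: external per-residue conservation scores are
oriented so higher = more likely binding (inverting low = conserved tracks),
min–max normalized to [0, 1] per chain, and binarized at the MCC-maximizing
threshold found on designated calibration chains.

*Consensus*: inclusive disjunction — a residue is called binding when any
component calls it, with probability the maximum of the component
probabilities; binary-only components contribute their 0/1 calls. The
operation is commutative, associative and idempotent, so all pairings and
the triple behave consistently; consensus sensitivity is never below any
component's and specificity never above.

## The synthetic generator

`simulateDataset()` emulates the statistical structure of the real task:
60 chains of 280–320 residues; 4 contiguous binding segments per chain of
2–4 residues, giving the task's ~4% positive-residue fraction (binding
residues cluster into a handful of short segments in real chains; with four
segments on a ~300-residue chain, segment lengths 2–4 are what keep the
positive fraction at 4%); integer PSSM log-odds `round(N(0,1))` with an
additive shift `delta` (default 2) at binding positions in the G/K/S/T
columns — the phosphate-loop residues, and the profile is the strongest
single input in practice, so planting the signal there makes single-group
ablations qualitatively realistic; frequencies proportional to
`background · 2^x` so conservation tracks inherit a weaker copy of the
signal; a planted G(+3)K collocation motif at segment starts; run-structured
secondary-structure probabilities; Beta(2,3) RSA; state-dependent dihedrals
(helix −63/−42, strand −120/135, coil uniform); and an entropy-based
conservation track in the low = conserved orientation.

What it does *not* emulate: real evolutionary covariance between profile
columns, genuine structural geometry (the toy complexes place an ATP-like
het group on an extended backbone purely to exercise the distance rule),
realistic alignment-transfer difficulty, or the long-tailed chain-length
distribution of the PDB. Passing tests on this generator therefore
demonstrate correctness of the machinery and recoverability of planted
signal at realistic scale and class imbalance — not real-data predictive
performance, which requires the external predictor outputs the package
consumes as inputs.

**The null.** The signal-free reference configuration is `delta = 0`
*and* `motif = NULL`: the planted motif is itself a genuine (collocation)
signal, so a "null" that keeps it is mis-specified and the pipeline would
legitimately score above chance on it. With both disabled the
cross-validated AUC sits within sampling noise of 0.5.

`simulateComplex()` writes toy PDB complexes where every labeled residue has
a non-hydrogen ligand atom at `cutoff − 0.1` and every other residue stays
at least `cutoff + 1` away, with optional exact-cutoff and hydrogen-contact
decoys probing the strict-inequality and non-hydrogen rules.

## Numerical choices

- Distances for annotation are compared as squared coordinate differences
  against the squared cutoff, so an atom placed exactly at the cutoff is
  excluded without floating-point ambiguity.
- MCC is computed with counts promoted to double (the denominator product
  overflows 32-bit integers at realistic residue counts) and is defined as 0
  whenever a denominator factor vanishes.
- The ROC curve sweeps unique score values under the `>=` convention, ties
  sharing one point, with trapezoidal area — identical to the tie-corrected
  rank-sum statistic, which the tests assert to 1e-12.
- Probability bins for the confidence analysis are twenty half-open 0.05
  intervals with a closed top bin; bin indices are rounded before flooring
  so boundary values land in the correct bin.
- The paired per-sequence comparison uses the Wilcoxon signed-rank test —
  the paired analog of the rank-sum test — with chains dropped pairwise
  when a metric is undefined, and all-zero difference vectors reported at
  the null center (p = 1). Shapiro–Wilk normality checks are reported
  alongside to motivate the non-parametric choice.

## Problem sizes and computational knobs

The pipeline's scientific constants are fixed (window 17, 5 folds, p < 1e-6,
linear C = 1 selection, 3.9 Å, 40% identity). The computational knobs in
`pipelineOptions()` bound the work at desk scale and are the package's own
defaults: forward selection examines the top 25 ranked candidates; SVM fits
during selection run on a seeded subsample of 2500 training residues and
the final model on 3500; kernel parameterization is off by default (the
default RBF kernel with gamma = 1/p, C = 1 is used) and can be switched on
where wanted. With these defaults the full 60-chain study configuration
(~18 000 residues) runs the complete cross-validated pipeline in well under
a minute per condition, and the planted-signal recovery (AUC ≥ 0.9 at
delta = 2; AUC ≈ 0.5 for the null) is robust to these knobs.

## Known limitations

- External predictors (PSI-BLAST, secondary-structure, RSA/dihedral,
  conservation scorers) are consumed as files, never executed; degraded-mode
  frequency derivation from log-odds is a documented fallback, not a
  replacement for real profile frequencies.
- The polynomial kernel degree is integral (backend constraint), so
  fractional degrees are not searched.
- Alignment transfer uses raw local-alignment score, not a true E-value;
  at fixed database this preserves template ranking but the abstention
  floor is score-scaled, not probability-scaled.
- Per-chain min–max normalization of conservation scores makes the
  conservation baseline's probabilities comparable across chains only in
  rank, not in absolute level.
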