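---
title: "Methods: sequence-based interhelical contact prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-based interhelical contact prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihrc)
```

## The problem

Alpha-helical transmembrane proteins (αTMPs) fold as bundles of
membrane-spanning helixes held together by interhelical residue contacts
(IHRCs): pairs of spatially close residues sitting on *different*
transmembrane helixes. Because solved αTMP structures are scarce, predicting
IHRCs from sequence is a practical intermediate between raw sequence and a
full 3D model. `ihrc` implements a complete, desk-scale pipeline for this
task: four sequence-derived feature families, a dual sliding-window pair
featurizer, structure-derived contact labeling, and a small one-dimensional
convolutional classifier with protein-level cross-validation.

## Per-residue feature tracks

Three tracks of length $L$ are computed once per protein:

* **E — evolutionary conservation.** The per-position information content of
  the PSSM profile, $E_k = \sum_x p_k(x)\log_2\!\frac{p_k(x)}{1/20}$ (bits),
  against a uniform background. A fully conserved position scores
  $\log_2 20 \approx 4.32$ bits; an uninformative one scores 0. When a
  PSI-BLAST ASCII PSSM carries its information column we use it verbatim;
  otherwise the implied distribution is recovered from the log-odds scores
  (treated as half-bit units, the usual ASCII convention). When only an MSA
  is available, `pssm_from_msa()` computes the information content exactly
  from column frequencies (no pseudocount) and uses a single pseudocount
  only for the integer log-odds, so the conserved-column closed form is
  exact.
* **T — digitized topology.** The membrane topology string over
  `{H, i/I, o/O}` is mapped `H → 2`, `o → 1`, `i → 0`. The labels are
  arbitrary but frozen; any injective relabeling is equivalent up to
  retraining.
* **R — within-helix relative position.** Non-helix residues get $-1$.
  Helixes are numbered from the N-terminus; odd-ordinal helixes are numbered
  $1, 2, 3, \dots$ N→C and even-ordinal helixes $1, 2, 3, \dots$ C→N.
  Because consecutive transmembrane helixes cross the membrane in opposite
  directions, residues with similar $R$ on neighbouring helixes lie near the
  same membrane face. Two numbering conventions are conceivable (per-helix
  reversal vs. one global C-terminal renumbering); we implement
  the per-helix one, under which $R$ is a membrane-depth coordinate —
  the property that makes the feature informative — and each helix's values
  are exactly $\{1..\text{len}\}$, a tested invariant.

## Evolutionary covariation

The pair feature $C_{i,j}$ is computed from the alignment columns by one of
three correlated-mutation statistics:

* **MI**, plug-in mutual information in bits, no pseudocounts; zero cells
  contribute zero.
* **OMES**, $\sum_{x,y}(N_{xy}^{obs}-N_{xy}^{exp})^2/N$ with
  $N_{xy}^{exp}=N f_i(x) f_j(y)$ — the Fodor–Aldrich normalization, the
  canonical form in the comparison literature.
* **ELSC**, a perturbation statistic. The rows carrying the modal residue of
  column $i$ (ties broken alphabetically) form a subset of size $n$; for
  each residue type $y$ of column $j$ with full-column count $N_y$ and
  subset count $n_y$, the score is
  $-\ln\prod_y \binom{N_y}{n_y}\big/\binom{N_y}{m_y}$, where $m_y$ is the
  expected subset count under proportional sampling, rounded half-up with
  largest-remainder repair so $\sum_y m_y = n$ and $m_y \le N_y$. The
  directed score is symmetrized, $(s_{i\to j}+s_{j\to i})/2$. Published
  descriptions of ELSC leave the subset and rounding conventions open; the
  variant above is pinned here for reproducibility and is verified against
  an exact binomial-coefficient oracle in the tests.

Gap handling is pairwise deletion: a row enters the counts for $(i,j)$ only
if neither column carries `-`. No sequence weighting and no average-product
correction are applied — they are deliberate extension points, not part of
the method. Per protein, the matrix is z-standardized over all defined
off-diagonal entries using the population standard deviation (always per protein,
never pooled across a dataset); a constant matrix maps to zeros.
Standardization could instead run over interhelical candidate pairs only;
all defined pairs is the default here since it makes $C$ comparable across
proteins regardless of topology, and a switch is left as an extension
point.

## The pair vector

A candidate pair $(i, j)$ is described by 31 numbers:
$V_{i,j} = (C_{i,j}, (E,T,R)_{i-2}, \dots, (E,T,R)_{i+2},
(E,T,R)_{j-2}, \dots, (E,T,R)_{j+2})$ — two windows of width 5 centred on
the two residues. Window positions outside $[1, L]$ contribute the sentinel
$(0, -1, -1)$; $-1$ is already the "not transmembrane" code of $R$, and $0$
is an uninformative conservation value. The PSSM is natively a
20-dimensional score vector per position; collapsing it to the scalar
information content keeps the pair vector at exactly 31 elements, and the
full-profile alternative is a documented extension rather than the
default. Candidate
pairs at prediction time are all interhelical H–H pairs on distinct
segments (an `all_pairs` switch lifts the restriction); training pairs
mirror prediction-time enumeration.

## Contact labeling

Ground truth comes from coordinates under three definitions: (I) minimum
heavy-atom distance strictly below 5.5 Å; (II) some heavy-atom pair within
the sum of the two van der Waals radii plus 0.6 Å (inclusive); (III)
Cβ–Cβ distance (Cα for glycine) at most 8 Å (inclusive). Definition I is
the default, being the most restrictive. Boundary semantics are a
convention: definition I is strict, II and III inclusive, with the
boundary cases frozen in tests. The bundled radius table
is a compact Li–Nussinov-style set: element defaults (C 1.70, N 1.55,
O 1.52, S 1.80, P 1.80 Å) refined by a few backbone atom-name classes;
unknown atom names fall back to the element radius, unknown elements are an
error. Under definition III a non-glycine residue missing its Cβ is skipped
with a warning rather than aborting, which is the right behaviour for
incomplete experimental models.

## The classifier

The classifier is a fixed design: five convolutional blocks of 512,
1024, 512, 1024 and 1024 channels, each `conv(kernel 3, zero-padded to
same length) → ReLU → max-pool(width 2, stride 2)`, on the 31 × 1 input;
spatial lengths run 31 → 15 → 7 → 3 → 1 and the fifth block skips pooling
at length 1; a dense sigmoid head emits the contact probability. Blocks are
stacked sequentially (no dense skip connections). No deep-learning runtime
is assumed: convolution is implemented as three shifted BLAS matrix
products, and the analytic gradients are verified against finite
differences in the unit tests.

Training hyperparameters are free parameters of the method and are fixed
once in `model_config()`: Adam (lr $10^{-3}$), 3 epochs, batch size
128, binary cross-entropy with the positive class weighted by
$N_{neg}/N_{pos}$ capped at 50 (contact data is heavily negative), decision
threshold 0.5. The small epoch count is deliberate: the network has ~8M
parameters and the package targets single-CPU, desk-scale runs; on the
synthetic world the loss plateaus within the budget, and every seed is
threaded so training is bit-reproducible. Evaluation reports ACC,
Precision, Recall and MCC, with any zero-denominator ratio reported as 0
and flagged — the convention that makes a never-positive predictor's MCC
print as 0. Cross-validation splits at *protein* level so no pair of one
protein appears on both sides of a fold.

## The synthetic world

`synthetic_spec()` fixes a generator whose defaults are the package's
canonical test world: 200 pseudo-proteins; two antiparallel
transmembrane helixes of 5 residues at 9 Å axis separation with 4-residue
loops (sequence length 22); 64-row alignments; planted couplings with
`p_couple = 1`. Helix geometry is ideal: 1.5 Å rise and 100° twist per
residue, Cα on the canonical 2.3 Å helical ring, and a single
pseudo-side-chain atom 1.5 Å further out radially (a one-atom stand-in for
a rotamer). Each helix draws a random azimuthal phase, so the residues
facing the neighbouring helix — and hence the contact set — differ between
proteins; without this the classifier could memorize a fixed positional
pattern instead of reading the covariation signal. Background alignment
columns are i.i.d. draws from database-like residue frequencies (so
conservation is non-degenerate); each planted pair maps column $a$ to
column $b$ through a fixed residue bijection with probability `p_couple`.
In the end-to-end training set the couplings are planted exactly at the
definition-I contact pairs of the generated bundle, so the mapping the
classifier must learn exists by construction.

What the generator does *not* emulate: rotamer packing, membrane physics,
phylogenetic correlation between alignment rows, alignment gaps (gap
handling is exercised by dedicated unit tests instead), and the shallow,
biased alignments of real membrane-protein families. A green
signal-recovery test therefore establishes that the implementation wires
the features to the classifier correctly and can recover a planted signal
— it does not establish accuracy on real membrane proteins, where
alignment depth is the binding constraint.

## Numerical and design choices

* Depth matters for ELSC: with perfectly coupled pairs the planted pair is
  reliably the matrix maximum for MI and OMES from ~20 rows, but ELSC needs
  roughly 48; the default world uses 64 rows.
* `i`/`j` indices are 1-based everywhere, matching PDB numbering and R
  idiom; the output files are 1-based by contract.
* In the matrix output file, unscored upper-triangle cells print `0` and
  the diagonal/lower triangle `-`; these fill characters are a convention
  of this package, pinned here and round-tripped by the readers.
* Model checkpoints are plain text (`dput` with hex floats), so a saved
  model survives source-only distribution and restores bit-identically.
* Ties in the max-pool route the gradient to the earlier position; Adam
  uses the standard bias correction; He initialization throughout.

## Limitations

The package predicts contacts only between predicted transmembrane helix
segments; topology prediction itself, profile search against sequence
databases, and the direct-coupling methods used as external baselines
(PSICOV, CCMpred and relatives) are out of scope — though an externally
computed covariation matrix can be injected through the TSV interface.
Real-data performance depends on alignment depth and topology quality in
ways the synthetic world deliberately does not model.
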