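---
title: "Linking coevolving residue sectors to correlated motions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking coevolving residue sectors to correlated motions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevodyn)
```

This vignette is the package's own account of its models, parameters,
numerical choices, and limitations. The running biological context is
dihydrofolate reductase (DHFR): a family with a well-characterised mobile
active-site loop (the Met20 loop), a global hinge motion between the
adenosine-binding and loop subdomains, and a naturally occurring
double-proline loop variant in the human enzyme — but nothing below is
specific to DHFR.

## The question

Statistical coupling analysis (SCA) finds groups of alignment positions
that coevolve across a protein family. Dynamic cross-correlation (DCC)
matrices from molecular dynamics find groups of residues that move
together in one protein. The package's central statistic asks: do residue
pairs that share a coevolving group also share correlated motion, beyond
what trivially-close residues would show?

## Alignment processing and weighting

`preprocess_alignment()` applies four filters in a fixed order: columns
gapped in the chosen reference sequence are dropped (and the surviving
columns acquire reference residue numbering), then columns with gap
fraction above `max_gap_frac_col` (default 0.2), then sequences with gap
fraction above `max_gap_frac_seq` (default 0.2), then sequences whose
fractional identity to the reference falls below `min_sid_to_ref` (default
0.2; raising it to 0.4 biases the retained family toward the reference's
subfamily, which is how a human-centred rerun of a bacterially-anchored
analysis is done). The order matters only for reproducibility; it is fixed
so that two runs with the same inputs give identical outputs, and
re-applying the function with the same parameters is a no-op (the existing
position map is preserved).

Fractional identity between two aligned rows is defined as matches divided
by the number of columns where at least one row is non-gap. This choice
avoids inflating identity for gappy pairs and is stated explicitly because
different packages disagree here.

`sequence_weights()` down-weights redundancy: sequence *s* gets weight
1/(number of sequences at ≥ 80% identity to *s*, itself included), and the
effective number of sequences is the sum of weights. Duplicating every
sequence leaves the effective number unchanged, which the tests assert.

## The coupling matrix

Positional frequencies are weighted and regularised with a pseudocount
`λ = 0.03`, blended as `(1 − λ) f + λ/21` over the 21-letter alphabet
(20 residues + gap). Conservation is the relative entropy
`D_i = Σ_a f_i(a) ln(f_i(a)/q(a))` against a fixed proteome-wide background
`q` (shipped as `AA_BACKGROUND`, overridable), extended with the
alignment's mean gap frequency for the gap symbol. The coupling matrix
entry for positions *i, j* is the Frobenius norm over residue pairs (gap
excluded, so gap covariation cannot drive sectors) of the covariance
tensor `f_ij(a,b) − f_i(a)f_j(b)`, each element reweighted by the
conservation gradients `φ_i(a) = ln[f(1−q)/(q(1−f))]`. The pseudocount
keeps `f` strictly inside (0, 1), so the gradients are finite without
further clipping.

## How many components, and which positions

`sca_select_k()` compares the real eigenspectrum with spectra of
column-shuffled alignments (each column's residues permuted independently,
destroying inter-column coupling while preserving per-column conservation
and the sequence weights): `k` is the number of real eigenvalues exceeding
the largest eigenvalue seen across randomisations (default 10 shuffles).
On alignments of i.i.d. columns this yields `k = 0` in the large majority
of runs, and `k` grows with planted coupling strength; both behaviours are
exercised in the tests.

`sca_decompose()` rotates the top-`k` eigenvectors with a symmetric
FastICA (logcosh contrast), implemented in-package. ICA is initialised
from a seeded random orthogonal matrix; on the rare non-convergence the
fit restarts with a new derived seed up to five times before erroring.
Component signs are fixed so each component's largest-magnitude loading is
positive, and components are ordered by their eigenvalue share
(`Σ_m W²_jm λ_m`), with ties broken by position-index order — all so that
a seed fully determines the output.

`assign_positions()` fits a t location-scale distribution to each
component's loadings by direct likelihood optimisation on unconstrained
transformed parameters (location, log scale, log degrees-of-freedom); the
heavy tail lets the planted/true sector positions sit in the tail without
dragging the bulk fit. Positions above the fitted quantile at
`cutoff_p = 0.95` are candidates; a position claimed by several components
goes to the one where its loading is largest (ties to the lower component
index), so components are disjoint by construction. If the fit fails the
empirical quantile is used, with a warning.

## Trajectories, superposition, and DCC

Trajectories are multi-model PDB files; models become frames and every
model is validated against the first (same atom names, residues, order)
before parsing, so a corrupt frame is reported by index. Superposition is
the least-squares rigid-body (Kabsch) fit onto a reference frame, fitted
on α-carbons by default; the test suite checks it against an independent
quaternion-method implementation. The DCC uses displacements about the
time-mean structure (not the first frame), the standard convention:

`DCC(i,j) = ⟨Δr_i·Δr_j⟩ / sqrt(⟨|Δr_i|²⟩⟨|Δr_j|²⟩)` on one atom per
residue (α-carbons by default). A residue with exactly zero fluctuation
makes the normalisation undefined and is a hard error naming the residue.

Note that superposition itself distorts correlations: fitting each frame
absorbs a little internal motion into the removed rigid transform. The
synthetic trajectories are generated in a common frame, so the analytic
comparison is done without fitting; fitting is exercised separately by the
rigid-motion invariance checks.

## Structural observables

* **Hinge distances** — per frame, the mean α-carbon distance over a pair
  set. The shipped presets follow the published DHFR choices: wild-type
  *E. coli* pairs 22/23/24–53, the N23PP/S148A mutant 22/23/25–54 (the
  loop insertion shifts the partners), human 24/25/27–66. The summary
  variance is the population variance; internal distances make the series
  rigid-motion invariant.
* **χ1 dihedrals** — signed N–CA–CB–γ torsion in (−180°, 180°], IUPAC
  sign convention, γ resolved as the first present of OG, OG1, SG, CG,
  CG1, CG2.
* **Frame partitioning** — top or bottom fraction (default 0.25) of
  frames by any per-frame scalar, ties broken by frame index. The default
  fraction is a package choice; no published threshold exists, and any
  open/closed classifier can be plugged in as the metric.
* **Contact mask** — pair excluded if the minimum heavy-atom distance in
  a chosen frame is ≤ 5 Å or the residue numbers differ by ≤ 2. The
  distance is measured on the experimental starting structure by
  convention (frame 1); a Cα–Cα variant is available. Enlarging the
  cutoff never unmasks a pair.

## Pair categories and the rank test

After dropping masked pairs and renumbering trajectory residues onto
reference numbering (piecewise offsets; the N23PP insertion is
`renumbering(after = 23, offset = -1)`, mapping trajectory residue 24 to
reference 23 — note the map is deliberately non-injective at the inserted
residue itself), each retained pair i < j gets exactly one primary label:
"IC k" when both residues belong to component k, otherwise "Not in same
IC". Two overlapping indicators complete the published category set:
"Any IC" (both residues in some component of the chosen sector union — a
parameter, since analyses differ on whether the first, conservation-like
component belongs to the sector) and "No IC" (neither residue in any
component). The partition identity |same-IC| + |not-in-same-IC| =
|retained| is asserted on every test input.

Distributions of |DCC| (absolute values by default; a signed mode exists)
are compared with a two-sided Mann–Whitney U test: exact enumeration of
the U null distribution via the Gaussian-binomial recurrence when
min(n, m) ≤ 8 and there are no cross-sample ties, otherwise the normal
approximation with tie and continuity corrections. Raw p-values are
reported to match the original presentation style, with a
Benjamini–Hochberg column added, and stars at p ≤ 0.05/0.01/0.001/0.0001.

The test treats pairs as exchangeable units. Pairs sharing a residue are
not strictly independent; on null synthetic data the measured type-I error
at α = 0.05 nevertheless sits inside the binomial band around 0.05 (the
acceptance script re-measures this at every run over 200 replicates), so
the approximation is adequate at these problem sizes.

## Motif co-occurrence

`motif_flags()` marks sequences carrying given residues (e.g. the
double-proline Met20-loop motif "PP") at given columns; a gap at a motif
column counts as absence. `motif_cooccurrence()` builds the full 2×2
contingency of motif presence against residue identity at a query column,
counting gaps as mismatch. Counts are plain sequence counts — matching how
such counts are reported in the literature — with an optional weighted
mode, and an optional Fisher exact p-value that is deliberately not part
of the core counting analysis.

## The synthetic generators

`make_msa()` plants coevolution with a latent-state model: per group, each
sequence draws one of two group-wide residue patterns; each group column
follows the pattern with probability ρ, else its background profile
(dominant residue at probability `conservation = 0.3`, rest uniform). This
was chosen over a Potts sampler because it gives exact control of
marginals and a clean null at ρ = 0 — the test surface needs known truth,
not biological realism. It deliberately omits phylogeny, indels within
groups, and realistic residue preferences, so passing recovery tests show
algorithmic correctness, not field performance on real families.

`make_trajectory()` draws per-residue displacements from a zero-mean
multivariate Gaussian with a block correlation structure, applied
independently per Cartesian axis and scaled by an amplitude (default 1 Å);
this makes the analytic DCC equal the specified correlation matrix
exactly, a closed-form oracle. Harmonic, isotropic, memoryless motion is
of course not protein dynamics; it validates the estimator, not the MD.
Non-positive-semidefinite block specifications are rejected with the
offending eigenvalue. `make_toy_structure()` builds idealised helix or
extended serine chains with enough atoms (N, CA, C, O, CB, OG) for
contact-mask and χ1 computations.

All generators are bit-reproducible given a seed (`withr::with_seed`, so
user RNG state is untouched).

## Problem sizes and numerical notes

The shipped tests and the acceptance script use 500-sequence, 100-column
alignments with two planted 8-column groups at ρ = 0.9 for sector
recovery (5 seeds), 10,000-frame trajectories for analytic-DCC
convergence (observed max error ≈ 0.017 against a 0.03 bound), 150-frame
30-residue trajectories for the 200-replicate null and 50-replicate power
studies, and exhaustive Mann–Whitney enumeration up to min(n, m) = 6.
These sizes were chosen as the smallest at which the planted effects are
comfortably inside their asymptotic regimes.

Degenerate inputs are handled explicitly: all-gap columns are excluded
from the coupling matrix with a warning; fewer than three non-collinear
fit atoms, zero-fluctuation residues, ragged alignments, missing atoms,
and inconsistent trajectory models are hard errors with the offending
item named.

## Known limitations

* Numeric identity with the reference SCA implementation (pySCA) is a
  validation goal, not a guarantee: the package follows the published
  definitions, but randomisation details (ICA initialisation, shuffle
  draws) differ.
* The MD side consumes trajectories; it does not produce them. Frame
  ranges, imaging, and solvent handling are upstream concerns.
* Reproducing published per-category DCC averages for real proteins
  requires the original trajectories and alignment snapshots; the package
  instead demonstrates the statistic's correctness, size, and power on
  planted ground truth.
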