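---
title: "Detecting ensemble molecular mimicry from thermodynamic profiles"
author: "emmtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting ensemble molecular mimicry from thermodynamic profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Antibody cross-reactivity between proteins that share neither sequence nor
structural similarity is hard to explain with the classical picture of
rigid-body epitope recognition. One proposed mechanism — ensemble
molecular mimicry — holds that two such proteins can nonetheless populate
thermodynamically similar conformational states, so that an antibody
raised against one can bind the other. The binding free energy is split
conceptually into an interfacial term and a conformational term; this
package computes proxies for the conformational term from sequence alone
and asks whether they track relative binding affinities measured on
proteome microarrays.

`emmtools` implements the complete computational chain:

1. **Thermodynamic profiles.** Every residue of a protein receives eight
   descriptors — {dG, dH_ap, dH_pol, TdS_conf} (kcal/mol) for the native
   and the denatured state of the ensemble.
2. **Thermodynamic environments (TE).** Per-state k-means clustering of
   the 4-D descriptor vectors defines 8 environments per state; a profile
   becomes a pair of strings over an eight-letter numerical alphabet.
3. **eTFR alignment.** The TE-encoded profile is aligned gaplessly against
   an amino-acid sequence in every full-containment register, scored by an
   environment-by-amino-acid substitution matrix, and converted to a
   p-value under a calibrated extreme-value null. The reported
   significance is `S = -log10(p_native) - log10(p_denatured)`, maximised
   over registers.
4. **FVC.** Fragment Vector Comparison computes the cosine similarity
   between all pairs of 8L-dimensional flattened profile windows of
   length L, giving a local-similarity background and the weight
   `f = M/N` (fraction of in-register windows with cosine above a
   cutoff), which scales the full-length significance to `S * f`.
5. **Correlation pipeline.** Summed native+denatured chip Z-scores are
   correlated (Pearson) against S, against S × f, and against a
   Smith–Waterman/BLOSUM62 percent-identity control.

## The surrogate descriptor predictor

The published per-residue energetic predictor is a trained
machine-learning model whose parameters are not public. `emmtools`
therefore ships a transparent surrogate with the same interface: a
20-row propensity table (one row per amino acid, eight descriptor
columns) smoothed along the chain by a symmetric window mean. The
packaged table was drawn once from normal distributions with realistic
magnitudes (native dG centred at 1.5 kcal/mol, enthalpies of a few
kcal/mol with apolar and polar terms of opposite sign, small entropy
terms; denatured-state values centred near zero) at a recorded seed, and
is stored as a versioned TSV. Real predictor output can be substituted at
any time through `read_profile_tsv()` — every downstream algorithm is
agnostic to where the profile came from. The surrogate makes the full
chain exactly testable: profiles are deterministic, cheap and reproducible.

The smoothing window default is 7 residues (odd, edge-truncated,
1-based, both window ends inclusive), reflecting that local folding
stability is a property of a residue's neighbourhood rather than a single
position. `window = 1` reduces to a table lookup.

## Environment fitting and encoding

Descriptors are z-scored per dimension (using training-set mean and SD)
before clustering and assignment; without this, the descriptor with the
largest numeric range would dominate the Euclidean metric. Whether the
published environment construction standardises first is not documented,
so the choice is recorded here as ours. Clustering is k-means with
k-means++ seeding, Lloyd iterations, and ten restarts (configurable, cap
100); the best fit by total within-cluster sum of squares wins, and
centroids are stored in lexicographic order so that the environment
alphabet is stable for a fixed seed. Assignment takes the nearest
centroid, with exact ties resolved to the lowest index.

## The substitution matrix and its null model

The environment-by-amino-acid substitution matrix is a log-odds matrix
built from co-occurrence counts in a profile database:
`score[e, a] = log2 P(e, a) / (P(e) P(a))` with a pseudocount (default
1.0) in every cell. Uniform co-occurrence gives exactly zero everywhere,
and the expected score under independence is non-positive — the standard
requirement for an extreme-value scoring regime.

Raw register scores are calibrated against shuffled pairs: environments
drawn i.i.d. from the database environment frequencies, residues i.i.d.
from a chosen composition. For each length pair (m, n) in the calibration
grid, the best-register score over `n_shuffles` pairs is fitted to a
Gumbel by the method of moments; the location is regressed on ln(mn)
(`mu = a + b ln(mn)`), and the scale β is the across-grid mean.
p-values are `1 - exp(-exp(-(raw - mu)/beta))`, floored at 1e-300 so
negative logs stay finite. Significance logarithms are base 10.

Two design points deserve emphasis:

* **The calibration grid fixes the query length.** The location of the
  best-register score has two components: a drift proportional to the
  *shorter* member's length (the per-position expected score is negative)
  and an extreme-value growth with the *register count* (≈ the length
  difference). A law linear in ln(mn) describes the second component
  well, but not the first. The default grid therefore holds m = 100 and
  varies n over 300–1200; within that design the law fits, the slope b is
  positive, and fresh-shuffle p-values are close to uniform. Queries of
  very different length than the calibrated m are only approximately
  calibrated — which is why `run_emm_pipeline()` calibrates a null per
  query by default, over the observed dimensions of that query's own
  pairs, the same per-query practice used in fold-recognition database
  scans. Extrapolating a single null to a single far-off length pair is
  the hardest case and should be avoided.
* **Gumbel is an approximation.** Register sums are approximately normal,
  and maxima of normal variables approach the Gumbel limit slowly
  (at a 1/ln k rate in the number of registers k). At a few hundred
  registers the residual shape error is a Kolmogorov–Smirnov distance of
  roughly 0.02–0.04 even for a perfectly estimated Gumbel. The test suite
  checks uniformity of fresh-shuffle p-values across the calibration
  design and the empirical type-I error rate at the 5% level.

The shuffle null preserves marginal composition only (no dipeptide
structure); registers are full-containment only, so the register count is
exactly |m − n| + 1 and ties across registers break to the lowest
offset.

## FVC and the S × f weighting

FVC operates on raw descriptor values, not environment indices. Windows
are flattened residue-major, each residue contributing its four native
then four denatured descriptors; the flattening round-trips exactly. The
cosine is clamped to [−1, 1] against floating-point drift, zero-norm
fragments are excluded with a count, and the full score population for a
window length L is retained as the background distribution
((L_A − L + 1)(L_B − L + 1) scores).

A published epitope alignment register is tested by extracting the single
cosine at that register and comparing it with the arithmetic mean of the
background (the published box-plot convention marks the average, not the
median). Across a panel of epitopes, the count above average is scored
with an exact binomial upper tail (`binomial_tail()`); with 9 of 11
above average the tail probability is 67/2048 ≈ 0.033 < 0.05.

The weight restricts FVC to the windows in the eTFR register: N in-register
window pairs, of which M have cosine strictly greater than the cutoff, so
f = M/N ∈ [0, 1] and S × f can only shrink the significance. The default
cutoff is 0.95 with window L = 20; the cutoff is exposed because the
source material is internally inconsistent between 0.95 and 0.99, and the
epitope window lengths in published alignments span 9–25 residues. When
the overlap is shorter than L, f is undefined and reported as missing;
missing-f records are excluded from (not imputed into) the weighted
correlation.

## The correlation pipeline

Chip measurements carry a native and a denatured Z-score per protein;
their sum is the affinity proxy. Where the denatured measurement is
missing the native value is substituted (flagged), mirroring the handling
of the one antibody whose denatured chip was unavailable. The correlation
is Pearson's r with a two-sided t-test on n − 2 degrees of freedom,
together with the least-squares slope and intercept; the test form is not
stated in the source material, and Pearson-with-t is the conventional
reading of "linear correlation". The sequence-identity control replaces
an external FASTA36 dependency with Smith–Waterman under BLOSUM62
(gap open 11 / extend 1) via Biostrings; ties resolve deterministically,
and alignments with no positive-scoring path report identity 0 over an
empty span. The gap penalties are recorded in the output and
configurable; the control's conclusion (no identity-affinity correlation)
is insensitive to them on the synthetic fixtures.

## What the synthetic generators emulate — and what they do not

`simulate_fixture_bundle()` reproduces the *statistical shape* of the
study: 7 virus antigens × 10 reported human binders (70 pairs), protein
lengths 100–1200 residues, i.i.d. residue composition, and chip tables
whose summed Z-scores depend linearly on significance with Gaussian
residual scatter (`z = alpha S + eps`). `noise_for_r_squared()` solves
for the residual SD that plants a requested population r²; the regime of
interest is r² ≈ 0.10 at n = 70, where the sample r² has expectation
≈ ρ² + (1 − ρ²)/(n − 1) ≈ 0.11. Planted-fragment pairs
(`plant_fragment()`) copy a descriptor block verbatim between profiles,
creating a register with cosine exactly 1 — the synthetic analogue of a
shared epitope.

The generators do **not** emulate: real energetic structure along the
chain (the surrogate's descriptors are exchangeable between sequence
neighbourhoods with the same composition), homology between proteins,
heavy-tailed or spatially structured chip noise, or any relationship
between a protein's thermodynamics and its chance of being spotted on a
chip. Passing tests therefore demonstrate the correctness and calibration
of the algorithms under the stated generative model, not the biological
effect size in real proteomes.

## Numerical choices and degenerate inputs

* p-value floor 1e-300 (keeps −log10 finite); cosines clamped to [−1, 1].
* Ties: centroid assignment → lowest index; register maximisation →
  lowest offset; FVC match ordering → descending cosine, then both start
  coordinates; M counts cosines *strictly* greater than the cutoff.
* Ambiguous FASTA letters (B, J, O, U, X, Z, stops, gaps) are stripped
  with one summarising warning by default, or rejected with
  `ambiguous = "error"`.
* Empty files, empty records, out-of-range registers and offsets,
  missing native Z-scores, f outside [0, 1], zero-variance correlation
  inputs, and degenerate (zero-variance) null-score distributions are
  all hard errors naming the offender.
* Single-product calibration grids fit a constant location (b = 0).

## Problem sizes used by the shipped tests

The suite fits environment models on corpora of ~14 proteins of 80–260
residues (a few thousand residues per state), calibrates nulls with
1000–2000 shuffles per grid point, checks uniformity on 2000 fresh
shuffles, runs 100-decoy self-recognition scans, and recovers the planted
r² over 1000 simulated 70-pair chip tables. These sizes were chosen so
that every statistical check has conventional power while the whole suite
remains quick to run; all of them scale up linearly through function
arguments.

## Known limitations

* The surrogate predictor is compositional: it cannot reproduce
  long-range energetic features a trained predictor would assign, so
  absolute S values are not comparable with published ones; only the
  machinery that consumes profiles is.
* The ln(mn) location law holds per query length; one shared null across
  queries of very different lengths mis-centres S (see above).
* The Gumbel tail is approximate at small register counts (near-equal
  length pairs); p-values there are bulk-calibrated but tail-approximate.
* FVC backgrounds for short proteins contain few scores, making the
  "above average" call coarse (a single-score background can never be
  above average).
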