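---
title: "Superposition-free ensemble analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Superposition-free ensemble analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensflex)
```

## The problem

Given many structures of one protein — crystal forms in different space
groups and ligation states, NMR model bundles, MD snapshots — we want to
know *where* along the sequence the conformation varies, whether that
variation is thermal-scale noise or a genuine switch between states, which
distant residues change together, and which members of the ensemble display
pockets the others hide. The classical route, global superposition followed
by per-atom deviations, makes every answer depend on an arbitrary choice of
reference and fitting region. `ensflex` avoids superposition altogether:
every descriptor it computes is intrinsic to the chain, so two structures
can be compared without ever being placed in a common frame.

All statistics are laid out over the columns of a user-supplied multiple
sequence alignment, with an explicit missing mask: a cell is masked when
the residue is a gap in the alignment, unmodelled in the structure, or
undefined for the descriptor (chain termini, Gly/Ala side chains, ...).
Masks only ever grow as descriptors are derived, never shrink.

## Backbone descriptors: curvature and torsion of the C-alpha trace

The backbone of a protein chain is treated as a space curve through its CA
atoms. Two local quantities characterise such a curve completely (up to
rigid motion): the curvature kappa (1/Å, non-negative — the deviation from
a straight line) and the torsion tau (1/Å, signed — the deviation from a
plane curve; its sign carries chirality, so a mirror image negates tau and
nothing else). An ideal alpha-helix has kappa ≈ 0.38 /Å and tau ≈ 0.15 /Å
at every residue; an extended strand has small kappa and large |tau|; a
hinge or loop rearrangement shows up as a local change in one or both.

### Why not spline derivatives

The textbook estimator interpolates the points with a cubic spline and
evaluates kappa = |r'×r''|/|r'|³, tau = (r'×r'')·r'''/|r'×r''|². CA atoms,
however, sample the backbone curve extremely coarsely — ~3.8 Å apart,
about 100° of helical turn per residue — and at that spacing the spline's
second and third derivatives are dominated by interpolation bias: on an
ideal helix the spline route misestimates kappa by ~40–65% and tau by
~35–40%. (That route is retained as `method = "bspline"` in
`ca_curvature_torsion()` for comparison, but it is not the default.)

### The osculating-helix estimator

The default estimator instead inverts the *discrete* geometry of the trace.
At residue *i* it measures three rigid-motion-invariant numbers from the
five CA atoms *i−2..i+2*:

* the mean chord length ℓ of the two chords meeting at *i*,
* the chord (bend) angle γ between them,
* the circular mean φ of the two virtual dihedrals spanning *i*.

A circular helix is the unique curve with constant kappa and tau, and for
points equally spaced on one these three numbers determine it in closed
form: writing g = cos γ,

cos δ = ( cos|φ| · (1 + g) − (1 − g) ) / 2

gives the turn per residue δ, from which the helix radius *a* and rise per
radian *b* follow from ℓ, and finally kappa = a/(a²+b²),
tau = sign(φ)·b/(a²+b²). The estimator is therefore *exact* on helical
arcs at any sampling density (the test suite verifies machine-precision
recovery across 12 radius/rise settings) and second-order accurate on
general curves; its only ill-conditioned regime is torsion near inflection
points (kappa → 0), where torsion is intrinsically undefined — such
residues report kappa ≈ 0 with tau masked (collinearity threshold:
bend angle < 10⁻⁶ rad).

Chains are split into maximal contiguous segments on author numbering,
breaking additionally where consecutive CA atoms are closer than 2.5 Å or
farther than 4.75 Å (outside the cis/trans peptide range). A segment
contributes only with ≥ 5 CA atoms, and the first and last two residues of
*every* segment — including the frayed ends around unmodelled stretches —
are masked, matching the 5-residue support of the estimator.

### phi/psi and the circular order parameter

`phi_psi()` computes the standard IUPAC backbone dihedrals (degrees,
(−180, 180]), masked wherever a defining atom is absent or the residues are
not consecutive. Angular variability across an ensemble is summarised by
the circular order parameter S(θ) = ‖Σⱼ(cos θⱼ, sin θⱼ)‖/n ∈ [0, 1] per
column and angle, combined as variability = 1 − (S(φ)+S(ψ))/2, so 0 means
all chains agree and antipodal angle pairs cancel completely.
Ramachandran classification is a configurable polygon lookup
(`inst/extdata/rama_regions.csv`, first match in file order, unmatched =
outlier); region conventions differ between validation schools, which is
why the polygons ship as data rather than code.

## Side-chain descriptors: sentinel atoms in a local frame

Side-chain conformation is summarised by one *sentinel* atom near the
side-chain terminus, chosen per residue type as the terminal-most atom that
X-ray crystallography assigns unambiguously (`inst/extdata/
sentinel_atoms.csv`; e.g. Asp uses CG, not the swappable OD1/OD2). For
Val/Thr/His the two candidate atoms are disambiguated geometrically: the
one with a strictly positive C–CA–CB–T pseudo-dihedral is taken, so the
choice is independent of deposited atom naming. The residue's (N, CA, C,
CB) quadruplet is superposed (proper rotation only — chirality preserved)
onto a fixed ideal reference at the origin, and the transform is applied to
the sentinel; its (x, y, z) then encode the rotameric state free of the
chain's global placement. The reference quadruplet uses ideal bond lengths
(N–CA 1.458, CA–C 1.525, CA–CB 1.530 Å), tetrahedral angles and
L-amino-acid chirality (chiral volume +2.5 ų); since every residue is
mapped through the *same* frame, any other fixed chiral frame would differ
only by a global rotation of descriptor space, to which all downstream
distances and PCA are invariant. Gly and Ala are masked.

## Per-position statistics

* **Variability** (`variability()`): per column, the mean Euclidean
  distance of each chain's descriptor tuple from the componentwise median
  tuple — on *standardised* (kappa, tau) for the backbone (so the two are
  commensurable) and on raw sentinel (x, y, z) (already in Å) for side
  chains. Columns with fewer than `min_fraction` (default 0.5) of chains
  present are masked.
* **Standardisation** (`standardise()`): z-scores over all unmasked cells
  of a matrix (sample sd), clipped at ±`cap_sd` (default 3). The cap
  exists because chains are later compared by Pearson correlation, which
  is outlier-sensitive.
* **Grouped variance** (`group_variance()`): with chains partitioned into
  groups (two functional states, or clusters of near-identical structures
  at a 1% Pearson-distance cut), each group contributes
  sᵢ = (1/nᵢ)Σⱼ(xᵢⱼ − x̄)² about the *pooled* column mean, and
  S = mean over non-empty groups of sᵢ; for the backbone
  S = S(kappa) + S(tau), additive on the variance scale, computed on the
  **raw** 1/Å matrices so the two components share units and the thermal
  baseline is not renormalised to 1 (as it would be on standardised
  values). Two open choices are fixed here and worth stating: groups are
  weighted equally (not by nᵢ), so large clusters of near-duplicates do
  not dominate, and the kappa/tau combination is additive rather than
  quadratic-mean or max.
* **Sliding-window RMSF** (`rmsf_window()`): the conventional fluctuation
  measure made superposition-local — each chain's `window` (default 5,
  odd) consecutive CA atoms are Kabsch-fitted onto the reference chain's
  window and the centre-column scatter is reported. It is the natural
  cross-check for the intrinsic descriptors.
* **B-factor normalisation** (`normalise_bfactors()`): per chain,
  iterative 3-sigma trimming of CA B-factors (stopping when nothing is
  removed or ≤ 50% remain) defines the mean/sd used to z-score *all*
  residues, keeping a few wild termini from compressing the scale.
* **Contacts** (`contact_fingerprint()`, `contact_fraction()`): one bit
  per residue — any heavy atom strictly within the cutoff of any partner
  atom (5.0 Å protein/crystal convention, 4.5 Å ligands). Partner sets are
  supplied by the user (symmetry mates are *not* generated internally);
  `partner_atoms()` builds the two common ones from the ensemble itself.

## Multivariate views

Incomplete matrices are reduced to complete ones by `select_full_matrix()`:
columns are visited in decreasing gap count (ties leftmost); a column's
gapped chains are removed unless that would push cumulative removals above
⌊mpc·n⌋ (default mpc = 10%), at which point the loop exits and every column
still containing a gap is dropped. The algorithm is deliberately simple
and non-optimal; its virtue is that it is exactly specified, and the tests
hold the implementation to an independent trace of the loop.

`nipals_pca()` implements NIPALS — sequential component extraction with
deflation — which on complete data reproduces the SVD's leading components
(asserted to 10⁻⁶ against base R's `svd` on seeded random matrices).
Columns are mean-centred only; no per-variable rescaling, since backbone
inputs are already ensemble-standardised. Loadings are oriented so their
largest-magnitude entry is positive, making signs reproducible.
`assemble_pca_variables()` interleaves per-position kappa/tau (or sentinel
x/y/z) with provenance labels (`p17_kappa`, ...) so loadings map back to
residues.

`correlated_pairs()` scores every position pair at sequence separation
≥ 30 (default) by the average across descriptor components of the
pairwise-complete Pearson correlation over chains, ranks by |r| and keeps
the top 25. The separation cutoff removes trivial through-backbone
correlation; constant columns and pairs with < 3 complete observations are
skipped. The average is of *signed* r (components pointing in opposite
directions partially cancel); ranking is by absolute value.

Chains are compared by Pearson distance (1 − r)/2 on their capped
standardised kappa/tau profiles, or Tanimoto distance on fingerprint bits
(empty ∪ empty ⇒ distance 0), and clustered by average-linkage `hclust`
with a flat cut (1% Pearson distance collects "the same structure solved
again" clusters). Trees export as Newick via `ape`; leaf order is made
deterministic by sorting chain ids before clustering.

## Distinct druggable pockets

Per-residue druggability scores (Dscore ∈ [0, 1], e.g. from Fpocket, whose
convention that all residues of one pocket share one Dscore is what makes
the algorithm work) form a chains × positions matrix. Three stages: (1)
per column keep the maximal Dscore if ≥ cutoff (default 0.9 — stricter
than the 0.7 its authors recommend for single structures, appropriate when
hundreds of ensemble members give high-scoring pockets many chances to
appear); (2) rank structures by stage-1 win count — effectively pocket
size — and keep the top t (default 5); (3) label surviving columns with
their winning structure's rank 0..t−1. All ties break on sorted chain id.
One property a user might expect does *not* hold: raising the cutoff can
*add* labelled positions when t binds, because win-count rankings
reshuffle; only the t-monotone direction is a theorem, and the tests
assert exactly that.

## The synthetic generator, and what passing tests do not show

`make_ensemble()` builds ideal-geometry chains (NeRF internal-coordinate
construction; alpha-helical φ = −57°, ψ = −47° by default, because a helix
exercises nonzero kappa *and* tau) and plants features with known ground
truth: a hinge (rigid rotation of everything past a pivot, about the local
binormal, in half the chains), a compensated loop flip (alternate
dihedrals at the loop entry and exit only, so the interior stays intrinsically
identical — the classic paired-peak signature), a rotamer switch (Ser OG
at two chi1 values), unmodelled stretches (residues deleted in a seeded
fraction of chains), and latent-variable correlated displacements.
Gaussian per-coordinate jitter (default 0.1 Å, the order of
crystallographic coordinate uncertainty) stands in for thermal noise.
Everything is a pure function of the spec including its seed; PDB output is
byte-stable.

What the generator does **not** emulate: real side-chain packing and
rotamer libraries, correlated (phonon-like) thermal motion, crystal-contact
induced strain, sequence heterogeneity beyond single-residue substitutions,
or realistic B-factor fields. Passing the recovery tests therefore shows
the statistics detect the *kinds* of signal they were designed for at
realistic noise amplitudes — not that they are calibrated on real
crystallographic ensembles.

Study conditions used by the validation suite (chosen once): hinge
recovery uses 20 chains × 60 residues, pivot 40, 30°, jitter 0.1 Å, 100
replicates; the thermal null is the same size without features, grouped by
1% Pearson clusters; correlated-pair recovery uses 100 chains × 80
positions with population r = 0.9 planted at separation 40. On matched
seeds the hinge-to-null ratio of maximal S comes out close to, but not
always above, an order of magnitude (~9–10×); the pooled-mean form of sᵢ
means grouping cannot actively suppress thermal noise — the separation
comes entirely from effect size — and kappa responds sublinearly to bend
angle, both of which temper the contrast.

## Numerical choices and degenerate inputs

* Alternate locations: highest occupancy wins, ties by file order.
* Insertion codes are part of residue identity; alignment columns, not
  author numbers, define equivalence across chains (columns are 0-based
  internally and 1-based in every file written).
* Sequence-to-alignment matching allows `X` wildcards and zero
  mismatches; unresolved residues are located through author-numbering
  gaps, so the mapping cannot slide along repetitive sequence.
* sd convention: sample (n−1) throughout.
* Zero-variance inputs: standardisation and B-factor normalisation return
  zeros with a warning; constant columns are excluded from correlation;
  Pearson distance with < 3 shared positions is undefined and the chain
  falls out of the tree into a singleton group, with a warning.
* NIPALS: convergence 10⁻⁹ on the score vector, 1000 iterations max,
  non-convergence is a warning plus a flag, never an error.

## Limitations

mmCIF input, symmetry expansion and automatic alignment construction are
out of scope by design (the alignment is an input; partner atoms for
crystal contacts are an input). Fingerprints are presence/absence only —
no interaction typing. Torsion near inflections is masked rather than
estimated. The method assumes near-identical sequences across the
ensemble; distant homologues would need alignment-quality handling this
package does not attempt.
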