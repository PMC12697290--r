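---
title: "Ensemble virtual screening: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble virtual screening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models implemented in `evscreen`, the
assumptions behind them, the parameters a user is expected to touch, and
the decisions taken where the underlying methodology admits more than
one defensible reading. It states no empirical results beyond what the
package's test suite and `scripts/acceptance.R` themselves compute.

# The screening pipeline

The package implements a two-arm virtual screen against one protein
target. The ligand-based arm filters a multi-conformer library through a
3D pharmacophore; the structure-based arm ranks the survivors with a
naive Bayes classifier fused over docking scores from several receptor
conformations. Upstream of both sits conformational analysis of the
target's crystal ensemble; downstream, fingerprint clustering picks
chemically diverse representatives from the top of the ranked list.
Docking engines are out of scope: docking scores enter as tables (CSV)
or are mocked by a user-supplied scorer.

# Crystal-ensemble clustering

## Model

Conformations are compared by C-alpha RMSD after optimal rigid
superposition (Kabsch, via the SVD of the cross-covariance matrix with
the determinant-sign correction, so reflections are never returned).
Residue correspondence uses the intersection of (chain, residue number)
labels across the ensemble — a deliberate simplification appropriate for
crystal series of one protein; no sequence alignment is attempted.

"K-means on an RMSD matrix" is formally ill-posed, since K-means needs
coordinates. The package embeds the matrix by classical
multidimensional scaling (up to `min(n-1, 10)` coordinates) and runs
K-means there. Two initialisations are tried — Ward-linkage hierarchical
centroids (deterministic) and 20 seeded random restarts — and the
solution with lower within-cluster sum of squares wins. The
hierarchical start matters: with ~10 well-separated conformational
families, purely random starts miss the planted optimum in a
non-negligible fraction of runs, which is visible as a silhouette dip at
the true K.

Cluster number K is chosen by maximising the mean silhouette
`s = (b − a)/max(a, b)` computed on the *original* RMSD matrix (not the
embedding) over a K grid of 2–14; ties break toward smaller K; singleton
clusters contribute silhouette 0 (the standard convention). When even
the best silhouette is below 0.1 the result is returned with a warning
rather than an error — a structureless matrix is an answer, not a
failure. Per-cluster representatives are medoids (the member minimising
mean RMSD to co-members), with lexicographic id tie-breaking so results
are input-order invariant.

## Parameters

* `kmin = 2`, `kmax = 14` — the evaluation grid for K (clipped to n−1).
* `n_restarts = 20` — K-means restarts per K.
* `seed` — recorded in the result; all stochastic steps derive from it.

# Pharmacophore representation and fitting

## Feature model

A pharmacophore is a set of typed spheres: kinds A (acceptor), D
(donor), H (hydrophobic), R (aromatic ring), N (negative ionizable), P
(positive ionizable), each with a centre, a tolerance radius (default
1.6 Å) and a weight (default 1), plus optional exclusion spheres. The
defaults are stated here precisely because the commercial tools that
popularised this representation do not publish theirs; 1.6 Å is a
conventional tolerance for fully diverse feature types.

Ligand feature points are perceived from the molecular graph by a fixed
rule table: donors are N/O bearing a hydrogen; acceptors are N/O with an
available lone pair (amide and pyrrole-type nitrogens excluded);
negative ionizable points sit at the centroid of
carboxylate/sulfonate/phosphonate groups; positive ionizable points at
basic amines and amidine/guanidine groups; ring features at the centroid
of each aromatic ring (chordless cycles of the aromatic-bond subgraph);
hydrophobic features at the centroid of each connected fragment of three
or more non-aromatic carbons with no attached heteroatom. Purely
aromatic carbons are deliberately excluded from hydrophobic fragments so
that benzene perceives as exactly one ring feature — the rule table is
written so that each atom's pharmacophoric role is unambiguous. The
rules are implemented as graph predicates rather than SMARTS: the
package's molecule model is its own, and a rule table in code is
testable without a pattern-matching engine.

## FitValue

For one conformer and one injective, kind-respecting assignment of model
features to ligand points, the assigned point set is rigidly aligned
onto the model (Kabsch); any placement that pushes a ligand heavy atom
inside an exclusion sphere is rejected; the score is

$$\mathrm{FitValue} = \sum_f w_f \, \max\!\big(0,\; 1 - (d_f /
\mathrm{tol}_f)^2\big)$$

with $d_f$ the post-alignment centre distance. This is the published
Catalyst-style geometric fit: bounded by the weight sum, smooth in the
displacement, and zero exactly when a feature sits on its tolerance
boundary. The reported value is the maximum over all conformers and all
assignments of size at least `min_features_to_match` (default: all
features; never below 3, since a rigid alignment needs three points).
"Flexible" fitting means best-over-provided-conformers; no on-the-fly
minimisation is done, because conformer generation is upstream of this
package.

A ligand with no valid assignment is *unmatched* and carries the exact
sentinel **−10**. The sentinel is part of the data model, not an error:
screening keeps `ceiling(keep_fraction · n)` top-ranked ligands but
never a sentinel (unless `keep_fraction = 1`), and the naive Bayes stage
gives the sentinel its own bin.

Assignment search is exact enumeration up to `cap = 1e5` assignments per
conformer; beyond that a greedy construction on internal-distance
compatibility with 2-swap refinement is used and a message notes the
fallback. All test and acceptance workloads stay inside the exact
regime.

## Complex-derived models

Deriving a model from a receptor–ligand complex is implemented as a
geometric filter, not hypothesis enumeration: a ligand feature survives
only if complementary protein context exists (polar protein atom within
3.5 Å for A/D; ≥ 3 apolar atoms within 4.5 Å for H; a basic-residue
nitrogen within 4.0 Å for N; an acidic-residue oxygen within 4.0 Å for
P; an aromatic-residue side-chain atom within 5.0 Å for R), and at most
six features are kept by descending contact count. This is an explicit
approximation to commercial complex-based hypothesis generators, which
score and enumerate candidate hypotheses; the contact distances are
conventional interaction cutoffs.

# Benchmarks

Actives are filtered by a strict Ki < 10 µM rule with allosteric
binders excluded; records without a Ki are dropped with a message —
activity filtering never throws on content. Decoys are property-matched
per active in the DUD-E spirit: windows MW ± 25 Da, ALogP ± 1, HBD ± 1,
HBA ± 2, rotatable bonds ± 2, net formal charge exact; candidates must
additionally have element-scheme Tanimoto ≤ 0.35 against *every* active;
within the eligible set the `ratio = 50` closest by window-normalised L1
distance are taken, and a pool member is reused across actives only once
the unused pool is exhausted. These windows are stated (rather than
inherited from any particular DUD-E release, which versions them) so the
behaviour is deterministic and testable; outputs will not byte-match a
decoy web service. Train/test splitting is stratified per class at 4:1
after a seeded shuffle — whether the original protocol stratified is not
documented anywhere we could follow, and stratification is the choice
that keeps class balance comparable across splits.

Chemical-space PCA z-scores the eight descriptors (ALogP, MW, HBD, HBA,
rotatable bonds, rings, aromatic rings, fractional polar surface area),
drops zero-variance columns with a warning, and fixes component signs by
the largest-absolute-loading-positive convention so plots reproduce
across platforms.

Descriptor definitions that the field leaves vendor-specific are pinned
as follows: ALogP is an atom-contribution logP with a compact
Crippen-style class table; fractional PSA is Ertl-style topological PSA
divided by an element-increment estimate of total surface, capped at 1.
Both are deterministic and monotone with the intended quantities but
*approximate*; they are suitable for matching, splitting and
chemical-space maps, not for reporting absolute logP values.

# Pose and score evaluation

Pose RMSD is heavy-atom, in-place (no re-superposition — both poses live
in the receptor frame, the standard redocking convention; superposition
is available behind a flag) and symmetry-corrected: the minimum over
automorphisms of the molecular graph that preserve element and bond
order, computed by VF2 with vertex colours (element, charge) and edge
colours (bond order). The automorphism count is capped at 10⁴, beyond
which the identity permutation is used with a warning. The top-scored
pose is the best by docking score (lower-is-better by default, ties to
the first in input order); redocking succeeds when its RMSD is within
2 Å — above that the prediction counts as failed.

The Mann–Whitney U test for active/decoy score separation uses midrank
U with tie correction. The two-sided p-value is computed by exhaustive
enumeration of all label assignments (ties included) when the pooled
sample size is at most 12, else by the normal approximation with
continuity correction. The U convention is fixed so that
$U / (n_1 n_2)$ equals the rank AUC of the first sample over the second
— the identity that links the test to enrichment.

# The naive Bayes consensus

Continuous scores are discretised per feature by equal-frequency binning
(default 16 bins) learned from the pooled non-sentinel training values;
the sentinel is its own seventeenth bin. Class-conditional bin
probabilities are Laplace-smoothed (α = 1), so a feature entirely
sentinel in one class is still usable and every prediction is finite.
Binning is the reason the −10 sentinel integrates so cleanly: no
imputation, no special-casing at prediction time.

Cross-validation is stratified k-fold (default 5); out-of-fold log-odds
are pooled and a single AUC is computed on the pooled predictions
(rather than averaging per-fold AUCs, which is noisier at these class
ratios; the source protocol says only that an AUC was computed).
Combination models — every subset of two or more receptor conformations;
four conformations give the classical eleven models — reuse one fold
assignment so comparisons are paired. Feature independence is assumed
as in any naive Bayes; scores from conformations of one target are
correlated in practice, which flattens (but in our simulated conditions
does not reverse) the gain from fusion.

Whether published single-conformation AUC figures of this kind are
train, test or cross-validated values is generally ambiguous; the
package exposes all three (fit + predict on any table, or `cv_auc`), and
its own reporting uses cross-validation throughout.

# Synthetic data: what it does and does not emulate

The generators define the study conditions for every test:

* `gen_toy_ensemble` — a shared random-coil C-alpha trace, per-cluster
  Gaussian base displacement (`between_sd`, default 5 Å per coordinate),
  per-member displacement (`within_sd`, default 0.3 Å), and a random
  rigid motion that superposition must remove. Defaults of 10 clusters ×
  7 members mirror the scale of a seventy-odd-structure crystal series.
  It emulates separation structure, not protein physics: no secondary
  structure, no correlated domain motions, no missing residues.
* `gen_toy_library` — molecules from a template grammar (seven ring
  scaffolds × up to three of seventeen substituents) with clean
  template-geometry conformers and SMILES. It spans MW, logP,
  donor/acceptor counts and charge, but its molecules are small and its
  similarity distribution narrower than a vendor library's; the decoy
  similarity ceiling therefore bites harder here than on drug-like
  collections, and benchmark tests select actives that have enough
  matchable pool members — exactly as public decoy services require.
* `gen_score_table` — class-conditional equicorrelated Gaussians on the
  docking-energy scale (lower = better), with per-class failure
  probabilities replacing values by the sentinel. Unimodal shifted
  Gaussians match the shape docking-score distributions typically show;
  heavy tails, multimodality and score-property correlations are not
  modelled.
* `gen_fit_values` — Gaussian FitValues per class with exact −10
  failures.

All generators are bit-reproducible from a seed. Passing tests on these
fixtures demonstrates the *statistical machinery* — recovery of planted
structure, analytic AUCs, sentinel semantics, determinism — not
performance on real screening data.

Problem sizes used by the test suite and the acceptance script (70
structures of 30 residues; libraries of up to 5000; score tables up to
10⁵ rows; 25–100 repeated simulations where a rate is estimated) were
chosen so that every stochastic check has comfortable statistical margin
while a full run stays a desk-scale computation.

# Numerical and degenerate-input conventions

* Kabsch requires ≥ 3 points and errors on collinear input (second
  singular value below 1e−8); the returned rotation always has
  determinant +1.
* Fingerprint hashing is 32-bit FNV-1a over sorted neighbour invariant
  tuples (one xor/multiply round per 32-bit value), folded modulo
  `nbits`; exact 16-bit limb arithmetic keeps it identical across
  platforms. Two empty fingerprints compare as Tanimoto 1 by
  convention, with a message.
* Equal-frequency bin edges collapse duplicates, so heavily tied
  features get fewer bins rather than empty ones.
* `screen_library` keeps `ceiling(keep_fraction · n)`; an all-failed
  library yields an empty result with a warning, not an error.
* Representative and medoid ties break lexicographically by id;
  top-scored pose ties break to input order. Both rules are stated so
  results are reproducible, not because the alternatives are wrong.
* PAM (k-medoids) is used for hit clustering on 1 − Tanimoto distance;
  its BUILD+SWAP search is deterministic, so the seed in the interface
  is recorded metadata.

# Known limitations

* No stereochemistry, no protonation-state enumeration, no conformer
  generation: conformers and protonation are inputs.
* Aromaticity is read from input (aromatic bond order 4 in SDF,
  lowercase SMILES); Kekulé-only input is not re-perceived.
* ALogP and fPSA are approximate contribution models (see above).
* The pharmacophore assignment search is exact only up to the stated
  cap; the greedy fallback can underestimate FitValue in pathological
  high-symmetry cases.
* The final, historically manual step of choosing compounds from the
  top clusters is replaced by a deterministic rule (best log-odds per
  cluster); a medicinal chemist's judgement is not reproducible and is
  documented as out of scope.
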