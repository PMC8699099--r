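---
title: "Structure-based comparison and clustering of protein domain families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based comparison and clustering of protein domain families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domalign)
```

## The problem

Protein families often conserve three-dimensional structure long after
sequence similarity has decayed beyond detection. The KCTD family (25 human
proteins sharing an N-terminal BTB/POZ oligomerization domain) is a textbook
case: the regions C-terminal to the BTB show essentially no cross-family
sequence similarity, yet most of them fold into a structurally similar
domain (a single β-sheet flanked by a few helices, the "KCTD-CTD"). With
predicted models now available for every member, those relationships can be
quantified purely from coordinates.

`domalign` implements that workflow at the Cα level:

1. read predicted or experimental structures into a uniform Cα-trace model
   carrying per-residue pLDDT confidence;
2. split chains into confident folded domains versus low-confidence
   disordered regions, or slice expert-curated domain ranges;
3. align every pair of domains by distance-matrix ("elastic") comparison and
   calibrate the score into a Z;
4. cluster the Z matrix by average linkage into a structure dendrogram
   (Newick), and project it into two dimensions by correspondence analysis;
5. superpose predicted models on experimental structures (Kabsch) to
   quantify prediction accuracy.

Everything operates on Cα traces only. Distance-matrix scoring, RMSD and
domain segmentation are backbone-level notions, so retaining side chains
would add parsing burden without changing any result.

## The elastic score and its Z calibration

Two domains A and B are compared through their intramolecular Cα–Cα
distance matrices $d^A$, $d^B$. For a sequential residue pairing
(alignment) with aligned positions $i, j$, the score is

$$
S=\sum_{i,j}\begin{cases}
\theta_E & i = j\\[2pt]
\left(\theta_E-\dfrac{|d^A_{ij}-d^B_{ij}|}{d^\ast_{ij}}\right)
\exp\!\left[-\left(\dfrac{d^\ast_{ij}}{\alpha}\right)^2\right] & i \neq j
\end{cases}
\qquad d^\ast_{ij}=\tfrac12\,(d^A_{ij}+d^B_{ij})
$$

with $\theta_E = 0.20$ (a 20 % relative-deviation tolerance) and
$\alpha = 20$ Å (a Gaussian envelope that down-weights long-range pairs).
These are the constants of the published Dali scoring function; matched
substructures contribute positively, distance disagreements beyond the
tolerance are penalized.

Raw scores grow with domain size, so they are calibrated against the mean
score of unrelated structure pairs of average length
$\bar L = \sqrt{L_A L_B}$:

$$
Z = \frac{S - m(\bar L)}{0.50\, m(\bar L)},\qquad
m(\bar L) = 7.95 + 0.71\bar L - 2.59\times10^{-4}\bar L^2
          - 1.92\times10^{-6}\bar L^3 \;(\bar L \le 400),
$$

continued linearly beyond 400 with the slope at 400. `Z >= 2` is treated as
detectable similarity — the same convention as the dashes in published
Z-score tables, whose smallest printed value is 2.0. Self-alignments need no
search: the identity pairing gives the closed form
$S_{self} = 0.2\,n + 0.2\sum_{i\ne j}\exp[-(d_{ij}/20)^2]$, which the
aligner's self branch returns exactly.

## The alignment search

Finding the best sequential pairing is a hard combinatorial problem; the
search is heuristic with three stages, all deterministic given the seed:

* **Seeding.** Candidate anchor pairs come from (a) hexapeptide fragment
  pairs whose 6×6 distance submatrices agree best (all 15 intra-fragment
  distances compared), deduplicated so seeds do not pile up on one diagonal,
  and (b) matched secondary-structure elements of the same type. The best
  `n_seeds = 20` by elastic score are kept.
* **Dynamic-programming growth.** For the current pairing, each candidate
  pair (a, b) gets an incremental compatibility (the elastic-score change
  from adding it); a monotone matching maximizing total compatibility is
  found by dynamic programming with free skips, and the cycle
  (compatibility → DP → rescore) repeats up to `dp_rounds = 3` times or
  until the score stops improving.
* **Simulated annealing.** Shift, extend and trim moves on contiguous
  aligned blocks, Metropolis-accepted under a geometric cooling schedule
  (`anneal_steps = 2000`, temperature 2 → 0.05 in score units). The
  best-ever alignment is kept, so the result never falls below the best
  seed.

The search considers sequential (order-preserving) alignments only.
Non-sequential alignments are rare between compact homologous domains,
which is the use case here.

All-against-all comparison aligns each unordered pair in both directions
and keeps the larger Z (making the matrix exactly symmetric); diagonal
entries are closed-form self-Z values; sub-threshold pairs are stored as
`Z = 0` with a significance mask of `FALSE`, mirroring the dash convention
of printed tables and keeping the matrix non-negative for the downstream
steps.

## Segmentation rules

Predicted models carry per-residue pLDDT (0–100) in the B-factor field.
A **disordered segment** is a maximal run of residues with pLDDT < 70 that
is strictly longer than 15 residues and has less than 50 % helix+strand
content. The 70 threshold and the ">15 residues, marginal secondary
structure" rule follow the convention used for annotating predicted KCTD
models; the 50 % quantification of "marginal" is this package's choice, as
no number accompanies the published rule. Confidence-bin summaries use the
standard pLDDT bins (>90, 70–90, 50–70, <50); boundary values fall in the
lower bin.

Secondary structure is assigned from Cα geometry alone, in the spirit of
P-SEA: for each 5-residue window the distances d(i, i+2), d(i, i+3),
d(i, i+4) are tested against windows derived from ideal helix geometry
(5.43 / 5.05 / 6.20 Å → windows 4.9–5.9 / 4.6–5.8 / 5.5–7.0) and ideal
extended-strand geometry (6.70 / 10.21 / 13.40 Å → 6.2–7.2 / 9.3–10.9 /
12.2–14.3); passing windows mark their three central residues, runs
shorter than 4 (helix) or 3 (strand) are eroded, and the two terminal
residues at each end are always coil.

For reproducing the published family analysis the domain ranges are **not**
inferred: the curated BTB/CTD boundary table ships as a fixture
(`kctd_domains()`), because the published boundaries came from expert
inspection. Automatic segmentation is intended for synthetic or novel
inputs. Two documented quirks of the shipped table: the KCTD19 "CTD" range
(396–487) is the protein's third BTB domain — the region that actually
participates in the family comparison — exposed as an explicit,
overridable choice; and the KCTD21 boundaries give a 152-residue CTD,
outside the published 57–146 summary range. The table keeps the printed
boundaries and flags the inconsistency rather than silently editing either
number.

## Superposition

`kabsch_superpose()` is the standard SVD solution for the least-squares
rigid fit; the reflection branch is removed by sign-flipping the smallest
singular vector, so only proper rotations are returned, and collinear
point sets (rotation under-determined) are rejected. Predicted-versus-
experimental RMSDs (`structural_rmsd()`) take their residue correspondence
from the elastic alignment — not from sequence numbering — and then
iteratively drop the worst pair while any deviation exceeds 3.5 Å
(never below 3 pairs). Published comparison tables report fewer
superimposed residues than the domain lengths, implying exactly this kind
of trimmed, alignment-based subset; since the published trimming rule is
unstated, residue counts are reproduced only approximately.

## Dendrogram and embedding

Average-linkage agglomeration runs **directly on similarity**: the pair of
clusters with the largest average pairwise Z over all cross-pairs merges
first, with the unweighted (UPGMA) update for merged clusters. Masked cells
participate as `Z = 0` — the aligner reports no similarity there, and
average linkage needs a complete matrix (averaging only observed cells is
available via the parsed mask if wanted). Equal-similarity ties break by
the lexicographic order of cluster representatives (smallest member
labels), making the tree bit-reproducible. Merge similarities are
non-increasing, so the tree is well-formed without inversions.

Newick export maps merge similarity to ultrametric heights
`h = (Z_ceiling - merge_Z) / 2`, where `Z_ceiling` is the largest diagonal
(self-alignment) Z of the input; leaves sit at height 0, so similar
structures are close. This height convention is this package's own (the
similarity-to-branch-length mapping is not standardized) and is recorded in
the output file header; the raw merge similarities are additionally emitted
as `[&Z=...]` comments on internal nodes. Cuts can be made at a similarity
level or at a requested cluster count k; a k that no level can produce
(because of tied merges) is an error listing the achievable counts.

The 2-D view is classical correspondence analysis: the non-negative Z
matrix is scaled by its grand total, standardized residuals under
row-by-column independence are decomposed by SVD, and principal row
coordinates on the first two axes are reported. When the similarity graph
has disconnected blocks (as the family matrix does: the β-propeller pair
and the β-solenoid outlier), leading singular values reach 1.0 and the
corresponding axes are component indicators; coordinates within a
degenerate eigenspace are basis-dependent, which matters when comparing
against other implementations but not for reading neighborhoods off the
plot.

## The synthetic generator

Toy structures make every stage testable with known ground truth and no
downloads:

* `build_ideal_sse()` — ideal α-helix Cα geometry (1.5 Å rise, 100° twist,
  2.3 Å radius → 3.8 Å bonds) and an extended zig-zag strand with exact
  3.8 Å bonds;
* `build_toy_domain()` — elements placed at packing offsets, joined by coil
  linkers laid on equal-chord circular arcs whose out-of-plane orientation
  comes from the seed (so coil varies with the seed while SSE coordinates do
  not); non-bonded contacts under 1.5 Å are an error;
* `perturb_structure()` — i.i.d. Gaussian coordinate noise
  (E[RMSD] = σ√3);
* `make_planted_family()` — one diverged template per group (σ_between),
  members perturbed from it (σ_within < σ_between), optionally flanked by
  20-residue low-confidence linkers.

Confidence constants are 92 (SSE), 60 (coil) and 45 (linkers), chosen to
straddle the 70 and 50 pLDDT bin edges so segmentation tests exercise every
bin. Default family settings are σ_within = 0.3 Å, σ_between = 3.0 Å with
three groups of three — strong, unambiguous planted structure, comparable
to the within/between-clade contrast in the real family table.

What the generator does **not** emulate: real side-chain packing, sheet
topology and hydrogen-bond geometry, correlated (domain-hinge) deformations
— its divergence is i.i.d. noise, which degrades chain geometry at large σ
— and realistic pLDDT noise. Passing tests therefore demonstrate the
correctness of the machinery (scoring, search, clustering, recovery of
planted structure), not predictive performance on real proteins; the
checks against the published family table and the reference RMSD table
cover the latter.

## Numerical choices and edge cases

* Distance ties in agglomeration and equal-score alignments resolve
  deterministically (lexicographic labels; fixed seeds).
* `d* = 0` terms in the elastic score (both distances zero) take the limit
  value θ_E; they occur only on the diagonal in practice.
* Altloc resolution keeps the highest-occupancy CA (ties: first in file);
  multi-model files use the first model; residues without a CA are dropped
  with a warning.
* PDB round-trips are exact to the fixed-width format: 10^-3 Å in
  coordinates, 10^-2 in confidence; absent confidence writes as 0.00.
* The AlphaFold Database model version in canonical filenames defaults to
  v4 (overridable); coordinate drift between model versions is expected to
  be small relative to the comparison tolerances.
* The package core never touches the network. Accession-named inputs are
  searched in a local cache; only the CLI's explicit `--fetch` step
  downloads.

## Problem sizes

The shipped tests run on 25-label similarity matrices (the packaged family
table), toy domains of 18–45 residues, planted families of 6–9 members, 50
random superposition instances against a random-restart oracle, 1,000
random pairings for the score-bound property, and 100 random ultrametric
matrices for exact UPGMA recovery — sizes at which every oracle is exact
or exhaustive enough to be trustworthy while the whole suite stays fast.

## Known limitations

* Sequential alignments only; circular permutations and non-sequential
  Dali-style alignments are out of scope.
* The Z calibration constants are those of the published method; a given
  web-server build may apply additional corrections, so small systematic
  offsets against served Z values are expected.
* Cluster boundaries in the published family tree reflect a dendrogram plus
  expert reading; no cut height is printed, so cluster membership is a
  qualitative comparison, not a numeric target.
* Single chains only: oligomeric assemblies, ligands and nucleic acids are
  outside the model.
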