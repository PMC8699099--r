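# domalign

Structure-based comparison and clustering of protein domain families at the
C-alpha level.

Protein families frequently conserve fold long after sequence similarity has
vanished. The motivating case is the human KCTD family: 25 proteins sharing
an N-terminal BTB/POZ domain whose C-terminal regions show no mutual
sequence similarity, yet — as predicted models reveal — mostly fold into a
common domain (a single β-sheet flanked by helices). `domalign` provides the
machinery to quantify such relationships directly from coordinates: it is
aimed at structural bioinformaticians who want a self-contained, scriptable
version of the classic "all-against-all structural comparison → Z-score
matrix → structure dendrogram" workflow, with no web-server dependency.

## What it computes

For two domains with intramolecular Cα–Cα distance matrices `d^A`, `d^B`
and a sequential residue pairing, the elastic (distance-matrix) similarity
score is

    S = Σ_{i=j} θ_E  +  Σ_{i≠j} ( θ_E − |d^A_ij − d^B_ij| / d*_ij ) · exp( −(d*_ij / α)² )

with `d* = (d^A + d^B)/2`, `θ_E = 0.20`, `α = 20 Å` — the scoring function
of the Dali method. Scores are length-calibrated into Z-scores,
`Z = (S − m(L̄)) / (0.50·m(L̄))` with `L̄ = √(L_A·L_B)` and `m` the standard
cubic mean-score curve; `Z ≥ 2` counts as detectable similarity. The
alignment itself is found by fragment/SSE seeding, dynamic-programming
growth and simulated-annealing refinement (deterministic given a seed).

Around that core:

* **I/O** — PDB and mmCIF reading (via bio3d), PDB writing, pLDDT
  confidence from the B-factor field, accession-to-filename resolution for
  AlphaFold DB / PDB naming (no network in the library core).
* **Segmentation** — Cα-geometry secondary structure, pLDDT-based disorder
  calling (>15-residue runs with pLDDT < 70 and marginal SSE content), and
  slicing of curated domain ranges.
* **Superposition** — Kabsch SVD superposition and alignment-based RMSD
  with iterative 3.5 Å trimming, for predicted-vs-experimental comparisons.
* **Trees & embeddings** — unweighted average linkage run directly on the
  similarity matrix, ultrametric Newick export with merge-Z node comments,
  level/k cuts, and a 2-D correspondence-analysis projection.
* **Synthetic structures** — ideal helices/strands, packed toy domains with
  seeded coil linkers, Gaussian perturbation, and planted families with
  known group structure, so the entire pipeline is testable offline.
* **Fixtures** — the published 25×25 C-terminal-domain Z-score table
  (`kctd_similarity()`), the curated BTB/CTD boundary table
  (`kctd_domains()`), and the predicted-vs-experimental reference pairs
  (`kctd_reference_pairs()`).

## Worked example

```r
library(domalign)

sm <- kctd_similarity()                 # packaged 25x25 Z-score table
tree <- average_linkage_tree(sm)
head(tree$height, 3)
#> [1] 50.3 23.5 22.9
```

The first merge joins the β-propeller pair KCTD3/SHKBP1 at Z = 50.3; the
next two merges (KCTD10/TNFAIP1 at 23.5, KCTD20/BTBD10 at 22.9) join the
closest canonical-CTD pairs. Cutting at Z = 15 leaves the propeller pair
isolated and the β-solenoid outlier KCTD9 as a singleton:

```r
cl <- cut_tree(tree, level = 15)
split(names(cl), cl)[1:4]
#> $`1`
#> [1] "K1"  "K15"
#> $`2`
#> [1] "K8"  "K12" "K16"
#> $`3`
#> [1] "K6"
#> $`4`
#> [1] "K11"

substr(tree_to_newick(tree), 1, 80)
#> [1] "(K9:31.8,((SHK:6.65,K3:6.65)[&Z=50.3]:25.1193,((K13:20.85,(TNF:20.05,K10:20.05)["

emb <- correspondence_embedding(sm)
round(emb$coords[c("K3", "SHK", "K9", "K1"), ], 3)
#>      axis1  axis2
#> K3  -0.139  2.838
#> SHK -0.139  2.762
#> K9   7.212  0.000
#> K1  -0.139 -0.310
```

Axis 1 isolates KCTD9 (no similarity to anything), axis 2 separates the
propeller pair — the structural outliers of the family, exactly as in the
published projection. The same machinery works on synthetic structures with
known ground truth:

```r
bp <- domain_blueprint(data.frame(kind = c("strand", "helix", "helix"),
                                  length = c(8, 12, 12)),
                       rbind(c(0, 0, 0), c(28, 0, 0), c(52, 9, 0)),
                       name = "toy")
dom <- build_toy_domain(bp, seed = 1)
align_structures(dom, perturb_structure(dom, 0.5, seed = 2), seed = 0)
#> <alignment_result> Z = 3.18 (S = 94.5), 41 pairs aligned (41 x 41)
structural_rmsd(dom, perturb_structure(dom, 0.5, seed = 2), seed = 0)
#> <superposition_result> rmsd 0.958 A over 41 residues
```

(0.958 Å ≈ the 0.5·√3 expectation for i.i.d. 0.5 Å coordinate noise.)

A thin CLI wraps the same functions: `exec/domalign` with subcommands
`pipeline`, `tree`, `align`, `superpose`, `embed`, plus an optional
`--fetch` step that downloads accession-named structures into a local cache
(the only place any network access happens).

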