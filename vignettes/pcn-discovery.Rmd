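---
title: "Discovering Primary Care Networks from registration patterns: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering Primary Care Networks from registration patterns: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcnets)
```

`pcnets` partitions general practices into Primary Care Networks (PCNs)
using only patient registration patterns: which small-area geography (LSOA)
each patient lives in and which practice they are registered with. This
vignette is the package's account of the method — the model and its
assumptions, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the design decisions taken where the design
was genuinely open.

## The model

### Registration matrix and market concentration

The unit of analysis is the LSOA-by-practice count matrix C, with
c~ij~ the number of unique patients resident in LSOA *i* registered to
practice *j*. Two preprocessing rules shape it:

* **Deduplication.** A patient observed under several (LSOA, practice)
  combinations within the study window resolves to the combination with the
  highest record frequency; frequency ties resolve to the combination with
  the latest record date. The residual double tie (equal frequency *and*
  equal latest date) resolves to the lexicographically smallest
  (practice id, LSOA id) pair — an arbitrary but deterministic fallback,
  counted and reported so its (rare) incidence is visible.
* **Small-practice exclusion.** Practices contributing fewer than
  `min_patients` (default 100) patients are dropped, and their patients are
  removed with them rather than reassigned. Removal is the conservative
  reading: reassignment would fabricate registrations that were never
  observed. Because dropping a column cannot push another column below the
  threshold, a single pass suffices.

Market concentration per LSOA uses the registration shares
s~ij~ = c~ij~ / Σ~j~ c~ij~: the Herfindahl–Hirschman index
HHI~i~ = Σ~j~ s~ij~² and the equivalent market size EMS~i~ = 1/HHI~i~,
the number of practices that would serve the LSOA if each held an equal
share. EMS is dimensionless, bounded by 1 below and by the number of
practices with non-zero share above, and satisfies EMS·HHI = 1 to floating
tolerance (asserted at 1e-12 in the tests).

### The practice similarity network

Each practice's profile is the distribution of its patients over LSOAs
(its column of C divided by the column total). Practices are compared by
cosine similarity, which is invariant to per-practice scaling — so profiles
and raw count columns give identical similarities. An alternative
orientation (normalising within LSOAs: the probability that a patient from
each LSOA registers with the practice) is available via
`gp_profiles(..., normalise = "lsoa")` for sensitivity analysis; the two
readings differ in general, and the per-practice orientation is the
default because it is the one the cosine formula's terms describe.

### RMST sparsification

The similarity matrix is dense and inhomogeneous; community detection
works on a sparsened backbone that preserves local and global
connectivity. On distances d = 1 − S, the Relaxed Minimum Spanning Tree
keeps edge (A, B) iff

d~AB~ ≤ mlink~AB~ + (dNN~A~ + dNN~B~) / γ

where mlink~AB~ is the largest edge on the MST path between A and B and
dNN~X~ is X's nearest-neighbour distance. The published descriptions of
the technique leave the relaxation term's exact form and the direction of
the pruning parameter open, so this rule is a package design decision with
the following rationale: the MST-path maximum captures global geometry,
the nearest-neighbour sum captures local scale (k = 1), and dividing by γ
makes larger γ prune harder — consistent with scanning γ upward as
progressively stronger pruning. The boundary is kept on equality so both
limits are well defined: γ → 0⁺ keeps the complete graph, γ → ∞ converges
to the MST plus ties. A multiplicative variant
(`rmst_sparsify(..., variant = "multiply")`) is available; it runs in the
opposite direction. MST construction breaks distance ties by lexicographic
edge order, fixing the tree deterministically.

### Markov stability and Louvain optimisation

Communities are found by maximising the Markov stability of the random
walk on the sparsened graph. With A the weighted adjacency, k the node
strengths, M = diag(k)⁻¹A and π = k/Σk, the stability of partition H at
Markov time *t* is

r(t, H) = trace[Hᵀ (Π e^{t(M−I)} − ππᵀ) H],  Π = diag(π).

Small *t* favours many small communities (at t = 0 the off-diagonal
entries are −π~i~π~j~ < 0, so the finest partition is optimal); large *t*
favours coarse ones. The package uses the full matrix exponential of the
continuous-time process as the default flavour. The flavour choice was an
open question — linearised and combinatorial-Laplacian variants exist —
and the continuous-time normalised-Laplacian form was chosen because it is
the standard presentation of the method and exact at all times; a
linearised option (`flavour = "linearised"`) is provided for speed at
small times. The flavour matters: the Markov time at which a given
structure (say, two triangles joined by an edge) becomes optimal differs
across flavours, which is why the package's tests derive expected optima
by exhaustive enumeration under its own flavour rather than assuming
literature values.

Because ΠM^k is symmetric for every k, M shares eigenvectors with the
symmetrised operator diag(k)^{-1/2} A diag(k)^{-1/2}; one symmetric
eigendecomposition per graph therefore yields the stability matrix at
*any* Markov time by rescaling eigenvalues — the whole time grid costs one
diagonalisation. Graphs whose positive-weight part is disconnected are
legal (the walk never crosses; cross-component stability entries are
negative, so components are never merged); only zero-strength nodes are an
error, since the sparsifier guarantees structural connectivity.

Optimisation is a generalised Louvain: local node moves (sweep order
randomised by seed) followed by aggregation, with aggregation summing
blocks of the original stability matrix so the reported r is always exact
on the original graph. Moves require strict improvement beyond 1e-12 to
avoid cycling on ties. Each (γ, t) model is optimised `runs_per_model`
times (study default 500; the tests use 10–50) and the most common
partition — after canonicalisation, so relabelled duplicates count
together — is the consensus. Multiplicity ties resolve to the higher mean
stability, then to the lexicographically smallest canonical labelling.

### Geographic validity and model selection

Registration similarity is blind to geography, so candidate communities
are vetted spatially, per community and in this order:

1. **Spatial outliers** (communities of ≥ 3 members): a member whose
   median straight-line distance to co-members exceeds 4× the community's
   median pairwise distance is removed. Both medians are computed once
   from the original membership — a single pass, because the criterion is
   described as one rule applied once, and iterating it would make the
   excluded set depend on removal order.
2. **Size**: surviving communities must have 3 to 20 practices
   (inclusive; the bounds' strictness is pinned by boundary tests at 2, 3,
   20 and 21 members).
3. **Containment**: the convex hull of the members must not be too mixed —
   the fraction of practices inside the hull (boundary inclusive) that are
   *not* members must be at most 25%. The denominator — all practices
   inside the hull, members plus foreigners — was chosen from the several
   readings the criterion admits because it makes the quantity a bounded
   mixing measure (0 = pure footprint, →1 = swamped). Collinear
   memberships give a zero-area hull; containment is then computed on the
   degenerate segment and flagged.

The score of a grid point is the number of practices in its valid
communities; the optimum is the (γ, t) with the highest score, ties going
to smaller γ then smaller t (unstated in the selection rule; smaller
values are the more conservative choice on both axes). Valid + excluded
counts are asserted to sum to the practice total at every grid point.

The Markov-time grid is log-spaced (times span two decades, and community
scales grow roughly geometrically in t); the γ grid is linear. Study-scale
defaults are 400 times in [0.01, 1] × 40 parameters in [2.1, 6.0]; both
grids and the run count are plain arguments, and every analysis in the
package's tests and acceptance script uses reduced grids (10 × 5, 20
runs) appropriate to desk-scale problems of 20–60 practices.

### Assembly

Practices in valid communities receive PCN ids in order of appearance;
everything else forms an explicit unassigned pool. Each LSOA is assigned
to the PCN holding the most of its patients, with ties to the smallest PCN
id and the unassigned pool losing ties to any real PCN (so an LSOA is only
unassigned when the pool strictly dominates). Coverage is reported per
LSOA (share of its patients in its modal PCN) and per PCN (patients in
catchment LSOAs registered inside the PCN over all patients in the
catchment — exactly the patient-weighted aggregate of LSOA coverage, and
invariant to splitting an LSOA into duplicate rows). PCN-level HHI/EMS per
LSOA reuse the concentration formulas on the LSOA-by-PCN aggregated
counts, with the unassigned pool kept as one market unit: its patients are
real demand, and dropping them would overstate concentration.

## The synthetic city

The generator stands in for the restricted patient-level data the method
was designed for. It emulates the post-extraction registration table:

* `k` community centres on a circle (spacing 40 units), LSOAs and
  practices scattered around their centre (Gaussian, sd 6), round-robin
  allocation guaranteeing every community at least one of each;
* registration by a gravity kernel: a patient in LSOA *i* picks practice
  *j* with probability ∝ exp(−d~ij~/λ), multiplied by ε when the practice
  lies outside the LSOA's planted community. The exponential is a
  conventional distance-decay choice; any positive decreasing kernel would
  serve. The default decay length λ = 15 is on the order of a community's
  footprint (diameter ≈ 2–3 sd), so patients discriminate little *within*
  their community but strongly against the next centre 40 units away —
  communities are internally well mixed, which is what "one natural
  community" means in this model. Shorter λ creates genuine
  sub-neighbourhood structure inside planted communities, and partitions
  finer than the planted one then become legitimately optimal;
* duplicate records (probability `dup_rate` per patient) built to be
  strictly dominated by the true pair — fewer records, or equal records
  with strictly earlier dates — so deduplication has an exact ground
  truth;
* CCG membership coinciding with the planted community, giving a known
  administrative truth for span statistics.

What it does **not** emulate: demographic structure (age, morbidity,
deprivation), practices with no geographic anchor (digital-first
providers), temporal churn, irregular LSOA geometry (tiles are squares,
not census boundaries), and the selection bias of secondary-care-derived
cohorts. Passing the planted-recovery tests therefore shows the pipeline
is correct and internally consistent — not that real registration data
contains communities this clean.

Acceptance-scale studies use 300 LSOAs × 60 practices × 6 communities with
50 patients per LSOA and ε = 0.05 (and the ε = 0 limit), on the reduced
10 × 5 grid with 20 runs per model. In the ε = 0 limit the similarity
matrix is exactly block-diagonal, cross-community stability entries are
negative at every time, and recovery plus 100% coverage is a theorem the
tests confirm rather than a tuning outcome.

## Numerical choices and degenerate inputs

* Cosine similarities are clamped to [0, 1] and symmetrised
  ((S + Sᵀ)/2) so downstream code may assume exact symmetry.
* All seeds derive from one master seed through a fixed mixing scheme
  (`gamma index`, `time index`, `run` counters), keeping every derived
  seed a valid 32-bit integer; the whole grid is reproducible and
  `metrics.json` reruns are asserted byte-identical.
* Point-in-polygon is ray casting with an explicit on-segment test so
  boundary points count as inside — the containment filter's stated
  semantics, which generic implementations don't guarantee.
* Zero-patient LSOA rows are excluded from market summaries and reported,
  not fatal; an empty matrix after the small-practice filter is fatal.
* A grid point whose model fails is recorded with its error, scored 0, and
  the search continues.

## Limitations

* The Louvain optimiser is greedy; the tests show best-of-50 runs attain
  the exhaustive optimum on all ≤ 8-node family graphs, but no such
  guarantee exists at scale — hence the consensus-of-runs design.
* Dense stability matrices put a practical ceiling around a few thousand
  practices; the linearised flavour extends this at small times.
* Straight-line distances ignore rivers, rail lines and travel time — the
  spatial filters inherit this simplification.
* The containment denominator and the RMST relaxation rule are documented
  package decisions among several defensible readings; both have
  configurable alternatives, and conclusions sensitive to them should be
  checked against the variants.
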