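# pcnets

Data-driven discovery of Primary Care Networks (PCNs) from patient
registration patterns.

PCNs are groupings of neighbouring general practices (GP practices) in the
English NHS, intended to serve "natural" communities of roughly 30,000 to
50,000 patients. `pcnets` identifies such communities directly from data: it
takes a patient-level registration table — which patient, resident in which
small-area geography (LSOA), is registered with which practice — and returns
a partition of practices into spatially coherent networks, together with
catchment areas, coverage and market-concentration statistics. It is aimed
at health-services researchers and analysts working with administrative
registration data, and ships a synthetic-city generator with planted
community structure so the entire pipeline can be exercised and validated
without access to restricted patient-level data.

## Method

The pipeline, end to end:

1. **Deduplication.** A patient observed at more than one (LSOA, practice)
   combination keeps the most frequent combination; frequency ties keep the
   most recent. Practices contributing fewer than 100 patients are excluded.
2. **Market concentration.** For LSOA *i* with registration shares
   *s<sub>ij</sub>* over practices *j*:
   HHI<sub>i</sub> = Σ<sub>j</sub> s<sub>ij</sub>², and the equivalent
   market size EMS<sub>i</sub> = 1 / HHI<sub>i</sub> — the number of
   practices that would serve the LSOA at equal shares.
3. **Similarity network.** Each practice's profile A is the proportion of
   its patients resident in each LSOA; practices are linked by cosine
   similarity S<sub>AB</sub> = Σ A<sub>i</sub>B<sub>i</sub> /
   (‖A‖ ‖B‖).
4. **RMST sparsification.** The dense network is sparsened with the Relaxed
   Minimum Spanning Tree: working on distances d = 1 − S, an edge (A, B) is
   kept iff d<sub>AB</sub> ≤ mlink<sub>AB</sub> + (dNN<sub>A</sub> +
   dNN<sub>B</sub>)/γ, where mlink is the largest edge on the MST path
   between A and B and dNN is each endpoint's nearest-neighbour distance.
   The output always contains the MST and stays connected; larger γ prunes
   harder.
5. **Markov-stability community detection.** On the sparsened graph, the
   stability of a partition H at Markov time *t* is
   r(t, H) = trace[Hᵀ(Π e^{t(M−I)} − ππᵀ)H], with M the random-walk
   transition matrix and π its stationary distribution. r is maximised by
   repeated generalised Louvain runs; the most common partition of 500 runs
   is the consensus. Small *t* resolves fine communities, large *t* coarse
   ones.
6. **Geographic validity and model selection.** Over a grid of 40 pruning
   parameters γ ∈ [2.1, 6.0] × 400 Markov times t ∈ [0.01, 1], each
   consensus partition is filtered: spatial outliers removed (median
   distance to co-members > 4× the community's median pairwise distance),
   communities outside 3–20 practices dropped, and communities whose convex
   hull contains more than 25% foreign practices dropped. The partition
   keeping the most practices wins.
7. **Assembly.** LSOAs are assigned to the PCN holding the most of their
   patients; per-LSOA and per-PCN coverage, PCN list sizes, CCG span and
   PCN-level HHI/EMS are reported.

## Worked example

Fit a synthetic city of 300 LSOAs and 60 practices with six planted
communities and 5% cross-community leakage, on a reduced 5 × 10 grid:

```r
library(pcnets)

city <- generate_city(n_lsoa = 300, n_gp = 60, k = 6, seed = 11)
reg  <- sample_registrations(city, seed = 12)
fit  <- pcn_fit(reg, city$gps, lsoas = city$lsoas,
                gammas = gamma_grid(5), markov_times = markov_grid(10),
                runs_per_model = 20, master_seed = 13)
summary(fit)
#> Primary Care Network fit - summary
#>   optimum: gamma = 2.1, Markov time = 0.3594
#>   6 PCNs; 60 of 60 practices grouped (100.0%)
#>   PCN size: median 10 practices (range 7-13)
#>   PCN list size: median 2550 (IQR 2326-2613)
#>   CCG span: 1 CCG(s): 100%
#>   LSOA equivalent market size (practices): median 8.31 (range 3.65-12.14)
#>   LSOA coverage: median 98.0% (range 90.0-100.0%)
#>   PCN coverage: median 98.4% (range 97.7-99.0%)
#>   PCN-level EMS per LSOA: median 1.04
```

All six planted communities are recovered exactly (`adjusted_rand_index`
against the planted labels is 1), every practice is grouped, and each PCN
stays within its planted CCG. The median LSOA-level EMS of 8.3 says a
typical LSOA's patients spread over the equivalent of eight practices,
while the PCN-level EMS of 1.04 says the same patients concentrate almost
entirely in one network — the signature of well-chosen community
boundaries. `plot(fit)` draws the map; `run_pipeline(pipeline_config(...))`
runs the same computation from CSV files and writes every artifact
(matrices, edge lists, grid records, membership, assignment, metrics,
GeoJSON catchments) with a provenance manifest. A command-line wrapper with
`simulate` / `run` / `report` subcommands is installed at
`inst/scripts/pcn-pipeline.R`.

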