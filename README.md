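# smlmpp — point-pattern analysis of two-color SMLM data

`smlmpp` quantifies how membrane receptors organize at the nanoscale from
single-molecule localization microscopy (SMLM/dSTORM) data. It was built for
the kind of question asked in CAR-T immunology: when a CAR-T cell engages a
target cell, do the chimeric antigen receptors (CARs) form nanoclusters, and
do they segregate from the bulky phosphatase CD45 at the contact — the
signature expected under the kinetic-segregation model of T-cell triggering?
The same toolkit applies to any two-channel localization dataset.

The package is aimed at microscopists and computational biologists who have
ThunderSTORM-style localization tables (one fitted emission event per row)
and want per-cell, per-condition statistics rather than rendered images.

## What it computes

**Pair-correlation function (PCF).** For a point pattern of intensity
λ = n/A in a window of area A, the estimator per annulus [r₁, r₂) is

    ĝ(r) = (observed ordered pairs at distance in [r₁, r₂))
           / ( n(n−1) · π(r₂² − r₁²) / A )

so complete spatial randomness (CSR) gives g(r) = 1 and nanoclustering
g(r) > 1 at short range. Toroidal (periodic) edge correction is the default;
a border-exclusion correction is available for real ROIs. The bivariate
version `cross_pcf()` replaces n(n−1) by n₁n₂ and measures co-organization
of the two channels.

**Extent of mixing (EOM).** The bivariate PCF is normalized by the PCF of
the pooled two-channel pattern:

    EOM(r) = (g₁₂(r) − 1) / (g_pool(r) − 1)

Random labelling of one pattern (the "perfectly mixed" reference) gives
EOM = 1; two independent patterns ("no interaction") give EOM = 0.
Segregation is reported as 1 − EOM, conventionally read at r = 20 nm
(molecular overlap) and r = 200 nm (overlap of larger features such as
microvilli). Bins where the pooled pattern has no structure are masked
rather than returned as unstable ratios.

**Blinking correction.** One fluorophore yields several localizations.
`merge_localizations()` links localizations within 20 nm that recur within a
~50 ms temporal gap (connected components of the spatiotemporal linkage
graph) and collapses each component to one molecule at the
intensity-weighted mean position.

**Nanocluster sizes.** `dbscan_clusters()` (ε = 45 nm, minpts = 2, i.e.
clusters are the components of the ε-neighbourhood graph) splits molecules
into monomers, dimers and ≥3-mers; `size_distribution()` reports class
fractions under both the per-molecule and per-cluster conventions plus the
cumulative cluster-size distribution.

**Axial separation.** `height_separation()` tests whether channel 1 sits
above channel 2 in z (Mann–Whitney by default, Welch optional).

**Cohort statistics.** `aggregate_condition()` produces per-condition
mean ± SEM and reference-relative p-values; `excess_killing()` and
`normalize_and_correlate()` build the normalized parameter matrix (each
column scaled by its maximum across cell lines) and its Pearson correlation
matrix.

**Synthetic ground truth.** `simulate_csr()`, `simulate_thomas()`,
`simulate_two_color()` (independent / random-label / co-clustered /
segregated couplings) and `emulate_blinking()` generate seeded localization
tables with known truth for every stage; `run_pipeline()` drives the whole
chain from a config list and writes CSV results plus a JSON manifest.

## Worked example

Two channels whose clusters are displaced by 150 nm (a segregated synapse
stand-in), pushed through blinking emulation, merging and the statistics:

```r
library(smlmpp)
w   <- roi(0, 4000, 0, 4000)                       # 4 x 4 um window
sim <- simulate_two_color("segregated", w, displacement = 150, seed = 42)
ch1 <- emulate_blinking(sim$ch1, channel = 1, window = w, seed = 43)
ch2 <- emulate_blinking(sim$ch2, channel = 2, window = w, seed = 44)
m1  <- merge_localizations(ch1)                     # 20 nm / 50 ms defaults
m2  <- merge_localizations(ch2)
nrow(ch1); nrow(m1)
#> [1] 3485
#> [1] 1106
eom_at(eom_curve(loc_coords(m1), loc_coords(m2), w))
#>   radius        eom segregation valid
#> 1     20 0.05132678   0.9486732  TRUE
#> 2    200 2.08632332  -1.0863233  TRUE
size_distribution(dbscan_clusters(loc_coords(m1)))
#> Cluster-size distribution over 1106 molecules:
#>   molecules in monomers 2.8%, dimers 2.7%, >=3-mers 94.5%
#>   clusters (>=2): dimers 14.0%, trimers 11.2%, larger 74.8%
```

Reading the numbers: 3485 raw localizations collapse to 1106 molecules
after blinking merging. EOM(20 nm) ≈ 0.05 — the channels barely mix at
molecular range, i.e. segregation ≈ 0.95, as expected when channel-2
clusters sit 150 nm away. EOM(200 nm) ≈ 2.1 reflects the cross-channel
pair enrichment at the 150 nm displacement scale itself (EOM is not
clipped, so attraction beyond the random-labelling reference can exceed 1).
Most molecules fall in ≥3-mers because each Thomas cluster contributes
several molecules within DBSCAN's 45 nm reach.

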