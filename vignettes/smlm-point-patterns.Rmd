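---
title: "Methods: two-color SMLM point-pattern statistics in smlmpp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-color SMLM point-pattern statistics in smlmpp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smlmpp)
```

# Scope and data model

`smlmpp` analyses localization tables: one row per fitted emission event,
with frame index, (x, y) and optionally z in nanometres, a channel id, and
optional quality fields (photon count, PSF sigma, localization
uncertainty). Upstream image processing — peak fitting, drift correction,
channel registration, astigmatism z-calibration — is assumed done by the
acquisition software (e.g. ThunderSTORM); this package starts where those
tools stop and ends with per-condition statistics.

All statistics are computed **per cell (per ROI) first** and only then
averaged across cells with SEM error bars. Pooling localizations across
cells before estimation would let bright cells dominate and would mix
heterogeneous intensities into spurious correlation structure.

# Blinking correction

A single fluorophore blinks, producing a burst of localizations. Merging
treats two localizations of one channel as the same molecule when they are
within `distance_nm` (default 20 nm) and their frame separation skips at
most `ceiling(gap_ms/1000 * frame_rate)` frames (default 50 ms; at the
13.4 fps typical of fixed-cell dSTORM this allows one skipped frame).
Molecules are the **connected components** of this linkage graph — an
order-independent formulation of the sequential grouping that localization
software performs — collapsed to the intensity-weighted mean position with
the first participating frame. A zero distance threshold disables linking
entirely, so merging with both thresholds at zero is the identity.

Two properties are worth stating honestly. First, merging is contractive
but not idempotent in general: fragments of an imperfectly linked burst
have centroids closer than their member localizations, so re-application
can occasionally merge further on noisy data. Second, with localization
error σ per axis, two independent localizations of the same molecule are
separated by a Rayleigh(σ√2) distance, so the probability that a 20 nm
radius links them is 1 − exp(−r²/4σ²) ≈ 0.75 at σ = 8.5 nm. Merging at
these settings therefore *reduces* over-counting (here by roughly a factor
of three on a mean-4-emission burst model) but leaves a residual
over-counting factor of ~1.2–1.3. This is intrinsic to the thresholds, not
an implementation artifact — the same reason practitioners describe merged
counts as comparative rather than absolute. Downstream statistics are
robust to it by design: the PCF/EOM normalizations are ratio statistics,
and cluster-size comparisons are made between conditions processed
identically.

# Pair-correlation estimators

For n points in a window of area A, the univariate estimator per annulus
[r₁, r₂) divides the observed ordered-pair count by its CSR expectation
n(n−1)·π(r₂²−r₁²)/A; the bivariate version uses n₁n₂. Bins are left-closed
([r₁, r₂)), 10 nm wide from 0 to 500 nm by default — narrow enough to
resolve the 20 nm readout, wide enough to keep per-bin pair counts stable
at typical densities (≥ ~10² pairs per bin at 100 points/µm² in a 4 × 4 µm
window).

**Edge correction.** The default is toroidal (periodic) wrapping, which is
exactly unbiased for stationary simulated processes and keeps oracle tests
closed-form; it requires `max(r_edges)` ≤ half the shorter window side.
For real ROIs, where the pattern is not periodic, a border-exclusion
correction is provided: for each annulus only points farther than its
outer radius from the ROI boundary serve as reference points. The
bivariate border correction is symmetrised (both erosion directions are
pooled) so that `cross_pcf(A, B)` and `cross_pcf(B, A)` are identical by
construction, not just in expectation.

**Degenerate inputs.** Fewer than 2 points (or an empty channel) is an
error naming the offending channel; an r range too large for the
correction is an error rather than a silently biased estimate.

# Extent of mixing

The EOM statistic normalizes the bivariate PCF by the PCF of the pooled
two-channel pattern:

$$\mathrm{EOM}(r) = \frac{g_{12}(r) - 1}{g_{\mathrm{pool}}(r) - 1}$$

The pooled pattern is the analytic random-labelling reference: relabelling
preserves the pooled pattern, so under random labelling
E[g₁₂] = E[g_pool] and EOM → 1, while independent channels give g₁₂ = 1
and EOM → 0. These two anchors fix the interpretation: 1 means the
channels look like random labels of one underlying pattern (maximal
mixing), 0 means no interaction, and 1 − EOM is reported as segregation.
The anchors constrain but do not uniquely determine a mixing statistic;
this ratio form was chosen because it reproduces both anchors exactly in
expectation, needs no Monte-Carlo loop, and degrades gracefully (a
Monte-Carlo relabelling denominator, `eom_curve_mc()`, is provided as a
cross-check and agrees with the analytic form within sampling error).

Numerical choices:

* **Denominator floor.** Where |g_pool − 1| < 0.05 the pooled pattern is
  statistically indistinguishable from CSR and the ratio is meaningless;
  such bins are masked invalid instead of returned. This is why synthetic
  Thomas patterns with σ = 30 nm clusters have no defined EOM at 200 nm —
  there genuinely is no structure at that scale to mix. Real synapse data
  carry structure (microvilli, lamellar ridges) at hundreds of nm, which
  is what makes the 200 nm readout meaningful there.
* **No clipping.** EOM above 1 (attraction beyond random labelling, e.g.
  cross-channel pair enrichment at a characteristic displacement) and
  below 0 are reported as-is.
* **Readout convention.** `eom_at()` returns the value of the left-closed
  bin containing the requested radius; with the default 10 nm grid,
  r = 20 nm reads the [20, 30) bin.

# Nanocluster analysis

DBSCAN with ε = 45 nm and minpts = 2 follows the recommended practice for
SMLM cluster analysis of membrane receptors. The minpts count **includes
the point itself** (a point with one true neighbour is core), because the
analysis must recognise dimers as clusters; with that convention at
minpts = 2, clusters are exactly the connected components of the
ε-neighbourhood graph with ≥ 2 members and isolated points are monomers.
The exclusive convention is available via `count_self = FALSE`. For
minpts > 2 the classic border-point ambiguity is resolved
deterministically: clusters grow from core points in ascending index
order and a border point joins the first cluster to reach it. Distances
are 2D (x, y) even when z is present, matching interface-projection
analyses.

Because "fraction of dimers" is ambiguous, `size_distribution()` reports
class fractions over molecules *and* over objects (and over clusters of
size ≥ 2 only), plus the cumulative cluster-size distribution. An
all-monomer result is flagged degenerate rather than plotted as an empty
curve.

# Axial statistics

`height_separation()` compares per-molecule z between channels with a
two-sided Mann–Whitney U test by default — SMLM z profiles are typically
skewed and the test should not reward that — with Welch's t-test as an
option. It operates on merged molecules, not raw localizations, to avoid
blinking pseudo-replication inflating significance. The sign convention is
delta_z = mean z(channel 1) − mean z(channel 2), so swapping channels
flips the sign exactly.

# The synthetic generator

The generator provides ground truth for validation and emulates:

* **CSR** (homogeneous Poisson) and **Thomas** (Poisson parents, Poisson
  offspring, isotropic Gaussian scatter) processes. Defaults of
  5 parents/µm², mean 10 offspring and σ = 30 nm give ~50 molecules/µm²
  organized in nanoclusters of realistic size and density for abundant
  membrane receptors; CSR defaults to 100 points/µm².
* **Couplings** between the channels: independent draws, random labelling
  (i.i.d. channel assignment with probability p), co-clustered (shared
  parents), and segregated (channel-2 parents displaced by a set distance
  in a random direction). These reproduce the EOM anchors (0, 1) and an
  intermediate monotone trend in displacement.
* **Blinking**: geometric emission counts (support ≥ 1, mean 4 —
  memoryless blinking, the simplest over-counting stand-in), consecutive
  frames by default with optional geometric dark gaps, uniform burst
  starts over the acquisition, and isotropic Gaussian localization error.
  The default error is σ = 8.5 nm per axis, i.e. ~20 nm FWHM resolution
  (FWHM = 2.355 σ), the conventional reading of "~20 nm resolution" for
  dSTORM.
* Children falling outside the window are wrapped toroidally, consistent
  with the toroidal edge correction (truncation is flag-selectable).

What it does **not** emulate: camera-frame rendering and PSF shape,
fluorophore photophysics beyond emission counts, multiple fluorophores per
antibody, drift, chromatic offsets, or inhomogeneous cell topography
(microvilli). Passing tests on synthetic data therefore validate the
estimators and their normalizations, not the biology of any particular
dataset; in particular the generator's flat 200 nm-scale structure means
the 200 nm EOM readout is exercised mainly through its masking logic.

# Validation strategy and problem sizes

Every estimator is tested against an independent brute-force oracle:
exhaustive O(n²) pair counting for `pcf()`/`cross_pcf()` (exact to 1e−12
on patterns of a few hundred points), BFS connected components of the
ε-graph for DBSCAN at minpts = 2, and BFS over the explicit spatiotemporal
adjacency matrix for merging (exact on ≤ 200 localizations). Statistical
anchors use seeded replicate simulations: the CSR null and the two EOM
anchors run 20–24 replicates of ~800–1600 points in a 4 × 4 µm window,
which keeps each anchor within a few SEM of its theoretical value while
the whole suite completes in about a minute. The axial test's type-I error
is checked over 1000 null replicates at n = 20 per channel.

# Known limitations

* The residual over-counting factor after merging (see above) means
  absolute molecule counts are comparative, not stoichiometric.
* The toroidal correction is only appropriate for simulated or visually
  homogeneous windows; use the border correction on real ROIs.
* EOM is undefined wherever the pooled pattern lacks structure; masked
  bins propagate as NA through the cohort stage and drop out of
  normalized-parameter correlations.
* The cohort stage applies no multiple-testing correction by default
  (per-comparison stars, as is conventional in imaging cohort figures); a
  Benjamini–Hochberg option exists and is off by default.
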