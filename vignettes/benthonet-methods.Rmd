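---
title: "Methods: core–satellite partitioning and co-occurrence networks in PAH-impacted sediments"
author: "benthonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: core-satellite partitioning and co-occurrence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(benthonet)
```

## The analysis problem

Coastal sediments chronically exposed to polycyclic aromatic hydrocarbons
(PAHs) host three-domain microbial communities whose structure reflects both
broad environmental gradients (salinity, temperature, latitude, sediment
texture, organic carbon) and the contamination itself. `benthonet`
implements a complete analysis chain for OTU count tables from such systems:

1. **Contamination classification** of samples from their 11-compound PAH
   chemistry.
2. **Core/satellite partitioning** of the species abundance distribution
   (SAD) by a dispersion-index test.
3. **Association inference**: all-pairs Spearman correlations over core
   OTUs, gated at |rho| ≥ 0.6 and p < 0.001.
4. **Null-model validation** of co-occurrence non-randomness with the
   checkerboard C-score and a standardized effect size (SES).
5. **Network analysis**: module detection by modularity maximisation,
   topological indices, and contaminated-vs-pristine network comparison.
6. **Module–environment coupling**: module eigengenes (SVD) correlated with
   environmental variables, plus PERMANOVA variance partitioning.

A synthetic community generator with planted ground truth makes every stage
testable end to end.

## Contamination classification

Within each region independently, samples are clustered by hierarchical
agglomerative classification on Euclidean distances of their 11 PAH
concentrations and the tree is cut at k = 2; the cluster with the higher
mean 9-compound PAH sum (`pah9_sum()`, the nine compounds covered by
sediment quality guidelines) is labeled *contaminated*. Concentrations are
log10(x+1)-transformed and Ward (`ward.D2`) linkage is used by default:
sediment PAH concentrations are heavy-tailed over orders of magnitude and a
log scale keeps single high-concentration samples from dominating the
Euclidean geometry. Both choices are configuration knobs
(`hac_transform`, `hac_linkage`) and are recorded in the run manifest,
since clustering on raw concentrations with other linkages is equally
defensible.

Diagnostic source ratios follow the standard rules:
phenanthrene/anthracene (P/A) < 10 together with fluoranthene/pyrene
(F/P) > 1 indicates a pyrogenic (combustion) source; P/A > 10 with
F/P < 1 a petrogenic one; other combinations are indeterminate, as are
samples with zero denominators. Guideline exceedance compares the sample's
9-PAH sum against each guideline's own 9-compound sum with a strict `>`
(boundary equality is non-exceeding). Guideline threshold tables (PEL, ERL,
T50) are user-supplied configuration — the package hard-codes no guideline
values.

Collinear predictors are grouped before any model fitting: variables with
|Spearman rho| ≥ 0.75 are joined into connected components and each group is
represented by one proxy — by default the member with the highest mean
absolute correlation to its group, with manual overrides so that, e.g.,
fluoranthene can stand for the full PAH suite and salinity for
latitude/temperature. We read "collinearity up to 0.75" as ≥ 0.75
(inclusive); the strictness is configurable.

## Core/satellite partitioning

For each OTU, counts across all samples (zeros included) give the mean, the
unbiased (n−1) variance, the variance-to-mean ratio (VMR; 1 under a Poisson
distribution), and the occurrence (number of samples with a non-zero
count). The dispersion statistic is VMR × occurrence, compared against the
central 95% band of the chi-square distribution. An OTU is **core** when
its statistic exceeds the upper (97.5%) limit — more aggregated across
sites than random dispersal explains — and **satellite** otherwise,
including underdispersed OTUs below the lower limit.

Three degrees-of-freedom conventions are available. The default ties df to
the occurrence, staying literal to the statistic VMR × occurrence; the
classical index-of-dispersion test convention (df = n_samples − 1) and
df = occurrence − 1 are selectable. All-zero OTUs get VMR defined as 0
(avoiding 0/0) and are satellites. A known ambiguity is documented rather
than resolved: descriptions of this test sometimes state that random
(Poisson) taxa fall *between* the band limits and sometimes that they fall
*below* the 2.5% line; this implementation uses the upper limit as the core
boundary, so both the within-band and below-band regimes are satellite.

Under a pure Poisson table the core-call rate converges to the upper-tail
mass of the band (~2.5%); the test suite verifies this at λ ∈ {2, 5, 20}
and the acceptance script recomputes it at 10,000 OTUs × 42 samples.

## Association inference

Spearman correlations use average-rank tie handling. The single-pair
function enumerates all n! permutations for n ≤ 9 (valid with ties) and
uses the t approximation for larger n; the all-pairs `edge_table()` is
vectorised with the t approximation, appropriate at the sample sizes where
network inference is sensible. The edge gate retains |rho| ≥ 0.6 with
p < 0.001. The absolute value matters: negative associations (e.g.
predator–prey pairs) pass the gate and carry a `sign` attribute. No
multiple-testing correction is applied by default — the stated gate is the
raw p-value — but a Benjamini–Hochberg mode exists (`adjust_p = TRUE`).

A prevalence filter (default: present in ≥ 25% of samples) removes
low-occupancy OTUs before correlation; rank correlations over mostly-zero
vectors are dominated by tie structure and inflate both false positives and
false negatives. The exact filter is a configuration knob because no
canonical choice exists.

Correlations are computed on (rarefied) counts, not relative abundances.
Compositional closure can induce spurious negative correlations;
dedicated compositional methods (SparCC-style) are out of scope and the
caveat stands.

## C-score null models

For a species pair with occupancies R_i, R_j sharing S_ij sites, the
checkerboard unit count is (R_i − S_ij)(R_j − S_ij); the C-score is its
mean over unordered pairs, and the normalized variant divides each pair by
R_i × R_j (pairs with R_i R_j = 0 are skipped). The normalization is a
standard choice documented as an assumption.

"Preserving site frequencies" is interpreted as fixed per-site (column)
totals with presences assigned to species equiprobably; the alternative
reading (fixed species occupancies) and a fixed–fixed checkerboard swap
algorithm are selectable and recorded in the manifest. SES =
(observed − null mean)/null sd over (by default) 5000 null matrices;
|SES| ≤ 2 is the random band, positive values indicate segregation.
One-tailed p-values use the add-one estimator (1 + #null ≥ obs)/(1 + n),
which never returns 0 and makes p_greater + p_less ≥ 1.

The generator is validated two ways: the sampled distribution on a small
matrix is uniform over the exhaustively enumerated reachable set, and
Monte-Carlo null moments on 3×4 matrices agree with exact enumeration.

## Network analysis

Networks keep only OTUs with at least one retained edge. Module detection
is Louvain-style modularity maximisation on the unweighted graph ignoring
edge signs (the convention of common network GUIs); signed-modularity
variants are deliberately not implemented. Average path length is computed
on the largest connected component — disconnected graphs have no finite
global path length and this restriction is stated with the result. Local
clustering of degree-<2 nodes counts as 0. The scale-free diagnostic is a
descriptive log–log degree-distribution regression, not a maximum-likelihood
power-law fit, and is labeled as such.

The contaminated/pristine comparison **rebuilds** the edge table within
each sample group from the same core OTU set, rather than subsetting the
global network: correlations estimated on the full sample set conflate the
two regimes and would mask group-specific rewiring. Group networks are
compared by their topology summaries and by node-level rank-sum tests on
degree and clustering distributions (our convention; significance marks on
such tables rarely state their test).

## Module eigengenes and PERMANOVA

Each module's OTU × sample matrix is row-standardized; the eigengene is the
first right-singular vector — a unit-norm per-sample summary — with
variance explained d₁²/Σd². Singular vectors are sign-ambiguous, so the
eigengene is oriented to correlate positively with the module's mean
standardized profile, making heat-map signs reproducible. Eigengene–
environment correlations are Pearson on transformed variables (log salinity,
log fluoranthene, squared F/P by default; Spearman selectable).

PERMANOVA uses vegan's `adonis2` with sequential (`by = "terms"`) Gower
decomposition, pseudo-F statistics, and free permutation of sample labels
(the historical default of that interface), on complete cases only — the
number of samples used is always logged. Community distance is Bray–Curtis
on rarefied counts: phylogenetic distances (weighted UniFrac) require trees
that are outside this package's scope, and the substitution is prominent
here and in the function documentation.

## The synthetic community generator

`simulate_community()` produces a table, metadata, taxonomy and full ground
truth. What it emulates, and the default study conditions:

* **42 samples** in two regions, half contaminated within each region.
* **Environmental copula**: salinity and temperature coupled to a latent
  latitude axis at rank correlation −0.8.
* **PAH suite**: 11 log-normal compounds sharing a per-sample site factor
  (log10 SD 0.30) with per-compound noise (log10 SD 0.10), giving
  inter-compound rank correlations ≈ 0.9; contaminated sites are elevated
  20-fold. These spreads were chosen so that the two contamination states
  form clearly separated, internally variable groups — about a 2× geometric
  SD of background PAH between sites within a region — which is the regime
  the classification stage is designed for. Baseline concentrations give
  P/A ≈ 7 and F/P ≈ 1.3, i.e. a chronic pyrogenic signature.
* **Core OTUs** (120): log-normal baselines (meanlog log 20, sdlog 0.8);
  non-module core respond to one environmental driver with |β| ∈ [0.5, 1.0]
  per driver SD plus idiosyncratic log-normal noise (SD 0.7) so that OTUs
  sharing a driver are correlated but not collinear.
* **Modules** (6, of 8–15 OTUs): members load (≈1 ± 0.15) on a shared
  per-sample latent factor = 0.6 × an environmental driver + shared noise
  (SD 0.9). The PAH-sensitive module's factor is −0.9 × standardized
  log10 fluoranthene + noise (SD 0.5). In contaminated samples all shared
  module signals are attenuated (× 0.7) and topped up with idiosyncratic
  noise of equal variance — the mechanism by which contamination degrades
  module co-occurrence while leaving marginal abundances similar. The
  attenuation value is calibrated to the edge gate: within-module
  correlations stay above 0.6 over the pooled sample set (so planted
  modules are recoverable from the full table) but fall below the retention
  threshold within the contaminated subset alone (so group-specific
  networks lose module edges).
* **Predator–prey pair**: the prey's log expectation is −1 × the predator's
  realized latent factor, inside the PAH-sensitive module, giving a strong
  negative association.
* **Satellite OTUs** (900): homogeneous Poisson across all samples with
  per-OTU means in [0.05, 0.6], so sparsity arises from Poisson zeros and
  the OTUs are *genuinely* randomly dispersed — exactly the null the
  dispersion-index test assumes. (An occupancy-subset construction with
  conditional Poisson counts was rejected: a zero-inflated Poisson with
  occupancy 0.1 and conditional mean 2 has VMR ≈ 2.8 and sits on the core
  boundary, contradicting the satellite definition.)
* **Depth scaling**: expected abundances are renormalized per sample and
  counts drawn by multinomial resampling at depth 3238, preserving the
  compositional, fixed-depth character of rarefied data; a
  negative-binomial noise model is available for overdispersion studies.

What it does **not** emulate: sequencing error, chimeras, OTU clustering
artifacts, phylogenetic correlation among OTUs, spatial autocorrelation
beyond the latitude copula, and temporal dynamics. Passing recovery tests
therefore demonstrates that the statistical machinery detects the planted
effects at realistic sizes — not that real sediment data meet these
assumptions.

Setting all effect sizes to zero (`beta_range = c(0, 0)`, no modules,
`contamination_multiplier = 1`) turns the generator into an exchangeable
null under which rank-sum and PERMANOVA p-values are uniform and SES is
calibrated; the test suite checks this by Kolmogorov–Smirnov tests.

## Numerical choices and degenerate inputs

* Exact rank-sum enumeration when both groups have n ≤ 8 without ties;
  normal approximation with tie/continuity correction otherwise.
* Exact Spearman p by full permutation enumeration for n ≤ 9.
* Chi-square limits with implied df < 1 force the OTU to satellite with a
  warning rather than erroring.
* Null SES with a degenerate (sd = 0) null distribution returns NA with a
  diagnostic instead of dividing by zero.
* Samples below the rarefaction depth are dropped (not padded), with a
  warning; rarefaction is a single seeded draw, with the seed recorded.
* Constant OTU profiles are dropped before SVD; constant variables are
  dropped from collinearity grouping and correlation with warnings.
* HAC refuses all-identical PAH profiles ("no separation").

## Problem sizes used in validation

Recovery experiments run at 30 samples × 300 OTUs (60 core with four
10-OTU modules, 240 satellites) — a size at which every planted effect is
comfortably detectable and replicated runs stay fast: 100 replicates for
core/satellite recovery, 50 for module/eigengene/network-contrast
recovery, 500 for p-value calibration, and 200 for SES calibration with
200 null matrices each. The full-scale defaults (42 × 1020, 5000 null
matrices, 1000 permutations) are what an analysis of a real dataset would
use.

## Known limitations

* Correlation-based edges inherit compositional bias from fixed-depth
  counts.
* The dispersion-index partition is sensitive to the df convention at low
  occupancy; we default to the literal reading and expose alternatives.
* The power-law diagnostic is descriptive only.
* PERMANOVA on Bray–Curtis is not a drop-in for phylogenetic (UniFrac)
  variance partitioning; conclusions about lineage-level filtering require
  trees.
* Louvain is stochastic; we fix the seed and renumber modules by size, but
  partitions can differ across igraph versions.
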