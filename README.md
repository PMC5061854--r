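# benthonet

Core–satellite partitioning and cross-domain co-occurrence networks for
PAH-contaminated coastal sediment microbiomes.

## What it does, and for whom

`benthonet` is for microbial ecologists analysing OTU count tables from
sediments along contamination gradients. It chains six stages:

1. **Contamination classification** — per region, hierarchical (Ward)
   clustering of Euclidean distances between log-transformed 11-compound
   PAH profiles, cut at k = 2; the cluster with the higher Σ PAH₉ (the nine
   guideline-covered compounds) is *contaminated*. Diagnostic source ratios
   (P/A < 10 and F/P > 1 ⇒ pyrogenic) and sediment-quality-guideline
   exceedance (PEL/ERL/T50, user-supplied thresholds) are reported
   alongside.
2. **SAD partitioning** — for each OTU the dispersion statistic
   VMR × occurrence (VMR = variance/mean over all samples) is compared to
   the central 95% χ² band; OTUs above the 97.5% limit are **core**
   (environmentally structured), the rest **satellite** (randomly
   dispersed).
3. **Association inference** — all-pairs Spearman correlations over core
   OTUs, retaining |ρ| ≥ 0.6 with p < 0.001; signs are kept.
4. **Null-model validation** — checkerboard C-score
   C<sub>ij</sub> = (R<sub>i</sub> − S<sub>ij</sub>)(R<sub>j</sub> − S<sub>ij</sub>)
   against null matrices preserving site frequencies; the standardized
   effect size SES = (obs − null mean)/null sd flags non-random structure
   outside |SES| ≤ 2.
5. **Network analysis** — Louvain modules, average degree/clustering/path
   length/modularity, and contaminated-vs-pristine network comparison with
   group-specific edge re-estimation.
6. **Module–environment coupling** — module eigengenes (first singular
   vector of the standardized module profile) correlated with transformed
   environmental variables, and sequential PERMANOVA (Bray–Curtis)
   variance partitioning.

A synthetic community generator (`simulate_community()`) plants core and
satellite OTUs, co-occurrence modules (one negatively coupled to
fluoranthene and containing a predator–prey pair), correlated
environmental gradients and a contaminated/pristine PAH suite — with full
ground truth, so every stage is validated by recovery experiments.

## Worked example

```r
library(benthonet)

sim <- simulate_community(synthetic_design(), seed = 1)
cfg <- benthonet_config(n_null_matrices = 500, permutations = 199,
                        random_seed = 1)
res <- run_pipeline(sim$table, sim$metadata, sim$taxonomy, cfg,
                    out_dir = "results/demo")

res$sad
#> sad_partition: 120 core / 900 satellite OTUs (11.8% core, 95.6% of reads)
res$nullmodel
#> C-score null-model report (fixed_site_frequencies, 500 null matrices, seed 1)
#>   observed 1.5057 (normalized 0.0011); null 1.8021 +/- 0.0171
#>   SES = -17.329; p(greater) = 1, p(less) = 0.001996
res$network$topology
#> topology: 100 nodes, 415 edges | <k> = 8.30, <C> = 0.685, Q = 0.820, <path> = 2.00
```

Reading this: the dispersion-index test recovers the planted 120-OTU core
(11.8% of OTUs holding 95.6% of reads); the co-occurrence network over the
core is strongly non-random (|SES| ≫ 2 — here negative, i.e.
aggregation-dominated: the planted modules co-occur far more than the
site-frequency null expects), and is modular (Q = 0.82). The
module–environment table flags the planted PAH-sensitive module:

```r
subset(res$module_env$env_corr, variable == "fluoranthene" & p < 0.05)
#>   module     variable      r         p
#>        2 fluoranthene -0.692  3.95e-07
```

and PERMANOVA attributes more core-community variance to the salinity
proxy than to fluoranthene (direction, not magnitude, is the point):

```r
as.data.frame(res$module_env$permanova)
#>           term df     R2    F     p
#>       salinity  1 0.1300 6.32 0.005
#>   fluoranthene  1 0.0674 3.27 0.005
#>       Residual 39 0.8026   NA    NA
#>          Total 41 1.0000   NA    NA
```

Per-stage TSV/GraphML/JSON outputs land in `out_dir`, including a run
manifest recording the seed and every threshold. A thin CLI wrapper lives
at `inst/scripts/benthonet.R` (subcommands `run`, `simulate`, `partition`,
`classify`, `nullmodel`).

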