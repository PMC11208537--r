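# paddynet

Statistical pipeline for soil-microbiome surveys of heavy-metal polluted
paddy fields. Given per-sample soil properties, metal concentrations and a
16S OTU count table, the package computes:

- **Pollution indices** — per-metal contamination factors
  `CF = C / C_background`, the pollution load index
  `PLI = (∏ CF_i)^(1/n)` (geometric mean; PLI > 1 flags pollution), and
  pH-dependent cadmium risk screening (GB 15618-2018 thresholds:
  0.3 mg/kg for pH ≤ 5.5, 0.4 mg/kg for 5.5 < pH ≤ 6.5).
- **Diversity** — Sobs, bias-corrected Chao1, ACE, Shannon (bits),
  Good's coverage, Bray–Curtis dissimilarity, and seeded NMDS.
- **Environment–community associations** — polynomial regressions,
  Spearman taxon–environment grids with BH adjustment, Mantel and partial
  Mantel permutation tests, variation partitioning (Hellinger + partial
  RDA, adjusted R²), and random-forest importance (%IncMSE).
- **Co-occurrence networks** — Pearson correlations on log10 relative
  abundances of core OTUs (≥ 90% prevalence), with the cutoff *S_t*
  chosen by a random-matrix-theory criterion: the smallest threshold at
  which the eigenvalue nearest-neighbour spacing distribution of the
  thresholded matrix leaves the GOE (Wigner) regime and becomes Poisson.
  Downstream: topology (avgK, GD, avgCC, scale-free R²), greedy
  modularity, 100-fold degree-preserving null ensembles, Zi–Pi keystone
  roles (module hubs / connectors at z ≥ 2.5 / P ≥ 0.62), per-module
  environment Mantel tests, and GraphML/GEXF/TSV export.
- **Synthetic data** — a generator that plants known co-occurrence
  modules, hub taxa and a pH-like gradient into multinomial counts at
  realistic depths, so every stage can be validated against ground truth.

The in-survey soil and metal tables (15 sites, Taihu region paddy
fields) ship as plain-text fixtures together with the background
concentrations used for CFs.

## Worked example

```r
library(paddynet)

fx  <- paper_fixture()                     # packaged survey tables
pol <- assess_pollution(fx$metals, fx$backgrounds, fx$soil)
head(pol[, c("sample_id", "CF_Cd", "CF_Pb", "PLI", "polluted",
             "cd_exceeds_screen")], 4)
#>   sample_id CF_Cd CF_Pb  PLI polluted cd_exceeds_screen
#> 1      YX_1 14.73  1.72 1.51     TRUE              TRUE
#> 2      YX_2 20.09  1.70 2.18     TRUE              TRUE
#> 3      YX_3  4.18  2.97 2.08     TRUE              TRUE
#> 4      YX_4 89.09  2.65 3.05     TRUE              TRUE
min(pol$PLI)
#> [1] 1.145386
```

Every site's Cd contamination factor is far above 1 (Cd background
0.11 mg/kg), the PLI exceeds 1 at all 15 sites — the whole survey area is
polluted, chiefly by Cd and Pb — and most sites exceed the pH-dependent
Cd screening value.

A full run on synthetic data with planted structure:

```r
bundle <- generate_dataset(generator_params(loading = 1.5, noise_sd = 0.3,
                                            seed = 7))
core <- prevalence_filter(bundle$otu, 0.9)     # OTUs in >= 90% of samples
corr <- correlation_matrix(core)               # Pearson on log10 rel. abund.
scan <- rmt_threshold(corr)                    # RMT cutoff selection
scan$st
#> [1] 0.78
net   <- build_network(corr, scan$st)
mod   <- detect_modules(net)                   # greedy modularity
roles <- node_roles(net, mod)                  # Zi-Pi keystone roles
nulls <- null_model_ensemble(net, 100, seed = 1)
mod$modularity; nulls$modularity$mean
#> [1] 0.81294
#> [1] 0.1403239   # empirical Q far above the degree-preserving null
```

The recovered partition matches the planted modules (adjusted Rand index
≈ 1 in the shipped tests), and the planted hub taxa surface near the top
of the within-module degree ranking.

`run_pipeline()` orchestrates all stages from one (YAML) config and
writes TSV/JSON outputs plus a machine-readable report;
`inst/scripts/paddynet.R` is a thin command-line wrapper
(`synth` / `pollution` / `run`).

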