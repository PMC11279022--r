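# leafendo

Community-ecology inference for two-group amplicon surveys of plant
endophytes. The package takes ASV count tables (taxa × samples) for a
healthy-leaf group (HL) and a non-healthy-leaf group (NL) — typically one
table of 16S-derived bacterial ASVs and one of ITS-derived fungal ASVs —
and runs the full chain a leaf-microbiome study needs:

* **Diversity and ordination** — richness and Shannon index with Welch
  t-tests, exact rarefaction expectations, Bray–Curtis distances, NMDS
  (Kruskal stress-1), and one-way PERMANOVA with permutation p-values.
* **Health-sensitive ASVs (hsASVs)** — TMM/CPM normalization,
  negative-binomial likelihood-ratio differential abundance with BH
  correction (edgeR), group-size-corrected indicator species analysis
  (IndVal) with permutation tests, and the intersection rule: a taxon is an
  hsASV iff both analyses call it (q < 0.05 and indicator p < 0.05).
* **Co-occurrence networks** — Spearman correlations within each kingdom,
  thresholded into a meta network (r > 0.6, p < 0.001) or per-group
  networks (bacteria r > 0.8, fungi r > 0.7, p < 0.01), greedy (CNM)
  modularity, module summaries (hsASV content, cumulative CPM per group,
  class composition), and topology metrics (nodes, edges, mean normalized
  betweenness, degree assortativity).
* **Assembly processes** — Levins' niche breadth
  `B_j = 1 / Σ_i P_ij²`, the Sloan neutral community model
  `freq(p) = 1 − Beta(d; N m p, N m (1 − p))` fitted for the migration
  rate m with bootstrap CIs and a 95 % prediction envelope, and C-score
  null-model analysis (`CU_ij = (R_i − S_ij)(R_j − S_ij)` averaged over
  taxon pairs) with sequential-swap randomization and
  `SES = (C_obs − mean(null)) / sd(null)`.
* **Synthetic communities with ground truth** — a generator that emits
  neutrally assembled two-group datasets (tunable migration rate,
  log-normal metacommunity, realistic library sizes), with optional known
  differential taxa, deterministic selection in the NL group, and
  correlated taxon blocks, so every stage of the chain can be verified
  against a recoverable answer.

A pipeline driver (`run_pipeline()` / `summarize_run()` /
`simulate_tables()`, plus the thin CLI at `inst/scripts/leafendo`)
orchestrates all stages deterministically under one seed and writes
TSV/JSON/GraphML artifacts with provenance.

## Worked example

```r
library(leafendo)

spec <- synthetic_spec(n_taxa = 300, n_samples_per_group = 20, seed = 42,
                       selection_strength = 1)
ds <- generate_dataset(spec)
ds$table
#> count_table: 296 taxa x 40 samples (bacteria)

alpha_diversity(ds$table, ds$metadata)$tests
#>     metric statistic            p
#> 1 richness  1.612633 1.164657e-01
#> 2  shannon  7.876509 8.765455e-09

pm <- permanova(bray_curtis(ds$table), ds$metadata, 999, seed = 1)
sprintf("F = %.3f, R2 = %.3f, p = %.3f", pm$pseudo_F, pm$R2, pm$p)
#> "F = 13.110, R2 = 0.257, p = 0.001"

filt <- prevalence_filter(ds$table, 5, 2)
hs <- identify_hsasvs(
  nb_lrt_differential(filt, ds$metadata, tmm_normalize(filt)),
  indval(filt, ds$metadata, n_perm = 999, seed = 2))
sum(hs$hs_flag)
#> [1] 108

hl <- subset_samples(ds$table, ds$metadata$sample_id[ds$metadata$group == "HL"])
ncm_fit(hl, n_bootstrap = 200, seed = 3)
#> Sloan NCM fit: m = 0.0910 (95% CI 0.0813-0.1043), R2 = 0.9176, N = 43335, 294 taxa

sequential_swap_null(presence_absence(prevalence_filter(hl, 5, 2)),
                     n_sim = 2000, burn_in = 500, thin = 10, seed = 4)
#> C-score: observed 1.2207, null 1.1931 +/- 0.0155, SES = 1.78 (2000 sims, 500 burn-in)
```

Reading the numbers: the Shannon contrast is strongly significant (the
selection-perturbed NL group is less even), PERMANOVA separates the two
groups (R² = 0.26 of the Bray–Curtis variation), 108 taxa are flagged
health-sensitive (the 20 seeded fold-change taxa plus taxa genuinely
shifted by the selection perturbation), the healthy group's fitted
migration rate recovers the generator's m = 0.1 within its bootstrap CI,
and its C-score SES of 1.8 is inside the |SES| < 2 random band — the
neutral group shows no significant co-occurrence structure.

End-to-end on files:

```r
paths <- simulate_tables("sim", synthetic_spec(seed = 1))
cfg <- pipeline_config(counts_bacteria = paths$bacteria,
                       counts_fungi = paths$fungi,
                       metadata = paths$metadata, out_dir = "run", seed = 1)
run_pipeline(cfg)
summarize_run("run")   # one row per kingdom x group:
                       # richness/Shannon, network topology, niche breadth,
                       # NCM m and R2, C-score SES
```

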