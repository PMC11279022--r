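---
title: "Methods and design notes for leafendo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for leafendo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

leafendo analyzes two-group (healthy vs non-healthy leaf, HL/NL) ASV count
tables through four linked stages: diversity/ordination, health-sensitive
taxon detection, co-occurrence networks, and assembly-process inference.
This vignette explains the models behind each stage, the parameters that
matter, the synthetic generator the verification rests on, and the design
decisions taken where more than one defensible convention exists.

## Data model

All abundance matrices are oriented **taxa × samples** with unique string
identifiers on both axes; empty samples are rejected at construction.
Counts are integer reads. On-disk formats are plain TSV (first column
taxon id, header row sample ids, UTF-8, no quoting) and the dense-JSON
flavor of the BIOM schema; sparse BIOM variants are rejected with a clear
message rather than half-supported. Both formats round-trip bit-exactly.
Permutation p-values use the add-one convention `(hits + 1)/(n + 1)`
throughout, so the smallest attainable p is `1/(n + 1)`.

## Diversity and ordination

Shannon diversity uses the natural log (the ecology convention; the choice
only rescales the index). Alpha diversity is computed on unrarefied counts
by default with an optional rarefy-to-common-depth switch; rarefaction
curves use the exact hypergeometric expectation
`E[S(d)] = S − Σ_i C(T − n_i, d)/C(T, d)` rather than Monte-Carlo
subsampling — it is the quantity the subsampling would converge to, with
no seed to document. Bray–Curtis distances, NMDS, and PERMANOVA delegate
to vegan: NMDS is Kruskal's stress-1 with monotone regression on pooled
distance ranks (ties averaged), best of `n_starts` random restarts,
coordinates centered; PERMANOVA is Anderson's one-way distance partition
with `pseudo-F = (SS_between/(a−1))/(SS_within/(N−a))`, and its F-value is
cross-checked in the tests against an independent implementation of the
partition, with the permutation p checked against exhaustive enumeration
on six-sample problems.

Group location contrasts are Welch's t-test (group variances are nowhere
assumed equal) or a Wilcoxon rank-sum on mid-ranks. The Wilcoxon is exact
— full enumeration of label splits, which remains valid under ties — when
the number of splits is at most 1e5, and switches to the tie-corrected
normal approximation beyond that.

## Health-sensitive ASVs

Normalization is TMM (trims: 30 % on M-values, 5 % on A-values; reference
by the 75th-percentile rule; factors rescaled to geometric mean 1) with
CPM on effective library sizes, computed by edgeR — the package this
normalization originates from. Differential abundance is the NB GLM
likelihood-ratio test (edgeR `estimateDisp` + `glmFit`/`glmLRT`,
chi-squared(1) reference, BH adjustment).

One important guard: the NB-LRT is anti-conservative for taxa observed in
only a handful of samples. A rare taxon that lands entirely in one group
by chance has an exchangeability probability of order 1e-2, yet the LRT
can assign it p ~ 1e-4, and such taxa then survive BH. We therefore apply
edgeR's `filterByExpr` before dispersion estimation (edgeR's own
documented requirement for low counts); it is exposed as
`expr_filter = FALSE` for users who want the unfiltered behavior. Taxa
excluded by the filter are reported as untested and can never be flagged
health-sensitive. Even with the guard, about 5 % of truly null datasets
yield at least one hsASV — that is the Benjamini–Hochberg expectation
(P(any rejection) ≈ α under a global null), carried by ubiquitous taxa
with genuine chance group differences, and no valid test removes it.

IndVal uses the group-size-corrected form: specificity
`A_g = mean_g(rel) / Σ_g' mean_g'(rel)` on per-sample relative counts
(making the statistic invariant to rescaling any one library), fidelity
`B_g` the within-group occurrence fraction, `IndVal_g = sqrt(A_g B_g)`.
Significance comes from label permutations of the max-over-groups
statistic (the association is two-sided with respect to health status);
an `exact = TRUE` mode enumerates all distinct splits for small designs
and is checked against a brute-force oracle in the tests.

A taxon is an hsASV iff the BH-adjusted differential q and the indicator
permutation p both fall below their thresholds (defaults 0.05 and 0.05).
The assigned group is the indicator's best group; disagreement with the
fold-change sign is flagged `discordant` rather than silently resolved.

## Co-occurrence networks

Spearman correlations (mid-rank Pearson-on-ranks, p from the t
approximation on n − 2 df) are evaluated within each kingdom only;
cross-kingdom pairs are excluded by default (a flag enables them) since
bacterial and fungal abundances come from different amplicons whose
CPM scales are not directly comparable. Constant taxon profiles give NA
correlations and can never become edges. Edge selection uses raw
p-values — faithful to the source workflow, which applies no
multiple-testing control at this step — with an optional BH mode, off by
default. Default thresholds: meta network r > 0.6, p < 0.001; per-group
networks r > 0.8 (bacteria) / r > 0.7 (fungi), p < 0.01, after the
prevalence prefilters (≥ 2 reads in ≥ 5 samples for bacteria, ≥ 3 for
fungi). Isolated nodes are dropped.

Modules come from Clauset–Newman–Moore greedy modularity maximization on
the unweighted graph (igraph's `cluster_fast_greedy`, deterministic
agglomeration order), guarded so the returned partition never scores
below the connected-components partition (igraph's cut can otherwise
return Q < 0 on, e.g., complete graphs). Topology metrics: mean
*normalized* shortest-path betweenness (Brandes; node values divided by
`(n−1)(n−2)/2`) and Newman degree assortativity, reported NA when the
endpoint degree variance is zero. "Degree of betweenness" is ambiguous in
the literature this follows; the mean of normalized node betweenness is
our documented reading, recorded in the output metadata. Module summaries
report member counts, hsASV content per group, cumulative member CPM per
sample summarized mean ± SD per group, and class-level composition; a
module is flagged *sensitive* when its hsASV fraction is positive and
exceeds a configurable quantile (default the median) of all module
fractions. Fruchterman–Reingold coordinates are presentation-only and
never affect any metric.

## Assembly processes

**Levins' niche breadth.** `B_j = 1/Σ_i P_ij²` with `P_ij` the fraction
of taxon j's total found in sample i, so `B_j` ranges from 1 (single-site
specialist) to N (perfectly even generalist) and is invariant to scaling
a taxon's counts. Community breadth per sample is the unweighted mean of
`B_j` over the taxa present. For the HL-vs-NL contrast each group is
treated as its own metacommunity — B computed over that group's samples,
per-sample community breadths compared by Wilcoxon. This is our reading
of "the total number of communities in each meta-community"; the pooled
alternative (one 40-sample metacommunity) measures mostly present-set
membership (which taxa survive in each group) rather than within-group
specialization, and is available by calling `levins_breadth()` without
metadata on any sample subset. Raw counts are used by default; the
proportions P are scale-free per taxon, so CPM input gives nearly
identical results.

**Sloan neutral community model.** For taxon j, `p_j` is its mean
relative abundance and `freq_j` its occurrence fraction; the neutral
expectation is `freq(p) = 1 − Beta(d; N m p, N m (1 − p))` with N the
mean library size, d the detection limit (default 1/N, the convention of
the standard implementation, exposed as a parameter), and m the migration
rate. m is fitted by bounded least squares on (1e-4, 1]: a 25-point log
grid locates the basin, golden-section refinement to tolerance 1e-9
finishes it (the SS is unimodal in m in practice; the grid guards against
plateaus at extreme m). `R² = 1 − SS_res/SS_tot`. The 95 % envelope uses
Wilson binomial intervals around the predicted frequency at n = number of
samples, partitioning taxa into above/within/below. The bootstrap CI on m
resamples **taxa** — they are the observations of this regression — with
1000 replicates by default.

Two detection models are provided. `"threshold"` (default) is the classic
convention: a taxon is detectable iff its latent relative abundance
exceeds d. On finite count data detection is really read sampling —
`P(detect) = 1 − E[(1 − q)^N]`, which for beta-distributed q has the
closed form `1 − B(a, b + N)/B(a, b)` — and the threshold convention
consequently over-estimates m by roughly a quarter at N = 5000 (we
verified this by direct integration). `detection = "sampling"` implements
the exact form and is what the parameter-recovery experiments use; the
threshold default is kept for comparability with published fits, whose m
values carry the same bias.

**C-score and the sequential-swap null.** The C-score is the mean of
checkerboard units `CU_ij = (R_i − S_ij)(R_j − S_ij)` over unordered
taxon pairs of the presence/absence matrix. The null model preserves both
row and column totals: repeatedly pick a random 2 × 2 submatrix and swap
it when it is a checkerboard. After `burn_in` warm-up attempts the score
is recorded every `thin`-th attempt for `n_sim` records (defaults 30,000
records, 500 burn-in, thin 1 — the sequential-swap convention).
`SES = (C_obs − mean(null))/sd(null)`; a degenerate null (sd = 0, e.g. a
bare 2 × 2 checkerboard whose chain alternates between its two
equal-score states) reports SES as NA with a diagnostic. The chain
updates the score incrementally — a swap touches two rows, so only pairs
involving those rows are recomputed.

Two practical notes. First, short chains are serially correlated and
understate the null SD; at the reduced length the tests use (n_sim =
2000) we set `thin = 10`, which restores the |SES| < 2 coverage of
random fixed-fill matrices to its nominal level (the full-length default
needs no thinning). Second, the sign semantics — SES < −2 aggregation,
SES > +2 segregation — operationally mean checkerboard-*poor* vs
checkerboard-*rich* relative to the fixed margins. Because the total
pairwise sharing `Σ S_ij` is fixed by the column totals, the C-score is
convex in the sharing distribution: naive "aggregated" constructions
(nested matrices, duplicated supports, common sample subsets) force
compensating segregation elsewhere and *raise* the score. The sign tests
therefore construct aggregated matrices by margin-preserving greedy
C-score minimization and segregated ones by maximization or disjoint
supports.

## The synthetic generator

`generate_dataset()` emulates the statistical structure the analysis
assumes, with every deviation from neutrality injected explicitly:

* **Metacommunity**: log-normal relative abundances (sigma = 2 by
  default), the standard species-abundance-distribution choice, giving a
  realistic rare-taxon tail.
* **Neutral assembly**: each sample's composition is
  Dirichlet(N m p_1, …, N m p_K) via normalized gammas — exactly the
  Beta(N m p, N m (1 − p)) Sloan marginals with an exact sum to one —
  then multinomially read-sampled to the library size. Defaults: m = 0.1,
  20 samples per group, libraries uniform on 5,000–75,000 reads, 500 taxa
  per kingdom (the scale of a filtered leaf-endophyte table).
* **Differential taxa** (default 20 at fold change 4, half up, half down)
  shift the NL metacommunity before drift — detectable but
  neutrality-preserving. The modified subset's total mass is preserved so
  unmodified taxa keep identical metacommunity abundance: between-group
  structure comes only from injected effects, keeping ground truth
  unambiguous.
* **Selection** (off by default; `selection_strength` = variance of log
  fitness) multiplies the drift-sampled composition of NL sample s by
  `exp(sqrt(ss) · z_j · w_s)`: fixed per-taxon susceptibility z_j and a
  per-leaf exposure w_s (log-normal, unit second moment) reflecting that
  decline severity varies among non-healthy leaves. Applied after drift,
  it distorts the occupancy–abundance relationship (lowering NCM R²) and
  narrows within-group niche breadth. With sample-constant multipliers
  the breadth effect largely cancels — a multiplier common to all of a
  taxon's samples divides out of its own occupancy profile — which is why
  the exposure gradient is part of the design.
* **Correlated blocks** (default 4 blocks of 10): a shared log-normal
  latent factor per block per sample, applied in both groups, with its
  scale calibrated so the realized within-block Spearman correlation
  matches `block_rho` (`tau² = rho/(1 − rho) · v̄`, v̄ the typical
  log-abundance drift noise of a block member). Blocks occupy the most
  abundant taxa so they survive prevalence filtering, and differential
  taxa fill blocks first, giving module-level ground truth.
* **Determinism**: one seed; each sample draws from its own derived
  sub-seed, so per-sample draws are order-independent.

What the generator does *not* emulate: sequencing error, chimeras, PCR
compositional artifacts, taxonomic mis-assignment, phylogenetic signal,
or genuine cross-kingdom coupling. Passing tests therefore demonstrate
the inference chain's correctness and calibration under the stated
generative assumptions — not robustness to those real-data artifacts.

## Pipeline

`run_pipeline()` executes filter → alpha/beta (+tests) → TMM/CPM →
differential + IndVal → hsASV → meta network + modules + summaries →
per-group networks + topology → niche breadth + NCM + C-score → summary,
writing every artifact under one output directory with a provenance file
(config, seed, package version, input digests). Stage seeds derive
deterministically from the global seed, so a run is byte-identical on
re-execution (the wall-clock log aside) and stages can be reproduced in
isolation. A failing stage halts with its name; completed artifacts
persist. Alpha/beta diversity and the assembly stage run on the full
tables; normalization, hsASV detection, and networks run on the
prevalence-filtered tables (the differential test additionally applies
its abundance filter, as above).

Study-scale defaults (999 PERMANOVA permutations, 9999 IndVal
permutations, 30,000 swap records, 1000 bootstrap replicates) are config
fields; the test suite and the acceptance script scale them down (199
IndVal permutations, 2000 swap records with thin 10, ≤ 200 bootstrap
replicates) and use 120–2000-taxa, 8–20-samples-per-group datasets —
sizes chosen so the whole verification runs in minutes while every
statistic remains well-resolved at its stated tolerance.

## Known limitations

* Single two-level factor only; no covariates, no multi-factor designs,
  no compositional (CLR/ALR) alternatives to TMM.
* NCM fits assume one metacommunity per fitted table; kingdoms and groups
  are fitted separately.
* Network inference is marginal correlation, not conditional independence
  (no SparCC/SPIEC-EASI); modularity is unweighted.
* The per-dataset hsASV false-positive rate is bounded by the BH
  guarantee (~5 % of null datasets yield ≥ 1 call), not zero.
* UniFrac and other phylogeny-aware metrics are out of scope (no tree).
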