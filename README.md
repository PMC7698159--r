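# budclock

Downstream statistics for a dated, replicated bulk RNA-seq time series
from field-grown perennial buds (the motivating system is grapevine bud
development across one growing season, June–November). For researchers
who have per-gene read counts, a sample sheet and a daily weather series
and want to know:

- whether a keyword-defined gene set (canonically heat-shock proteins:
  descriptions containing both "heat" and "shock") tracks daily mean air
  temperature more strongly than chance, and
- which genes are stable, highly expressed qRT-PCR reference candidates.

## What it computes

- **Normalization** — CPM (`cpm()`) and RPKM (`rpkm()`), with CPM-sum
  detectability filters (`filter_by_expression_sum()`; conventions: ≥ 10
  before correlation, ≥ 500 for reference candidates, `>=` comparison).
- **Gene set vs environment** — per-sample median (or mean) of the set is
  paired with the temperature of each sampling date; Spearman's ρ (midranks
  + Pearson) with an analytic two-sided p from
  `t = ρ·sqrt((n−2)/(1−ρ²))`, calibrated against random gene sets of the
  same size from genes passing the same cutoff
  (`environment_correlation()`, `random_set_null()`; empirical p uses the
  add-one estimator).
- **Reference genes** — stability score `sd/median` across all samples,
  ascending ranking of genes with CPM sum ≥ 500, top 20
  (`stability_score()`, `rank_reference_candidates()`).
- **Profiles** — replicate mean/min/max time courses
  (`replicate_summary()`), TF-family heatmap matrices (`family_heatmap()`),
  and an astronomical day-length model (`day_length()`, ±10 min at
  mid-latitudes).
- **Synthetic data** — `simulate_counts()` generates an 18 × 3 dated
  negative-binomial count matrix with planted temperature-coupled,
  housekeeping, switch, peak, background and silent gene classes plus a
  matching AR(1) seasonal temperature series, so every stage is testable
  without external data.

## Worked example

```r
library(budclock)

sim <- simulate_counts(seed = 1)          # counts, sheet, annotation, env, truth
v   <- cpm(sim$counts)

hsp      <- select_genes_by_keywords(sim$annotation, c("heat", "shock"))
eligible <- filter_by_expression_sum(v, 10)
focal    <- gene_set(intersect(hsp, eligible), "hsp")

corr <- environment_correlation(v, focal, sim$env, sim$sheet)
corr
#> <gene_set_correlation> hsp (median, per_sample)
#>   rho = 0.9803, p = 2.62e-38, n = 54

null <- random_set_null(v, eligible, length(focal), sim$env, sim$sheet,
                        n_draws = 200, seed = 7, rho_obs = corr$rho)
null
#> <null_distribution> 200 draws of 60 genes (seed 7)
#>   rho_obs = 0.9803, empirical p = 0.004975, z = 8.10

rank_reference_candidates(v, 500, 20)     # top-20 stability ranking
```

ρ = 0.98 with analytic p ≈ 10⁻³⁸ says the planted heat-shock-like set
tracks the simulated temperature almost perfectly on this synthetic world
(real keyword sets correlate far more weakly); the empirical p = 0.005 is
the calibrated statement — none of 200 size-matched random sets reached
the observed ρ. In the ranking, all 20 planted housekeeping genes occupy
the top 20 (their stability scores ≈ 0.08 versus ≥ 0.2 for everything
else).

## Command line

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","budclock.R",package="budclock"))')" \
    run --out out_dir --seed 1           # simulate + full pipeline + report.json
# subcommands: simulate | run | envcor | refgenes | profiles
```

Outputs are TSV/CSV tables plus a JSON run report echoing every threshold
and seed; reruns with the same configuration and seed are byte-identical.

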