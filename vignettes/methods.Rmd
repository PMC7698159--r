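---
title: "Methods: seasonal bud transcriptome analysis with budclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seasonal bud transcriptome analysis with budclock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Perennial buds develop in the field across a full season, so their
transcriptome reflects two entangled signals: an internal developmental
program (for grapevine buds, a program switch around July coinciding with
floral transition and rising dormancy-marker expression) and the
environment, foremost air temperature. `budclock` implements the
downstream statistics for a dated, replicated bulk RNA-seq time series:
given per-gene read counts, a sample sheet, and a daily mean-temperature
series, it asks whether the aggregate expression of a gene set defined by
annotation keywords (canonically heat-shock proteins, "heat" and "shock"
together in the description text) tracks temperature more strongly than
random gene sets of the same size and the same expression cutoff, and it
predicts stable, highly expressed qRT-PCR reference genes.

## Model and procedure

**Normalization.** Counts per million for gene $g$ in sample $s$ are
$\mathrm{CPM}_{gs} = 10^6 \, c_{gs} / \sum_g c_{gs}$; RPKM additionally
divides by the gene length in kilobases. The per-sample denominator is the
column sum of the delivered count matrix (reads assigned to genes). The
original alignment totals before read assignment are unavailable
downstream, so "per million mapped reads" is interpreted as "per million
assigned reads"; this is recorded here as a package-level convention and
both filters and correlations are self-consistent under it. No
between-sample normalization (TMM, DESeq size factors) is applied: the
method operates on plain CPM/RPKM by design.

**Detectability filters.** A gene passes a filter when its CPM sum over
*all* samples is greater than or equal to the threshold. Two thresholds
matter: 10 (before gene-set/temperature correlation) and 500 (reference-gene
candidates). The comparison is `>=` in both cases; the reference-gene
threshold is stated as "greater or equal" in the underlying protocol and
the same convention is applied to the cutoff of 10.

**Gene-set vs temperature correlation.** The set is aggregated per sample
(median by default; mean available) and each observation is paired with the
daily mean temperature of its sampling date — the day's value only, no
window averaging, because the pairing should stay explicit and auditable.
Spearman's $\rho$ is the Pearson correlation of midrank-transformed values
(average ranks on ties); the analytic two-sided p-value uses
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ with $n-2$ degrees of freedom. Default
pairing is per sample (each replicate one observation, $n = 54$ in the
emulated design) rather than per time point ($n = 18$): a printed
$p = 10^{-4}$ at $\rho \approx 0.5$ is only consistent with the larger
$n$, and the per-time-point mode is retained as an option because summary
figures typically display per-date medians. Neither mode is asserted to be
the published computation; both are provided.

**Matched random-set null.** Because annotation-keyword sets are not
random draws (they share expression levels and functions), the analytic p
is calibrated against random gene sets of the same size drawn without
replacement from the genes passing the same CPM-sum cutoff. The empirical
p uses the add-one estimator $(1 + \#\{|\rho_{null}| \ge |\rho_{obs}|\}) /
(1 + n_{draws})$ so finite resampling never reports zero. The draw seed is
recorded in the result and the run report.

**Reference-gene ranking.** Candidates pass the CPM-sum $\ge 500$ filter
and are ordered by the stability score $\mathrm{sd}/\mathrm{median}$
computed across all samples (replicates as separate observations, matching
"across all samples" taken literally; the median is of all values, not of
replicate means). The SD uses the sample ($n-1$) denominator — the
underlying protocol does not specify, $n-1$ is the small-sample
convention, and switching is a one-line change. Ties are broken
lexicographically by gene id so the ranking is fully deterministic. The
top 20 are reported by default.

**Keyword matching** is plain case-insensitive substring matching, not
word-boundary matching: "heat" also hits "heatmap". That collision is
accepted deliberately — the selection rule is defined on strings, and
silently switching to word boundaries would change set membership.

**Day length** uses a closed-form solar model (Fourier-series solar
declination over the day of year; sunrise/sunset at solar altitude
−0.833°, i.e. refraction plus solar radius) instead of scraping published
sunrise tables. Against an independent NOAA-style Julian-day computation
the model is within ~3 minutes at 49.218° N (frozen oracle values:
16.2378 h on 2016-06-21, 8.1907 h on 2016-12-21); the accuracy target is
±10 minutes, ample for plotting photoperiod next to expression. Polar
latitudes (|lat| > 66°) are rejected rather than approximated.

## The synthetic-data generator

`simulate_counts()` states a world resembling the emulated field design:
18 sampling dates with 3 replicates between 2016-06-01 and 2016-11-03; a
daily temperature series as a seasonal sinusoid (level 12 °C, half-range
9 °C, warmest around day 196) plus AR(1) noise (lag-1 correlation 0.7,
innovation SD 2.5 °C) — values typical of a south-west German summer and
autumn; log-normal library sizes around $10^6$ (SD 0.15 on the log scale)
so CPM's library-size correction is actually exercised; gene lengths
uniform on 500–5000 bp.

Six planted classes (60 temperature-coupled, 20 housekeeping, 40 switch,
20 transient-peak, 800 background, 60 near-silent genes) draw
negative-binomial counts with per-class dispersion (housekeeping 0.005 —
nearly Poisson; background 0.2 — strongly overdispersed; others 0.05).
Temperature-coupled genes move their natural-log mean by 0.08 per °C
around the series mean and carry "heat shock protein" in their
description, so keyword selection doubles as truth recovery. Switch genes
step up or down by 1.5 log units through a logistic with a 5-day time
constant centred on 2016-07-15. All randomness flows from one seed through
derived sub-streams (temperature, gene parameters, counts), so enlarging
the gene universe does not perturb the temperature series.

What a green test does **not** establish: the generator has no
compositional structure beyond the planted classes, no batch or lane
effects, no GC/length bias, no annotation errors, and its keyword planting
is exact by construction — real annotation text is noisy, and real HSP
sets contain non-responsive homologs. Green means the statistics do what
they claim on data whose truth is known, not that the biological numbers
of any particular dataset are reproduced.

## Numerical choices and degenerate inputs

- Analytic Spearman p at $|\rho| = 1$ is clamped to the smallest positive
  double rather than 0, keeping p in (0, 1].
- For $n \le 7$ without ties, the t-approximation deviates from the exact
  permutation p by at most ≈0.15 (measured over 160 random cases; worst
  near perfect correlation at tiny n). Tests assert a 0.16 band; at the
  default $n = 54$ the approximation is accurate.
- Constant aggregate vectors, zero-count sample columns, genes missing
  from annotation, sampling dates missing from the weather series, and
  empty post-filter sets all raise classed errors instead of NaN.
- Dates are ISO-8601 at daily resolution; impossible dates (2016-06-31)
  are format errors, and a missing temperature for a sampling date is an
  error, never interpolated.

## Null-calibration scenario

The calibration check demands that with *all genes uncoupled from
temperature* a random focal set is rarely called significant and the null
mean is near zero. Setting only the coupling coefficient to zero is not
enough: switch and peak genes remain calendar-coupled, and since
temperature itself trends over the season they correlate with it
indirectly — both directly and compositionally, because a coordinated
up-switch of 40 genes deflates every other gene's CPM. The calibration
scenario therefore also removes the switch and peak classes (measured:
null mean −0.016; 98 of 100 random focal sets with empirical p > 0.05).
The compositional effect is real in field data too, which is exactly why
the matched random-set null — which inherits the same confounding — is the
right control for a keyword set.

## Known limitations

- CPM/RPKM are compositional; the package deliberately does not correct
  for it (the matched null inherits it instead).
- The per-sample/per-time-point ambiguity of the published correlation is
  documented, not resolved.
- The stability score is SD/median only; geNorm/NormFinder-style pairwise
  stability measures are out of scope.
- The day-length model ignores elevation and horizon obstruction.
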