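# kbscan

Strong NF-kB binding sites rarely act alone. Promoters and enhancers of
NF-kB-responsive genes typically carry one high-affinity kB site (consensus
`GGGRNNYYCC`) surrounded by a cluster of low-affinity ("weak") sites, and
in-cell occupancy measured by ChIP tracks the *summed* affinity of the
cluster better than the affinity of the single strongest site. `kbscan` is
an R package for quantifying that effect, aimed at regulatory-genomics
analysts working with TF binding-site affinity tables, ChIP peak sets and
DNA-pulldown proteomics.

It provides four connected analyses:

1. **Site designation and classification.** Every 10-bp window of a
   sequence (both strands) is designated a kB site when its 10-mer appears
   in an affinity Z-score lookup table with Z > 0 and deviates from
   `GGGRNNYYCC` at ≤ 3 positions. Sites with Z ≥ 6 are *strong*, below 6
   *weak* (the boundary corresponds to roughly K<sub>D</sub> ≈ 300 nM).
2. **Cumulative Z-scores and correlation curves.** For each ChIP peak
   (±500 bp), the cumulative Z at window length *L* is the sum of Z over
   designated sites whose centers lie within ±*L*/2 of the strongest
   motif's center. Pearson's *r* between ChIP scores and cumulative Z is
   traced over *L* = 10…500 bp, with and without weak-site contributions,
   plus a pooled-variance t-test comparing weak-site counts between
   occupancy-ranked peak halves.
3. **Equilibrium occupancy projection.** Fraction bound
   *f* = *C* / (*C* + *K*<sub>D</sub>) under the free-ligand
   approximation — e.g. a weak site with *K*<sub>D</sub> = 3 µM is only
   ~6% occupied at 200 nM nuclear TF.
4. **Pulldown enrichment.** DNA-pulldown mass-spec peptide-count matrices
   are filtered (total count < 5 excluded), normalized per pulldown,
   converted to per-protein Z-scores, and proteins with mean experimental
   minus mean control Z strictly above 0.5 are called enriched; optional
   seeded k-means clusters rows for heatmaps.

A synthetic-data module generates affinity tables, peak cohorts with
planted site clusters, and count matrices with known ground truth, so the
entire pipeline runs and is validated without any external downloads.

## Worked example

```r
library(kbscan)

tbl <- gen_zscore_table(150, seed = 42)
tbl
#> Affinity Z-score table (150 10-mers, source: synthetic (seed 42))
#>   Z range: 0.98 .. 18.29; 150 entries with Z > 0

co <- gen_peak_cohort(cohort_spec(n_peaks = 60, seed = 42), tbl)
co$peaks[[1]]
#> Peak region 'peak_001': chip_score 4.63, 3 kB site(s) (1 strong, 2 weak),
#>   anchor GGGAGACAAC (Z = 6.45) centered at offset 499.5 of 1001 bp

correlation_curve(co$peaks, c(10, 50, 150, 500))
#>   window_length     r_all r_strong_only
#> 1            10 0.3628985     0.3559232
#> 2            50 0.5253445     0.3618755
#> 3           150 0.6645726     0.3598966
#> 4           500 0.7349817     0.3607528
```

The curve shows the core phenomenon: at a 10-bp window (the anchor alone)
occupancy correlates weakly (*r* ≈ 0.36); widening the window to the
planted ~150-bp cluster span raises *r* to ≈ 0.66, while removing the weak
sites' contributions (`r_strong_only`) pins the correlation at the
anchor-only level — the weak cluster carries the signal.

```r
unlist(compare_ranked_halves(co$peaks)[c("mean_top", "mean_bottom",
                                         "t_statistic", "p_value")])
#>     mean_top  mean_bottom  t_statistic      p_value 
#> 6.0000000000 4.0333333333 3.9381646981 0.0002227847
```

High-occupancy peaks carry on average 6.0 weak sites against 4.0 for
low-occupancy peaks (pooled t-test, p ≈ 2e-4).

```r
round(100 * fraction_bound(c(200, 250), 3000), 2)
#> [1] 6.25 7.69
```

At 200–250 nM nuclear dimer, a 3-µM weak site is only ~6–8% occupied at
equilibrium — individually negligible, which is why the clustered,
cumulative analysis above is the informative one.

```r
gp <- gen_pulldown(50, n_experimental = 4, n_control = 2,
                   n_enriched = 5, effect_size = 20, seed = 42)
res <- pulldown_enrichment(gp$matrix)
res
#> Pulldown enrichment: 50 proteins retained (total count >= 5), 5 passed (score > 0.5)
identical(sort(names(res$passed)[res$passed]), gp$enriched)
#> [1] TRUE
```

The enrichment filter recovers exactly the five planted proteins.

A pipeline driver (`run_pipeline()`, with subcommands `simulate`, `scan`,
`correlate`, `occupancy`, `pulldown`, `all` and a thin CLI wrapper in
`inst/scripts/kbscan.R`) orchestrates these stages over FASTA /
narrowPeak / TSV files and writes a checksummed, timestamp-free manifest,
so one seed reproduces a run byte for byte.

## Package layout

- `R/scan.R`, `R/zscore_table.R` — site designation against an affinity
  table (`designate_sites()`, `consensus_mismatches()`, `classify_site()`).
- `R/cluster.R` — peak regions, anchors, `cumulative_z()`,
  `correlation_curve()`, `compare_ranked_halves()`.
- `R/occupancy.R` — `fraction_bound()`, `occupancy_table()`.
- `R/pulldown.R` — `pulldown_enrichment()` and its stages.
- `R/simulate.R` — `gen_zscore_table()`, `gen_peak_cohort()`,
  `gen_pulldown()` with planted truth.
- `R/io.R`, `R/pipeline.R` — FASTA/narrowPeak/TSV round-trips,
  `run_pipeline()`, manifests.
- `vignettes/kb-site-clusters.Rmd` — the model, parameter rationale, and
  what the synthetic benchmarks do and do not demonstrate.
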