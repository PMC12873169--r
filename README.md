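# corestab

Core microbiota, temporal stability and taxa-function robustness for
longitudinal gut-microbiome cohorts sampled across life stages (Infant /
Adult / Elder).

corestab is for microbiome researchers who follow individuals over months
to years with repeated genus-level 16S profiles and want, from one seeded
pipeline:

* **Core microbiota** — per-group taxon prevalence at a relative-abundance
  detection limit (presence = abundance > 1e-4), cores at the 100/80/50%
  prevalence levels, and the seven-region membership partition across the
  three age groups.
* **Temporal similarity** — within-individual Jaccard similarity as a
  function of the time lapse between samples (60-day bins), and the
  *Jaccard core index* `JCI = |C∩S| / (|C| + |S| − |C∩S|)` of each sample
  against a fixed 50%-prevalence reference core, tracked over subject age.
* **Taylor-law stability** — per-individual OLS fit of
  `log10 σ = log10 √V + β·log10 μ` over that individual's taxon moments, so
  that `σ² = V·μ^(2β)`: `β = ½` is the Poisson limiting class, `β = 1` the
  exponential class, and `V` is the variance a dominant taxon (μ ≈ 1) would
  attain — the community's instability amplitude. Fits are standardized to
  the Adult group and classified against circular confidence regions of
  radius `r = √(−2·ln(1−p))` (the "healthy window", p = 0.68 / 0.98).
* **Taxa-function robustness** — project composition through a
  PICRUSt2-style genome-content table (16S copy-number corrected), knock
  out random taxa at increasing magnitudes, summarize the functional
  response `d_F = s·max(0, d_T − b)`, and standardize `(s, b)` against a
  shuffled-genome null: **attenuation** `(mean s_null − s_obs)/sd s_null`
  and **buffering** `(b_obs − mean b_null)/sd b_null`, globally or per
  KEGG-style pathway/superpathway.
* **Group statistics** — exact/tie-corrected two-sided Wilcoxon rank-sum
  contrasts between age groups with optional Benjamini–Hochberg adjustment.
* **Synthetic cohorts** — a generator with the same statistical structure
  (Taylor-law fluctuations, core/transient prevalence with an age trend,
  tunable genome redundancy), bit-reproducible from one seed, so every
  stage is testable without sequencing data.

## Worked example

```r
library(corestab)

tab <- generate_cohort(cohort_config(seed = 1))
tab
#> abundance_table: 60 taxa x 240 samples (30 individuals)
#>   samples per age group: I=80, A=80, E=80
#>   collection day range: 0..656

# cores at the three prevalence levels: size grows with age
ca <- core_analysis(tab)
sapply(ca$cores, function(th) sapply(th, nrow))
#>   1 0.8 0.5
#> I 0  24  25
#> A 0  24  35
#> E 1  24  57

# per-individual Taylor fits, healthy window at 68%
fits <- fit_taylor_cohort(tab)
aggregate(cbind(V, beta, r2) ~ age_group, fits, function(x) round(mean(x), 3))
#>   age_group     V  beta    r2
#> 1         A 1.231 0.947 0.970
#> 2         E 1.440 0.969 0.967
#> 3         I 0.908 0.915 0.977
table(classify_window(standardize_fits(fits), 0.68)$inside,
      fits$age_group)
#>         I A E
#>   FALSE 6 3 3
#>   TRUE  4 7 7

# within-individual Jaccard decay, Adults, 60-day bins
pairs <- pairwise_within_individual(tab)
head(bin_series(pairs[pairs$age_group == "A", ]), 3)
#>   bin gap_mid mean_jaccard sd_jaccard n_pairs
#> 1   0      30    0.5839980 0.05749620      25
#> 2   1      90    0.5981391 0.04794613      57
#> 3   2     150    0.5777834 0.04658940      39
```

Core size increases with age (25 → 35 → 57 genera at the 50% level) because
the generator gives transient taxa an age-increasing presence probability;
more Infants than Adults/Elders fall outside the 68% healthy window; and
individuals retain roughly 60% of their genera between samples. The fitted
β̂ ≈ 0.93–0.97 illustrates the small-sample upward pull toward the slope-1
boundary discussed in the methods vignette
(`vignettes/corestab-methods.Rmd`) — with 8 time points these are
comparative, not calibrated, estimates.

## Full pipeline and CLI

```r
run_pipeline("out/", pipeline_config(seed = 1))     # ~1.5 min, 1 CPU
rerun_from_manifest("out/manifest.json", "out2/")   # bit-identical re-run
```

or from the shell:

```sh
Rscript -e 'corestab::corestab_main()' all --seed 1 --out out/
Rscript -e 'corestab::corestab_main()' simulate --seed 1 --out sim/
Rscript -e 'corestab::corestab_main()' core --abundance sim/abundance.tsv \
    --metadata sim/metadata.tsv --thresholds 1.0,0.8,0.5 --out cores/
```

Subcommands: `simulate`, `core`, `jaccard`, `taylor`, `robustness`,
`compare`, `all`; global flags `--config PATH --seed INT --out DIR
--log-level LEVEL`.

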