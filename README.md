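# enamelgrowth

Tools for analysing incremental growth lines in tooth enamel and dentine,
aimed at dental histologists and palaeobiologists who estimate how fast
tooth crowns grew — in particular in non-mammalian cynodonts, whose
prismless enamel carries daily short-period laminations and accentuated
long-period lines every second day.

Enamel records its own growth history. Ameloblasts are recruited along the
enamel–dentine junction (EDJ) at the **crown extension rate** (CER, µm/day),
and each secretes enamel at the **daily secretion rate** (DSR, µm/day),
leaving daily incremental lines that mark successive positions of the
forming front. The package provides:

- a forward model of incremental amelogenesis/dentinogenesis
  (`simulate_section()`) that produces ground-truthed synthetic sections and
  polarized-light-style band images (`render_section_image()`);
- the **cumulative-length CER estimator** (`cumulative_cer()`): iterating
  from the cusp, a growth trajectory of length *A* is followed from the EDJ
  to an accentuated line; dividing by the local mean daily spacing gives
  *x = A / DSR* days, the EDJ advance over those days is *y*, and the daily
  extension rate is *y/x*. The crown average is Σ*y*/Σ*x* and Σ*x* is the
  crown formation time over the measured EDJ;
- DSR estimation between daily lines perpendicular to the outer enamel
  surface (`measure_dsr()`), and its image-side counterpart
  (`sample_transect()`, `detect_band_spacing()`);
- a **periodicity test** (`periodicity_concordance()`): enamel extension
  rates computed under candidate periodicities of the long-period lines are
  compared with the dentine extension rate from daily von Ebner lines over
  the same stretch of EDJ — under a 1-day reading the enamel rate doubles,
  so the dentine benchmark cleanly identifies the 2-day periodicity;
- the **comparative statistics chain** (`run_group_comparison()`):
  phylogenetic generalized least squares of log rates on log body mass
  under Brownian covariance, Box-Cox transformation of the residuals,
  MANOVA with Wilks' Λ and its exact F transform, pairwise two-group
  MANOVAs, univariate ANOVAs with pooled-SD post-hoc contrasts, and
  Kruskal–Wallis with Dunn tests — every pairwise family FDR-adjusted
  (Benjamini–Hochberg);
- a seeded species-level simulator (`simulate_species_dataset()`) with a
  built-in five-group amniote design (non-probainognathian cynodonts,
  mammaliamorphs, diapsids, non-hypsodont and hypsodont crown mammals)
  calibrated to the published group means (86.0 vs 10.1 µm/day mean CER in
  non-probainognathians vs mammaliamorphs).

For two response variables the exact F transform of Wilks' Λ is

    F = ((1 − √Λ)/√Λ) · ((ν_e − 1)/ν_h),  df = (2 ν_h, 2 (ν_e − 1)),

and the multivariate effect size is partial η² = 1 − Λ^(1/s),
s = min(responses, ν_h).

## Worked example

```r
library(enamelgrowth)

# a cynodont-like section: CER 88 um/day, DSR 1.5 um/day, 2-day repeat interval
sec <- simulate_section(section_config(cer = 88, dsr = 1.5, n_days = 12, seed = 42))

count_repeat_interval(sec)
#> [1] 2
measure_dsr(sec)
#> <dsr_estimate> mode prismless: mean DSR 1.500 um/day over 273 gaps (39 transects)
cumulative_cer(sec, p = 2)
#> <crown_growth_summary> p = 2 day(s) per long-period line
#>   6 segments: sum(y) = 1056.0 um over sum(x) = 12.0 days
#>   average CER 88.00 um/day, average DSR 1.500 um/day
periodicity_concordance(sec)
#> <periodicity_result> dentine rate 88.00 um/day
#>   p = 1: enamel CER 176.00 um/day (discordance 100.0%)
#>   p = 2: enamel CER 88.00 um/day (discordance 0.0%)  <- chosen
```

The repeat interval of 2 is read off the lines themselves; the concordance
test confirms it independently: only the 2-day reading of the long-period
lines matches the dentine extension rate (a 1-day reading doubles the
enamel estimate to 176 µm/day).

```r
# comparative stage on calibrated synthetic species data
tbl <- simulate_species_dataset(comparative_config(seed = 42))
res <- run_group_comparison(tbl, default_comparative_tree())
res
#> <group_comparison> 39 observations, 5 groups (species unit)
#>   MANOVA: Wilks' lambda 0.092, F(8, 66) = 18.93, p = 2.05e-14, partial eta^2 = 0.696
#>   ANOVA DSR: F(4, 34) = 7.36, p = 0.000222, partial eta^2 = 0.464
#>   ANOVA CER: F(4, 34) = 43.44, p = 6.6e-13, partial eta^2 = 0.836
tidy(res)     # long table of every test, with FDR-adjusted p-values
glance(res)   # one-row MANOVA summary
autoplot(res) # body-mass-corrected DSR-CER scatter by group
```

On this draw the non-probainognathian vs mammaliamorph contrast is
significant for CER (adjusted p ≈ 4e-06) but not for DSR (adjusted
p ≈ 0.71): fast crown extension, not thicker daily enamel, is what
distinguishes the stem group.

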