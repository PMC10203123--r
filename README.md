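# paleorange

Does being rare make a species more likely to go extinct? Ecological
neutral theory says yes: if all individuals have identical demographic
rates, small populations random-walk to zero sooner, so taxon abundance
and longevity should be positively correlated. The fossil record of
marine microplankton — deep-sea drill-core samples dated in Ma, with
thousands of specimens counted per sample — is one of the few places that
prediction can be tested directly at the species level.

paleorange is an R package for micropaleontologists and paleobiologists
running that test. It provides:

* **Occurrence I/O** — validated reading/writing of age-dated
  sample × species count matrices (CSV/TSV), with taxon metadata
  (taxonomic order C/N/S, biogeographic category E/C, species-level flag)
  and explicit exclusion lists for reworked or misidentified occurrences.
* **Range vetting** — for each species, first/last occurrence, the mean
  gap `g` between occurrences, an error bar of `e = max(1, ⌈g⌉)` samples
  on each range endpoint, and a filter cascade (edge, error-bar overflow,
  range-doubling) that keeps only species whose full range is credibly
  inside the study interval. Longevity is
  `L = midpoint(FO error bar) − midpoint(LO error bar)` in my.
* **Abundance metrics** — percent relative abundance
  `p_ij = 100·n_ij/N_j` within the species-level assemblage; per-species
  mean, maximum and SD over the range (zeros inside the range included)
  and their ln transforms; per-sample richness and Good–Turing/Chao
  coverage `C = 1 − (f1/n)·(n−1)f1/((n−1)f1 + 2f2)`.
* **The statistical battery** — OLS regressions `L ~ ln abundance` with
  residual diagnostics, one-way ANOVAs of longevity by order and by
  biogeography, a mixed model `L ~ ln ā + (1 | biogeo)` fit by ML, and
  AICc model comparison (`AICc = AIC + 2k(k+1)/(n−k−1)`).
* **Synthetic data** — a zero-sum Moran neutral-drift simulator with
  exactly tracked lifetimes, a niche generator with a *known*
  abundance–longevity coupling `β` for parameter-recovery tests, and
  region-shaped fixtures (a 97-sample Southern-Ocean-like composite and a
  14-sample tropical-Pacific-like site), all seed-deterministic.

Everything is tidyverse-native: functions take data frames / occurrence
tables and return tibbles, fitted models have `tidy()`, `glance()`,
`augment()` and `autoplot()` methods, and results chain with the pipe.

## Worked example

```r
library(paleorange)

tbl <- simulate_fixture("SO", seed = 1)   # Southern-Ocean-shaped synthetic data
tbl
#> <occurrence_table> 97 samples (22.65-0.04 Ma), 544 taxa (536 species-level), 721,680 specimens

run <- run_pipeline(tbl, label = "SO", quiet = TRUE)
run
#> <range_run> SO: 235 included species of 536 species-level taxa
#>   median longevity 6.59 my; ln mean RA regression R^2 = 0.000 (p = 0.853)
#>   mixed vs abundance-only model: delta AICc = 2.07

run$ols$mean
#> <range_ols> SO: longevity ~ ln mean RA  (n = 235)
#>   slope = 0.0328 (p = 0.853), R^2 = 0.0001, AICc = 1332.37

run$anova_order
#> <range_anova> longevity by order_code: F(2, 232) = 0.001931, p = 0.9981
```

Reading the output: of 536 species-level taxa, 235 survive vetting (the
rest touch the edge of the record, have overflowing error bars, ranges
more than doubled by their error bars, or no occurrences). This fixture
generates longevity independently of abundance, and the regression
recovers exactly that: a slope indistinguishable from zero, R² ≈ 0.0001,
p = 0.85. The ANOVA likewise finds no longevity differences among the
three radiolarian orders, and the mixed model adding biogeography is
worse than abundance alone by ΔAICc = 2.07, so the simpler model is
preferred. `autoplot(run$ols$mean)` draws the regression,
`plot_longevity_groups(...)` the violin/box comparison, and
`write_results(run, "out/")` exports the species table, model summaries,
residuals and a JSON headline summary.

To see the *neutral* world instead, where abundance does predict
longevity:

```r
sim <- simulate_neutral_community(J = 100, nu = 0.01, n_steps = 5e5, seed = 7)
cor.test(sim$species$mean_abundance, sim$species$longevity_my,
         method = "spearman", exact = FALSE)
#> rho = 0.83, p < 2.2e-16   (5,058 completed species lifetimes)
```

A thin command-line front end lives at `inst/cli/paleorange.R`
(`run --config run.yaml`, `simulate --which SO --out stem`).

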