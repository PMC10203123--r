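---
title: "Methods: vetting stratigraphic ranges and testing abundance as an extinction-risk predictor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vetting stratigraphic ranges and testing abundance as an extinction-risk predictor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Ecological neutral theory predicts that a taxon's population size and its
extinction risk are inversely related: rare species random-walk to zero
faster than common ones, so abundance and longevity should be positively
correlated. paleorange implements the pieces needed to test that
prediction against microfossil occurrence time series — deep-sea drill-core
samples dated in Ma, with specimen counts per species — and against
synthetic communities where the true answer is known.

The pipeline is: read and validate a sample × species count matrix, vet
species ranges so that only species whose full stratigraphic range is
credibly inside the study interval remain, summarize each survivor's
relative abundance over its range, and run the inferential battery (OLS
regressions of longevity on ln abundance, one-way ANOVAs by taxonomic
order and biogeographic category, a mixed model combining abundance and
biogeography, AICc comparison).

## Range vetting and longevity

A species' observed range is the interval from its oldest (FO) to its
youngest (LO) sample with a positive count. Observed endpoints understate
true origination and extinction times, so each endpoint carries an error
bar derived from how gappy the species' record is:

* **mean gap** `g`: the average length, in samples, of the maximal runs of
  zero-count samples strictly between FO and LO;
* **error bar** `e = max(1, ceiling(g))` samples — a species seen in every
  sample of its range still gets the 1-sample minimum, since even a
  continuous record does not pin the true endpoints to the observed ones;
* the FO interval spans from the sample `e` positions *older* than FO down
  to FO itself; the LO interval from LO to the sample `e` positions
  *younger*. Bars extend outward only: the uncertainty being modelled is
  "the species originated before we first saw it / died out after we last
  saw it".

Longevity is the midpoint of the FO interval minus the midpoint of the LO
interval, in millions of years (my).

Species are excluded when their range cannot be trusted:

1. **edge filter** — any occurrence in the `edge_samples` (default 2)
   oldest or youngest samples of the composite sequence: the species may
   range beyond the study interval (or still be extant);
2. **overflow filter** — the error bar runs off either end of the sample
   sequence, which is the same concern expressed through the error bar;
3. **doubling filter** — the outer error-bar span exceeds twice the raw
   observed range (strict inequality; a single-sample range, raw span 0,
   always fails): the range is too poorly constrained to use.

Flagged occurrences (suspected reworking or misidentification) are zeroed
before any of this, via an explicit `(taxon, sample)` exclusion list.

Two readings of "average gap size" are defensible: averaging over maximal
zero *runs* (the default) or dividing the total number of interior zero
samples by the number of consecutive occurrence pairs. They differ only
when a species has both long and short gaps; `gap_method = "samples"`
switches to the second reading for sensitivity analysis.

Filter order (exclusions → edge → overflow → doubling) only affects which
reason is recorded for a species failing several filters, never who is
included; the edge decision deliberately ignores the error bar so the two
filters stay independent.

## Abundance metrics and coverage

Counts are standardized within each sample to percent relative abundance
of the *species-level* assemblage: `p_ij = 100 n_ij / N_j`, with genus-
and higher-level columns excluded from numerator and denominator alike.
Per species, the mean, maximum and standard deviation of `p_ij` are taken
over **all** samples between FO and LO, counting samples where the species
was missed as zeros. Zero-inclusive averaging matters: with thousands of
specimens per sample, the smallest nonzero single-sample share is already
~0.01–0.04%, and observed range-wide means can sit well below that only if
the zeros count. The SD uses the n−1 denominator; a species whose
within-range abundance never varies has SD 0, no defined ln SD, and is
dropped from the SD regression only.

Abundance metrics enter the models as natural logs of the percent values,
which removes most of the right skew of lognormal-like species abundance
distributions.

Sample coverage (the Good–Turing/Chao estimator from singletons `f1` and
doubletons `f2`, `C = 1 − (f1/n)·(n−1)f1/((n−1)f1 + 2f2)`) is reported per
sample as a counting-completeness check; it never gates the analysis. The
estimator equals 1 exactly when a sample has no singletons; the degenerate
one-specimen sample is assigned coverage 0.

## The statistical battery

* `fit_longevity_ols()` — OLS of longevity on one ln-abundance metric,
  two-sided slope test, α = 0.05. Residual diagnostics (Shapiro–Wilk,
  Breusch–Pagan, a residual sign-runs statistic against fitted order) are
  advisory only.
* `longevity_anova()` — classical one-way fixed-effects ANOVA (type-I sums
  of squares, R's `aov`), used for the three polycystine orders
  (Collodaria / Nassellaria / Spumellaria) and for endemic vs cosmopolitan
  species. Groups need ≥ 2 members each.
* `fit_longevity_mixed()` — `longevity ~ ln mean abundance + (1 | biogeo)`
  via lme4, **maximum likelihood** (not REML) so its AICc is comparable
  with the abundance-only OLS fit. A random intercept on a 2-level factor
  is fragile by construction: singular fits (between-category variance
  estimated at 0) are flagged with a warning and returned, not errored,
  and a fixed-effects ANCOVA variant (`random = FALSE`) is provided for
  sensitivity.
* `aicc()` — `AIC + 2k(k+1)/(n−k−1)` with `k` counting the residual
  variance; `compare_aicc()` reports Δ = AICc(complex) − AICc(simple),
  positive Δ favouring the simple model.

No multiple-testing correction is applied; all p-values are reported
together so users can apply their own.

## What the synthetic generators emulate

`simulate_neutral_community()` is a zero-sum Moran model, the canonical
neutral null: each step one uniformly chosen individual dies and is
replaced by the offspring of a uniformly chosen survivor, or by a new
species with probability `nu`. Species lifetimes and time-averaged
abundances are tracked exactly, and the community can be "fossilized" by
multinomial sampling at chosen ages. One generation maps to 0.08 my by
default, chosen once so the median completed lifetime at the default
J = 100, nu = 0.01 lands near 8 my, a realistic radiolarian median. The
simulator demonstrates the qualitative neutral expectation (abundance and
longevity positively coupled); it is not the per-capita
environmental-stochasticity variant, models no time-averaging in the
sediment, and its absolute time scale is a convention.

`simulate_species_truth()` / `simulate_niche_community()` build the
alternative world with a *known* abundance–longevity coupling: ln mean
abundance is Normal (default sd 2 ln-units, spanning roughly four orders
of magnitude as real assemblages do) and true longevity is
`L = L0 + β·(ln a − mean ln a) + ε`, truncated at 0.5 my by redrawing ε.
The abundance term is centered so the marginal longevity distribution
stays at `L0` (default 8.2 my) whatever the coupling β; that keeps the
0.5 my truncation a rare event (~2% of draws at the defaults) and the
generating slope essentially unattenuated, which is what makes clean
parameter-recovery tests possible. Ranges are placed uniformly within the
study interval, within-range abundance wiggles lognormally (sdlog 0.5),
and samples are multinomial draws.

`simulate_fixture()` produces datasets with the gross shape of the two
study regions — a Southern-Ocean-like composite (97 samples, 22.65–0.04
Ma, ~7,190 species-level specimens/sample, 100–200 species/sample, C/N/S
orders in roughly 15:135:39 proportions, multiple sites with age-tied
rows) and an eastern-Pacific-like single site (14 samples, 10.3–0 Ma,
~2,500 specimens/sample, a few hundred species/sample) — plus a handful of
genus-level columns that every computation must ignore. Species pools,
range-length distributions and abundance shapes were calibrated once to
land in those observed bands and then frozen.

What the generators do **not** emulate: time-averaging within a sample,
preservation/dissolution bias among taxa, age-model error, depth-stratified
sub-communities, and spatial structure among sites. Passing tests on
synthetic data therefore shows the *machinery* is correct and the study
design can recover known signals at realistic sizes — not that real
assemblage data meet the generators' assumptions.

## Numerical choices and degenerate inputs

* Samples sort oldest-first; exact age ties (possible in multi-site
  composites) break deterministically by site then sample id, so results
  are identical however the input rows are ordered.
* Non-integer or negative counts, samples missing from the age file, and
  unresolvable exclusion entries are hard errors naming the offending
  record; taxa missing from the metadata file are kept with a warning as
  non-species-level (hence ignored by every computation).
* "More than doubled" is strict (`extended > 2 × raw`), so a raw span
  exactly doubled by its error bars is kept.
* A non-positive longevity for an included species is a hard error — it
  can only arise from corrupted age ordering.
* ML (never REML) for every AIC-compared fit; AICc is the headline
  criterion with plain AIC alongside.
* All generators consume a single integer seed and are bit-reproducible;
  the pipeline itself is deterministic given its inputs.

## Problem sizes used in the test suite

The suite exercises the oracle comparisons on 100 random small instances
(n = 5–30), the slope test's type-I error on 2,000 null replicates of
n = 50, coupling recovery on 500 generator seeds of 200 species, and one
Moran run of 5 × 10⁵ events (J = 100, nu = 0.01, ~5,000 completed
lifetimes). These sizes give Monte-Carlo standard errors comfortably
inside the asserted bands (e.g. ±0.005 on a 0.05 rejection rate) while
keeping the default test run fast on a single CPU.

## Worked example

```{r example}
library(paleorange)

tbl <- simulate_fixture("SO", seed = 1)
run <- run_pipeline(tbl, label = "SO")
run
run$aicc_comparison
autoplot(run$ols$mean)
plot_longevity_groups(dplyr::filter(run$species, status == "included"),
                      order_code)
```

## Known limitations

* The vetting procedure estimates range endpoints in *samples*, so its
  resolution in my is only as good as the sampling density; strongly
  uneven sample spacing makes the error bars uneven in time.
* The exact mixed-model formula used in comparable published analyses is
  rarely stated; the random-intercept choice here is one defensible
  reading, and ΔAICc values from it should be compared across studies only
  approximately.
* Relative abundance is a proxy for absolute abundance only where sample
  size and sedimentation rate are stable; the package does not model
  flux-based absolute abundances.
* The occurrence data carry no phylogenetic structure, so species are
  treated as exchangeable within groups.
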