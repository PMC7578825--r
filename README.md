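# trophicniche

Quantitative tools for fish feeding ecology, built around a two-method
analysis of intraspecific dietary competition in size-structured populations
(the motivating system is the black amur bream, *Megalobrama terminalis*, of
the lower Pearl River). The package answers, from gut contents and from
stable isotopes jointly: how wide is each size group's trophic niche, how
much do groups overlap, how specialized are individuals within a group, and
does feeding rhythm differ between groups?

It provides, for researchers doing this kind of analysis:

* **Diet composition** — percent by weight (%W) and percent by number (%N,
  detritus excluded by convention), gonadosomatic and fullness indices.
* **Dietary overlap** — the simplified Morisita index
  `C_ij = 2 Σ p_ik p_jk / (Σ p_ik² + Σ p_jk²)`, with the conventional
  `C_ij > 0.6` significance screen.
* **Individual specialization** — the Shannon-entropy decomposition
  `TNW = WIC + BIC` (total / within-individual / between-individual niche
  width, in nats), the WIC/TNW ratio, and mean pairwise proportional diet
  similarity.
* **Isotopic niche geometry** on the (δ¹³C, δ¹⁵N) biplot — Layman metrics
  (NR, CR, CD, MNND), convex hull area (TA), standard ellipse area
  `SEA = π√(λ₁λ₂)` with the small-sample correction
  `SEAc = SEA·(n−1)/(n−2)`, deterministic ellipse-overlap areas, and
  isotope-vs-length regressions.
* **A Bayesian stable-isotope mixing model** with trophic enrichment
  factors, Dirichlet prior and residual error, fitted by multi-chain
  Metropolis with split-chain R-hat diagnostics.
* **Inference** — two-sample Hotelling's T², a residual permutation
  procedure (RPP) for CD/MNND/centroid differences, Pearson correlation,
  and season-random-intercept linear mixed models with likelihood-ratio
  tests for diel feeding rhythm.
* **Seeded synthetic-data generators** for all four input tables
  (Dirichlet-multinomial diets, bivariate-normal isotopes, mixing-model
  consumers, ordinal gut-fullness series), so every stage runs and is
  tested without any field data.

Input formats are plain CSVs (`read_diet_csv()`, `read_isotope_csv()`,
`read_sources_csv()`, `read_fullness_csv()`); printed group-level summary
tables from the motivating study ship with the package (`bream_*()`
accessors). See the vignette in `vignettes/trophic-niche-methods.Rmd` for
the models, assumptions and numerical choices.

## Worked example

Dietary overlap between the four size groups from the packaged group-mean
%W compositions:

```r
library(trophicniche)
dm <- bream_groupmean_diet()
round(morisita_matrix(dm, basis = "mass"), 3)
#>                small_juvenile large_juvenile sub_adult adult
#> small_juvenile          1.000          0.982     0.997 0.995
#> large_juvenile          0.982          1.000     0.984 0.993
#> sub_adult               0.997          0.984     1.000 0.998
#> adult                   0.995          0.993     0.998 1.000
```

Every pairwise index far exceeds 0.6: all size groups share essentially the
same (detritus-dominated) diet by mass, i.e. intense potential competition.

Isotopic niche of a simulated adult group (defaults reproduce the published
group means/SDs; n = 8 for adults):

```r
it <- simulate_isotopes(isotope_sim_config(seed = 42))
niche_metrics(it, "adult")
#> NR 8.07  CR 3.44  CD 2.37  MNND 1.45 ± 1.05  TA 15.4  SEA 9.15  SEAc 10.7
```

NR/CR are the δ¹⁵N/δ¹³C ranges (‰), CD the mean distance to the centroid,
TA the convex-hull area and SEA/SEAc the (corrected) standard ellipse area
(‰²) — the two standard measures of isotopic niche width.

Individual specialization in a simulated group with strong diet
heterogeneity (Dirichlet concentration α = 0.5):

```r
cfg <- diet_sim_config(group_sizes = c(small_juvenile = 30),
                       q = rep(0.25, 4), alpha = 0.5, seed = 42)
sp <- tnw_wic(simulate_diet(cfg), basis = "count", exclude = character())
#> TNW 1.329  WIC 0.394  WIC/TNW 0.296  diet similarity 0.310
```

WIC/TNW ≈ 0.3 means individuals use only ~30% of the group's niche width —
strong individual specialization, mirrored by the low mean diet similarity.

Mixing model on consumers simulated from three benthic prey sources with
known proportions (0.5, 0.3, 0.2):

```r
src <- bream_prey_sources()
sub <- source_set(as.data.frame(src[src$source %in% c("Mni", "Cfl", "Bsp"), ]))
cons <- simulate_consumers(mix_sim_config(sub, p = c(0.5, 0.3, 0.2), n = 40, seed = 42))
fit <- fit_mixing_model(mixing_model_spec(sub, cons, seed = 42))
fit$sources
#>   source  mean ci_low ci_high
#> 1    Mni 0.509  0.461   0.557
#> 2    Cfl 0.297  0.241   0.351
#> 3    Bsp 0.194  0.171   0.216     (max split R-hat 1.005)
```

All three true proportions sit inside their 95% credible intervals.

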