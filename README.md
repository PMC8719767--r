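# morphburden

Hierarchical analysis of metazoan parasite burden across host color morphs,
built for the lingcod (*Ophiodon elongatus*) blue/brown polymorphism and
reusable for any host survey with the same shape of data: a host table (one
row per fish with region / sampling location / depth / sex / color /
morphometrics) and a long count table (fish × parasite taxon × count).

The scientific question the package addresses: does a discrete color morph
carry a different parasite load, and does that difference depend on host
sex?  Because blue males are rare, naive Wald inference is fragile, so the
package pairs the model with design-constrained permutation tests.

## What it implements

* **Burden GLMM** — the central model, an NB2 negative-binomial mixed model
  for per-taxon counts:

  `count ~ depth + sex + color + sex:color + (1 | region/location/fish) +
  (1 + sex*color | taxon) + offset(log(length))`

  with treatment contrasts referenced at female/blue, depth standardized by
  the scale-then-add-2 convention, and a log-length offset (burden as a
  rate per cm).  Fitted by Laplace-approximated maximum likelihood with a
  compiled inner Newton solver for the joint random-effect mode
  (`fit_burden_model()`, `extract_taxon_effects()`,
  `blue_to_brown_ratio()`).
* **Constrained permutation tests** — relabel exactly 4 males blue
  (scheme 1), optionally also 11 females (scheme 2), refit the full model
  per replicate and compare interaction z values two-sided with ties
  counted as extreme (`run_permutation_test()`).
* **Community PERMANOVA** — Bray-Curtis dissimilarities and sequential
  (Type-I) permutational MANOVA with terms sex-color combination, sampling
  location, depth (`community_dissimilarity()`, `permanova()`).
* **Condition indices** — Fulton's K (mass/length³) and the fourth-root
  transformed hepatosomatic index, with lme4-backed mixed post-hoc models
  and audited outlier exclusion (`fultons_k()`, `hepatosomatic_index()`,
  `fit_condition_model()`).
* **Morph frequency** — sex-by-color contingency summary and chi-squared
  test (`morph_frequency_summary()`, `sex_color_chisq()`).
* **Synthetic data** — `generate_dataset()` draws host and count tables
  from exactly the generative model the burden GLMM assumes (nested
  intercepts, correlated taxon effects, NB2 counts, allometric
  morphometrics), with stored truth for recovery testing.
* **Pipeline** — `run_pipeline()` chains the stages with config hashing,
  per-stage status and checksummed outputs; a thin CLI wrapper lives in
  `inst/scripts/morphburden-cli.R`.

All user-facing functions take data frames and return tibbles; fitted
objects have `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

```r
library(morphburden)

cfg <- generator_config(n_fish = 89, cell_allocation = "proportional", seed = 2026)
sim <- generate_dataset(cfg)          # 89 fish, 25 taxa, 59/4/15/11 cells
fit <- fit_burden_model(sim$hosts, sim$counts)
fit
#> <burden_fit> NB2 mixed model, Laplace approximation
#>   n = 2225 observations (89 fish x 25 taxa), logLik = -7986.997, theta = 0.956
#>   converged: TRUE
#>                    term  estimate       se         z          p
#>             (Intercept) -2.535630 0.175517 -14.44661 2.6333e-47
#>                   depth -0.031743 0.048564  -0.65364 5.1334e-01
#>               sex[male]  1.245262 0.235588   5.28575 1.2519e-07
#>            color[brown]  0.306238 0.127451   2.40278 1.6271e-02
#>  sex[male]:color[brown] -0.595044 0.269721  -2.20614 2.7374e-02

blue_to_brown_ratio(fit, "male")
#> [1] 1.334833
```

Reading the output: the negative `sex[male]:color[brown]` estimate means
the blue-versus-brown burden gap is larger in males than in females — in
this simulated dataset a blue male carries about 1.33 times the per-taxon
burden of a brown male of the same length, depth and site
(`exp(-(0.306 - 0.595))`).  `theta` is the NB2 dispersion (small values =
strong overdispersion); z is estimate/SE with a two-sided normal p.

Per-taxon interaction slopes for a caterpillar plot
(`autoplot(fit)` draws it):

```r
head(extract_taxon_effects(fit), 3)
#> # A tibble: 3 × 4
#>   taxon_id deviation cond_sd total_slope
#>   <chr>        <dbl>   <dbl>       <dbl>
#> 1 T12         -0.935   0.367       -1.53
#> 2 T08         -0.779   0.367       -1.37
#> 3 T04         -0.456   0.350       -1.05
```

Morph frequency by sex:

```r
s <- morph_frequency_summary(sim$hosts)
s$proportions
#> # A tibble: 2 × 4
#>   sex        n n_blue prop_blue
#>   <chr>  <int>  <int>     <dbl>
#> 1 female    26     11    0.423
#> 2 male      63      4    0.0635
sex_color_chisq(s$table)
#> # A tibble: 1 × 3
#>   statistic    df   p_value
#>       <dbl> <int>     <dbl>
#> 1      17.0     1 0.0000377
```

The permutation test refits the model per constrained relabelling:

```r
res <- run_permutation_test(sim$hosts, sim$counts,
                            scheme = permutation_scheme("males_only",
                                                        n_replicates = 199,
                                                        seed = 1))
glance(res)   # observed z, proportion of replicates at least as extreme
```

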