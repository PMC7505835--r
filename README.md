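# retbench

Retention benchmarks for salvage logging in naturally disturbed forests,
estimated by mixed rarefaction/extrapolation of paired incidence data.

## The problem

Forests hit by wildfire, windstorms or insect outbreaks are routinely
salvage logged. The disturbed-but-unlogged habitat hosts species — many of
them deadwood-dependent — that do not persist in salvaged areas, so managers
need a number: **what proportion of a naturally disturbed area must be left
unlogged to maintain, say, 90% of the richness of the species unique to the
unlogged habitat?**

`retbench` computes that benchmark from the standard field design in this
literature: one species-by-plot matrix from unlogged, disturbed reference
plots and one from salvage-logged plots of the same disturbance, surveyed
with equal effort. It is written for ecologists synthesising such paired
matrices across studies, taxa and disturbance types.

## The method

Abundances are reduced to incidence frequencies $Q_i$ (plots occupied out of
$T$). Within each habitat, the non-parametric species–area relationship is
the sample-based rarefaction/extrapolation curve: rarefaction uses the
hypergeometric non-detection probability
$m(T, Q_i, t) = \binom{T-Q_i}{t}/\binom{T}{t}$ (evaluated via log-gamma, so
$t$ may be real), and extrapolation uses the Chao2 estimate
$\hat Q_0 = \frac{T-1}{T} \frac{Q_1^2}{2Q_2}$ of undetected richness.

Salvage logging a share $1-p$ of the area is modelled as *plot replacement*:
keep $t_1 = p\,T_1$ unlogged plots, replace the rest with plots drawn from
the logged habitat. With species classified at the reference-sample level as
unique-to-unlogged, unique-to-logged or shared, the expected mixture
richness decomposes as

$$U(t_1) + L(t_2) + S(t_1,t_2) = \sum_{u.u.}[1 - m_1(t_1)] +
\sum_{u.l.}[1 - m_2(t_2)] + \sum_{sh}[1 - m_1(t_1)\,m_2(t_2)].$$

Two benchmarks summarise the normalized unique-richness curve
$u(p) = U(pT_1)/U(T_1)$ per dataset:

* `p_star` — smallest $p$ with $u(p) \ge q$ (default $q = 0.9$), by
  grid-free bisection;
* `frac_at_half` — $u(0.5)$, the unique richness maintained when half the
  area is logged.

Benchmarks are averaged (mean ± SD) over all matrices and by disturbance
type, saproxylic status, taxon and year, and a beta regression with an
AIC-selected spline smooth tests for a trend with time since disturbance.
A synthetic-data module generates paired datasets with known analytic truth
so the whole pipeline is testable without field data (the packaged example
collection is synthetic — real matrices of this kind are typically available
only on request).

## Worked example

```r
library(retbench)
library(dplyr)

coll <- synthetic_collection()   # 24 paired synthetic datasets, fixed seeds
res  <- run_pipeline(coll)

filter(res$summaries, grouping == "all")
#> # A tibble: 2 × 6
#>   grouping level statistic        n  mean     sd
#>   <chr>    <chr> <chr>        <int> <dbl>  <dbl>
#> 1 all      all   frac_at_half    24 0.819 0.0501
#> 2 all      all   p_star          24 0.652 0.0794

res$regressions$p_star
#> <beta_gam> response: p_star, n = 24
#>   smooth(years_since_disturbance): df = 1 (AIC-selected), LRT p = 0.3416
#>   phi = 42.279, log-likelihood = 28.944, pseudo-r2 = 0.013
```

Across these 24 synthetic matrices, a mean of 65.2% (SD 7.9) of the
disturbed area must stay unlogged to keep 90% of the unique species, and
logging half the area retains on average 81.9% (SD 5.0) of unique richness;
the benchmark shows no trend with time since disturbance (the collection is
generated without one). Per dataset:

```r
pd <- coll[["fire_beetles_sapro"]]
pd
#> <paired_dataset> fire_beetles_sapro: T1 = 18 unlogged, T2 = 14 logged plots, 89 pooled species
retention_for_fraction(pd, q = 0.9)
#> [1] 0.7263832
unique_fraction_at_retention(pd, 0.5)
#> [1] 0.7698496
autoplot(compute_mixture_decomposition(pd))  # decomposition over p in [0,1]
```

A small example dataset in the package's CSV formats ships under
`inst/extdata/` (`synthetic_example_*.csv`); see `read_species_matrix()`,
`read_metadata()` and `load_collection()` for the on-disk interface, and
`inst/cli/retbench.R` for a command-line front end
(`compute` / `summarize` / `simulate` / `regress`).

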