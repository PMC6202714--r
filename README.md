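# eivpool

Multilevel Bayesian models of Ellenberg-style indicator values for
vegetation resurvey studies.

## The problem

Ellenberg indicator values (EIVs) score plant species on ordinal scales for
their optimal environmental conditions — moisture (F), light (L), soil
nutrients (N), soil reaction (R) and salt tolerance (S). When plots are
surveyed in two time-periods, ecologists usually compare the raw per-plot
mean score between periods to infer environmental change. That practice
discards the within-plot spread of species scores, weights a 7-species plot
as heavily as a 120-species plot, and breaks down when historical species
lists are incomplete.

`eivpool` instead feeds the species-level scores into hierarchical
varying-intercept/varying-slope models, fitted by MCMC (JAGS), so plot
means and between-period changes are estimated with full uncertainty and
partially pooled across plots. It is aimed at plant ecologists analysing
resurvey data, but applies to any per-species trait averaged within sample
units.

## The models

With `y_i` the indicator score of species occurrence `i` in plot `j[i]` and
`x_i` the 0/1 period indicator:

- **M1 (no pooling)** — `y_i ~ N(alpha_j[i] + beta_j[i] * x_i,
  sigma_species)` with independent wide priors for every plot: `alpha_j` is
  the period-1 plot mean, `beta_j` the between-period change; equivalent to
  one t-test per plot.
- **M2 (partial pooling)** — additionally `(alpha_j, beta_j) ~
  MVN((mu_alpha, mu_beta), Sigma(sigma_alpha, sigma_beta, rho))`: plot
  estimates shrink toward the population mean in proportion to their
  information content.
- **M3 (partial pooling + group-level predictor)** — the bivariate-normal
  means take one value per habitat `k`: `(mu_alpha[k], mu_beta[k])`, so
  estimates pool toward their habitat mean and habitat-level change is
  estimated directly.

On top of the fits the package computes per-level Bayesian R² and
Gelman–Pardoe pooling factors (λ), DIC/pD model comparison, plot- and
habitat-level change tables with credible intervals, a conventional
raw-means GLMM baseline with single-step family-wise correction of its
habitat contrasts, and a species-depletion validation experiment (remove
90% of species from species-rich plots, refit, score precision and accuracy
against the full-data means). A synthetic-survey generator with ground
truth makes every step testable without any field data.

## Worked example

```r
library(eivpool)

params <- sim_params(n_habitats = 3, plots_per_habitat = 8,
                     species_per_cell = 30,
                     mu_alpha = c(4, 5, 6), mu_beta = c(-0.5, 0, 0.5),
                     seed = 203)
sim <- simulate_survey(params)
sim$frame
#> model_frame: 1440 observations, 24 plots, 3 habitats, index N
#>          y    plot period x j habitat k species
#> 1 1.472276 plot001      1 0 1   hab01 1 sp00001
#> 2 3.129036 plot001      1 0 1   hab01 1 sp00002
#> ...

fit <- fit_model(sim$frame, "M3", mcmc = mcmc_config(seed = 13))
print(metrics_row(fit), digits = 3)
#>   model index sigma_species sigma_alpha sigma_beta r2_data r2_alpha r2_beta
#> 1    M3     N          1.55        0.35      0.292   0.354    0.864   0.762
#>   lambda_alpha lambda_beta   pd  dic
#> 1        0.403       0.642 30.7 5385

print(summarize_changes(fit, "habitat"), digits = 2)
#>    unit  mean median   lo50  hi50  lo95  hi95 excl0_50 excl0_95
#> 1 hab01 -0.68  -0.68 -0.800 -0.56 -1.04 -0.34     TRUE     TRUE
#> 2 hab02  0.14   0.14  0.032  0.27 -0.21  0.48     TRUE    FALSE
#> 3 hab03  0.50   0.51  0.386  0.63  0.15  0.84     TRUE     TRUE
```

The metrics row reads: within-plot species scores spread with sd 1.55
(dwarfing the between-plot sds 0.35/0.29, the usual situation for EIVs);
habitat explains 86% of intercept and 76% of slope variance; intercepts and
slopes are pooled at λ = 0.40 and 0.64; the fit used ~31 effective
parameters. The change table recovers the generating habitat changes
(−0.5, 0, +0.5): habitats 1 and 3 show credible directional change, habitat
2 does not.

Real data enter through three CSVs — an indicator table
(`species,F,L,N,R,S`), occurrence lists (`plot,period,species`) and a plot
design (`plot,habitat[,area_m2,lat,lon]`):

```r
eiv <- load_eiv_table("plantatt.csv")
occ <- load_occurrences("occurrences.csv")
des <- load_plot_design("design.csv")
frame <- build_model_frame(occ, eiv, des, index = "N")
```

A command-line front end wraps the same functions
(`inst/scripts/eivpool`): subcommands `simulate`, `fit`, `metrics`,
`baseline`, `deplete`, each writing CSV outputs plus a `manifest.json`
that makes runs byte-reproducible from the recorded config and seed.

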