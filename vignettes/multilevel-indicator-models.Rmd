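---
title: "Multilevel models of indicator values: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel models of indicator values: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery of `eivpool`: the models
and their assumptions, the priors and tunable parameters, the derived
metrics and the conventions behind them, what the synthetic-data generator
does and does not emulate, and the numerical choices made where the design
was genuinely open.

## Data model

Species occurrence lists per plot per time-period are joined to an
indicator-value table to give one row per *scored occurrence*:
`(y, plot, period, habitat, species)`, with `y` the ordinal score of the
species on the chosen index (moisture F on 1–12; light L, nutrients N and
reaction R on 1–9; salt tolerance S on 0–9, zero for non-halophytes).
Species names are joined after trimming, whitespace-collapsing and
case-folding, because historical lists carry typographic variance; original
spellings are preserved in outputs. Occurrences of species with no score
for the chosen index are dropped and counted in a per-frame report rather
than imputed — the community mean is defined over scored species, and
imputation would smuggle information across indices. Duplicate
(plot, period, species) triples are presence/absence duplicates and are
removed with a logged count. Each index is modelled separately; the period
indicator is `x = 0` for the first and `x = 1` for the second period, with
no centering, so that the intercept is interpretable as the period-1 plot
mean.

## The three models

All three share the data level

$$y_i \sim \mathrm{N}\!\left(\alpha_{j[i]} + \beta_{j[i]} x_i,\;
\sigma_{\text{species}}\right),$$

treating the ordinal scores as exchangeable Gaussian observations within a
plot-period cell. This Gaussian treatment of ordinal data is an
approximation; the generator's ordinal mode (below) quantifies its effect.

* **M1 (no pooling).** Every `alpha_j`, `beta_j` gets an independent
  Normal(0, 100) prior. Each plot is a separate two-group comparison;
  `alpha_j` converges to the period-1 sample mean and `beta_j` to the raw
  between-period difference (the unit tests verify this to 0.05).
* **M2 (partial pooling).** `(alpha_j, beta_j)` are draws from a bivariate
  normal with means `(mu_alpha, mu_beta)`, standard deviations
  `(sigma_alpha, sigma_beta)` and correlation `rho`. Pooling shrinks
  poorly-informed plots toward the population mean.
* **M3 (partial pooling with a group-level predictor).** The
  bivariate-normal means take one value per habitat,
  `(mu_alpha[k], mu_beta[k])`; `sigma_alpha`, `sigma_beta` then measure
  residual between-plot variation *after* habitat is accounted for, and
  habitat-level change is read off `mu_beta[k]` directly.

Plots observed in only one period are retained: their missing-period
parameter is informed by pooling under M2/M3, and only by its prior under
M1 (flagged with a warning).

## Priors and sampling

Priors are minimally informative: Normal(0, sd = 100) on all location
parameters, Uniform(0, 100) on `sigma_species`, `sigma_alpha`,
`sigma_beta`, and Uniform(−1, 1) on `rho`. The bivariate normal is
parameterized directly by `(sigma_alpha, sigma_beta, rho)` through its
exact conditional factorization

$$\beta_j \mid \alpha_j \sim \mathrm{N}\!\left(\mu_\beta + \rho
\tfrac{\sigma_\beta}{\sigma_\alpha}(\alpha_j - \mu_\alpha),\;
(1-\rho^2)\sigma_\beta^2\right),$$

which avoids inverse-Wishart priors and their induced dependence between
scale and correlation. On the score scale (units of indicator points, range
at most 11), sd = 100 and an upper bound of 100 are far outside any
plausible value, so the priors are effectively flat; the suite checks that
doubling the location-prior sd moves the posterior mean of `mu_beta` by
less than 0.02.

Models are sampled with JAGS through `rjags`. `mcmc_config()` defaults to 4
chains of 1000 warmup + 1000 retained draws, thin 1 — desk-scale and
sufficient for the summaries reported here; raise it for publication runs.
Each chain gets a Mersenne-Twister RNG seeded deterministically from the
configuration seed, plus data-derived starting values (raw plot means and
differences), so identical configurations give bit-identical draws.
`check_convergence()` computes split-chain R-hat by hand (each chain halved,
so within-chain drift inflates the statistic) and autocorrelation-based
effective sample sizes via `coda`; a failing check attaches a warning to
the fit rather than discarding it.

## Derived metrics

All posterior intervals are central (equal-tail) quantile intervals; table
entries are posterior means. Both are conventions — medians differ
negligibly for these well-behaved posteriors.

**Per-level Bayesian R².** Computed per draw as
`1 − V(errors)/V(values)` with `V` the finite-sample variance across units,
then summarized over draws. Data level: errors
`y_i − (alpha_j[i] + beta_j[i] x_i)` against the observed `y`. Intercept
and slope levels: errors of `alpha_j` (`beta_j`) around their modelled
mean — the global mean for M2, the habitat mean for M3. Under M2 the
modelled mean is a constant within each draw, so level-2 R² is *exactly*
zero — a structural fact, not a numerical accident: a single global mean
explains none of the between-plot variance. For M3, level-2 R² measures the
share of between-plot variance explained by habitat.

**Pooling factors.** `lambda = 1 − V_j(E_s[eps_j]) / E_s[V_j(eps_j)]`, with
`eps_j` the level-2 errors above, `E_s` the posterior expectation. Values
near 1 mean the posterior-mean errors are nearly identical across plots
(complete pooling); near 0, each plot's error is estimated on its own. This
is a single number per level, not a per-draw posterior; the two variance
components are returned alongside it. Estimates outside [−0.05, 1.05]
trigger a warning.

**DIC.** Classic Spiegelhalter form with the posterior-mean plug-in:
`pD = Dbar − D(theta_bar)`, `DIC = Dbar + pD`, where `theta_bar` takes the
posterior mean of every `alpha_j`, `beta_j` and of `sigma_species`. The
plug-in convention is validated structurally: under M1, `pD` lands within a
few percent of the actual parameter count `2J + 1` (e.g. ≈149 for 74
plots). Pointwise log-densities are exposed separately so `Dbar` is
recomputable from raw draws.

**Change tables.** Plot-level change is `beta_j`; habitat-level change
(M3) is `mu_beta[k]`; habitat contrasts are draw-wise differences. No
multiplicity adjustment is applied to any of these: partial pooling already
shrinks estimates toward their group mean, which is what licenses
simultaneous inference across units.

## The raw-means baseline

The comparison method fits `mean ~ habitat * period + (1 | plot)` by REML
(`lme4`) to the per-cell raw mean scores, deliberately reproducing the
flaws being critiqued: each plot mean enters with equal weight regardless
of its species count, and the within-plot spread never reaches the model.
One design point was genuinely open: a "plot effect nested in time-period"
would give every random-effect level exactly one observation (each
(plot, period) cell contributes one raw mean), making that variance
unidentifiable and confounded with the residual — `lme4` rightly refuses.
The default is therefore the crossed plot intercept, the identifiable
structure that accounts for resampling the same plots;
`random = "plot_by_period"` relaxes the check for users who want the
literal nested form.

Habitat-change contrasts are corrected for multiple comparisons with the
single-step max-|z| method: the two-sided quantile of the multivariate
normal with the contrasts' correlation matrix (`mvtnorm`), the same
adjustment `multcomp` applies to mixed models (the suite cross-checks the
critical value against `multcomp::glht`). The quasi-Monte-Carlo quantile is
computed under a fixed internal seed (caller RNG state restored) so results
are reproducible; Bonferroni is available as a guaranteed-conservative
fallback. Adjusted intervals are clamped to be at least as wide as
unadjusted ones, and degenerate fits (zero residual variance) fall back to
the unadjusted quantile on zero-width intervals.

## The depletion experiment

The validation that motivates the whole framework: if the models can
recover a species-rich plot's mean after 90% of its species are deleted,
the pooled information is doing real work. One plot with more than
`min_species` (default 50) recorded species is drawn uniformly per
(habitat, period) stratum — 14 cells for 7 habitats when every stratum
qualifies; strata without a qualifying plot are skipped with a warning. The
selection is made once and held fixed; only the removed species are
re-randomized each iteration, with per-iteration seeds derived
deterministically from the plan seed. Each selected cell retains
`max(1, round(n × (1 − fraction)))` species ("about 90%" removal permits
rounding; an empty cell would break fitting).

Models are refitted to each depleted frame and the posterior plot mean of
each depleted cell — `alpha_j` for period-1 cells, the draw-wise sum
`alpha_j + beta_j` for period-2 cells — is scored against the *full-data
raw mean* of that cell, the "true mean" (a plot with >50 species estimates
its own mean well; using the full-data model estimate instead would bias
the comparison toward the models). Precision: mean 50% and 95% interval
widths, and mean over cells of 1/variance of the point estimates across
iterations. Accuracy: hit proportions of the 50%/95% intervals and mean
absolute distance from the true mean. The iteration default is 120;
metrics are exactly recomputable from the persisted per-iteration raw
table. Why species are missing (detection processes) is out of scope: the
removal is uniform by construction.

## The synthetic generator

`simulate_survey()` reads the M3 structure generatively: habitat-level
means, bivariate-normal plot parameters, Gaussian species scores, and
returns the realized `alpha_j`, `beta_j` as ground truth. Defaults mimic
the variance magnitudes of real indicator-value resurveys —
`sigma_species = 1.6` dwarfing `sigma_alpha = 0.35` and
`sigma_beta = 0.3` — and `studland_like_preset()` fixes the survey shape to
74 plots in 7 habitats with cell richness uniform on 10–120. Habitat mean
changes in the preset span ±0.45: small effect sizes, as expected on an
ordinal indicator scale.

Two deliberate simplifications. Species identities are synthetic labels
drawn independently per plot-period cell: the models treat rows as
exchangeable within a cell, so persistent species identity across periods
is irrelevant to what is being tested, but it means the generator cannot
emulate, e.g., turnover of particular species. And generation is
continuous by default, with an ordinal mode (round, clip to score bounds)
used in robustness checks — the suite verifies that ordinal rounding at
default variances moves the fitted `sigma_species` only modestly, which is
the empirical defense for fitting Gaussian models to ordinal scores.
Passing tests on these surveys therefore show sampler and estimator
correctness under the models' own assumptions, not robustness to detection
bias, abundance weighting or phylogenetic correlation, none of which are
simulated.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen so the
whole suite completes in minutes on one CPU while every check retains a
clear margin: most fits use 2 chains × (400–500 warmup + 400–500 retained);
calibration checks use 10 replicate surveys of 24 plots; the DIC
model-ordering check uses 5 replicate surveys at the full 74-plot scale
(where DIC gaps of 14–60 dwarf Monte-Carlo noise, while at 24 plots the
M2/M3 gap of ~1–2 is within it); the depletion comparison uses 20
iterations. These sizes are the package's own trade-off, configurable
upward for publication-grade runs.

Other numerical details: the split R-hat of a constant chain is defined as
1 (0/0 → complete agreement); `sigma_alpha` appearing in a denominator of
the conditional factorization is harmless under the Uniform(0, 100) prior
since the event `sigma_alpha = 0` has measure zero and initial values are
strictly positive; CSV outputs from the command-line tool serialize floats
at 6 significant digits for diffability, with full precision retained in
the posterior draw containers.

## Known limitations

Cumulative-link (ordinal-likelihood) variants, spatial autocorrelation,
species-level covariates (cover weights, invasiveness) and detection
modelling are intentionally outside the current surface; the model-frame
and fit containers keep those extension points clean. Taxonomic synonym
resolution is not attempted — species joining is purely typographic, and
taxa absent from the indicator table are dropped per index, with the drop
report as the audit trail. WAIC/LOO are not computed; DIC is retained as
the comparison criterion, with the pointwise log-density matrix available
for anyone wanting alternatives.
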