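# betaforest

Forest-plot variants for reporting **large ensembles of single-predictor
linear regression models** — the situation that arises when multicollinearity
rules out multiple regression and every outcome × predictor pair gets its own
model, multiplied again by the plausible values (PVs) of large-scale
educational assessments. A 10-domain × 5-PV × 5-predictor analysis is 250
models; no standard display shows them at once.

`betaforest` provides the full pipeline and three displays:

- **Beta-range forest plot** — per domain × predictor: a bar spanning the
  smallest-to-largest of the m PV point estimates β̂₁…β̂ₘ, whiskers spanning
  the outermost 95% CI limits, and a black tick at the Rubin-pooled estimate
  Q̄ = (1/m)Σβ̂ᵢ with total variance T = W + (1 + 1/m)B (W = mean squared SE,
  B = between-PV variance of the estimates).
- **Bootstrap ridgeline plot** — per outcome lane, one kernel-density curve
  per predictor of B case-bootstrap standardized coefficients.
- **Bootstrap violin plot** — the same densities, mirrored and dodged.

All coefficients are **standardized** (outcome and predictor z-scored before
fitting, weighted moments under sampling weights), so a slope is the SD
change in the outcome per SD change in the predictor and, for simple OLS,
equals the Pearson correlation. Models come in three forms: plain OLS,
weighted least squares, and a school random-intercept mixed model
(`lme4`, REML) for clustered assessment data.

Two simulators make every stage testable without restricted data: a
truncated-multivariate-normal **decathlon** table (10 correlated event
results + 7 correlated hematological indices per athlete) and a hierarchical
**assessment** table (students in schools in countries, 10 domains × 5 PVs,
country-level macro predictors, lognormal sampling weights).

## Worked example

```r
library(betaforest)

d <- simulate_timss_like(hierarchy_config(
  n_countries = 10, schools_per_country = 8,
  students_per_school = 12, seed = 42))

fits <- fit_model_grid(d, outcomes = paste0("BSMALG0", 1:5),
                       predictors = c("GDP", "Gini"),
                       weights = "weight", cluster = "school")
pooled <- pool_table(fits)
ranges <- summarize_ranges(fits, pooled)
print(ranges, digits = 3)
#>   domain predictor beta_pooled est_min est_max ci_outer_lower ci_outer_upper
#> 1 BSMALG       GDP       0.183   0.178   0.191         0.0420          0.328
#> 2 BSMALG      Gini       0.119   0.114   0.129        -0.0264          0.270
```

Read: across the five Algebra plausible values, the standardized GDP slope
ranged from 0.178 to 0.191 (pooled 0.183); the widest CI ran from 0.042 to
0.328, clear of zero, so every PV model was significant. The Gini whiskers
cross zero: at least one PV model was not. Render it:

```r
plot_beta_range_forest(ranges, plot_options(), "forest.svg")
```

Bootstrap displays from the decathlon data:

```r
dec <- simulate_decathlon(n_units = 10000, seed = 1)
draws <- bootstrap_grid(dec,
  outcomes = attr(dec, "event_names"),      # 10 events
  predictors = attr(dec, "marker_names"),   # 7 blood markers
  n_reps = 500, seed = 1)                   # -> 35,000 rows
plot_bootstrap_ridgeline(draws, plot_options(), "ridge.svg")
plot_bootstrap_violin(draws, plot_options(), "violin.svg")
```

The same pipeline is scriptable (`simulate → fit → pool → summarize → plot`):

```sh
Rscript inst/cli/betaforest simulate decathlon --n 10000 --seed 42 --out d.csv
Rscript inst/cli/betaforest bootstrap --data d.csv \
  --outcomes 100m,long_jump --predictors ferritin,hemoglobin \
  --reps 500 --seed 7 --out b.csv
Rscript inst/cli/betaforest plot violin --data b.csv --out fig.svg
```

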