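---
title: "Visualizing regression ensembles: models, pooling, and the three plots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Visualizing regression ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betaforest)
```

## The problem

When predictors are strongly collinear, or are being screened one at a time,
the defensible analysis is a *grid* of single-predictor models rather than
one multiple regression. In large-scale educational assessments the grid is
multiplied again: each proficiency domain is reported as m (typically 5)
plausible values (PVs) — independent imputations of a latent score — and the
recommended workflow fits every model once per PV and pools afterwards. Ten
domains × 5 PVs × 5 predictors is 250 models. `betaforest` computes that
grid, pools it, condenses it, and draws it.

## The model layer

Every cell is a single-predictor linear model on **z-scored** variables.
With sampling weights \(w_i\), means and SDs are weighted:
\(\bar x_w = \sum w_i x_i / \sum w_i\), and the variance uses the
unbiased-analog denominator \(V_1 - V_2/V_1\) (with \(V_1=\sum w_i\),
\(V_2=\sum w_i^2\)), which reduces to the ordinary \(n-1\) form under equal
weights and is invariant to rescaling all weights by a constant. The fitted
slope on z-scores is the standardized coefficient \(\beta\); for simple OLS
it is exactly the Pearson correlation, which the test suite asserts to
1e-10.

Three estimation routes share one contract:

| weights | cluster | estimator |
|---|---|---|
| – | – | OLS (`stats::lm`) |
| ✓ | – | WLS (`stats::lm`, row weights) |
| any | ✓ | random intercept per cluster (`lme4::lmer`, REML) |

Wald intervals use \(\beta \pm t_{n-2}\,se\). For the mixed model the
\(n-2\) df is a pragmatic approximation — with thousands of students the
\(t\) quantile is indistinguishable from normal, and no df convention is
implied by the reference output format (which prints only \(\beta, t, p\),
CI). Standardization happens *before* fitting; for simple OLS this
coincides with post-hoc rescaling of the raw slope, and unlike the post-hoc
route it extends unambiguously to weighted and clustered fits.

Degenerate cells (zero residual variance, e.g. \(y = -x\)) report
\(se = 0\), \(p = 0\), a point CI, and `degenerate = TRUE` instead of
erroring, so a 250-cell grid never aborts; genuinely unfittable cells
(constant columns, too few rows) are recorded in the `error` column.
Missing data are handled by listwise deletion per model — only rows complete
in that cell's outcome, predictor, weight, and cluster columns are used.

## Rubin's rules

For m PV fits of one domain × predictor cell,
\[
\bar Q = \tfrac1m\sum\hat\beta_i,\qquad
W = \tfrac1m\sum se_i^2,\qquad
B = \tfrac1{m-1}\sum(\hat\beta_i-\bar Q)^2,
\]
\[
T = W + (1+\tfrac1m)B,\qquad
\nu = (m-1)\Bigl[1+\frac{W}{(1+\frac1m)B}\Bigr]^2,
\]
with CI \(\bar Q \pm t_\nu \sqrt T\). Two numerical choices:

- \(B = 0\) exactly (all m estimates identical) makes \(\nu\) infinite; the
  normal quantile is used, the limit the formula approaches.
- The classic small-m df is used rather than the Barnard–Rubin
  complete-data adjustment: with tens of thousands of observations per fit
  the adjustment changes the CI in the fourth decimal, and the simpler rule
  is the transparent default.

Pooling operates on standardized slopes and their SEs, never on \(t\) or
\(p\) columns. The worked five-estimate example (betas 0.20, 0.21, 0.22,
0.21, 0.21, all SEs 0.01 → \(\bar Q = 0.21\), \(W = 10^{-4}\),
\(B = 5\times10^{-5}\), \(T = 1.6\times10^{-4}\)) is frozen in the tests by
hand-evaluating these formulas.

## The beta-range summary and the forest plot

Each cell is condensed to one row: min and max of the m point estimates,
minimum of the m lower CI limits, maximum of the m upper limits, plus the
pooled \(\bar Q\) — reducing 250 rows to 50 while retaining where *every*
underlying model lies. The invariant
\(\text{CI}_L \le \hat\beta_{min} \le \bar Q \le \hat\beta_{max} \le \text{CI}_U\)
is checked on every generated summary and again before rendering.

The plot stacks domains on the y-axis, dodges one band per predictor within
each domain, fills bands by predictor (Okabe–Ito palette, first-appearance
order), draws whiskers for the outer CI range, a black tick at \(\bar Q\), a
solid red line at the null effect, and dotted lines at ±0.1/±0.3/±0.5 — the
conventional small/moderate/large thresholds, mirrored to the negative axis
because slopes can be negative. A whisker crossing the red line means at
least one PV model missed significance. Domain codes are mapped to display
names (`BSMALG` → "Algebra") by a user-overridable table.

## Bootstrap distributions

CIs say little about *where inside* the interval the effect likely lies.
The bootstrap layer resamples rows with replacement (case bootstrap),
re-standardizes within each resample, refits, and keeps the slope: B draws
per cell (500 by default, after the demonstration design of 70 models ×
500 = 35,000 coefficients).

Design choices, each visible in the code:

- **Resampling unit is the row.** The demonstration data are exchangeable
  athletes; cluster resampling is unnecessary there. Bootstrap fits use the
  plain/weighted engine — refitting a mixed model 500× per cell is out of
  proportion to what the display shows.
- **Degenerate resamples are redrawn**, not emitted as NA: every cell
  delivers exactly B draws, so densities are never silently thinned. A cell
  that produces 100·B consecutive degenerate resamples errors out.
- **Per-cell seeds** come from a documented 31-bit polynomial hash of
  (master seed, predictor, outcome), so a cell's draws do not depend on
  where it sits in the grid, and reordering the input lists changes
  nothing.

Ridgeline and violin plots are drawn from **one shared kernel density
estimate per cell** (Gaussian kernel, Silverman's rule-of-thumb bandwidth on
that cell's draws, 512 grid points) — the ridgeline draws it upward from the
outcome's lane, the violin mirrors it around the cell's center line. The
test suite verifies that the peak of the ridgeline curve and the widest
point of the violin sit at the same abscissa to 1e-6. Rendering is a pure
function of (table, options): identical inputs produce byte-identical SVG.

## The simulators: what the stated world is, and is not

**Decathlon.** 17 variables per athlete with the demonstration marginals
(100 m mean 10.78 s, SD 0.29; hemoglobin 15.92, SD 1.08; etc.), drawn from
a truncated MVN. The true correlation matrix of the original demonstration
lives in an unavailable supplementary protocol, so a transparent block
parameterization stands in: 0.6 within events, 0.5 within markers, 0.4
across, all user-overridable. The four timed events (100 m, 400 m, 110 m
hurdles, 1500 m) enter through a sign vector applied as a similarity
transform of the block matrix — flipping both their cross-block and their
within-event correlations — because "lower time = better performance" must
hold against markers *and* against jumps/throws; the transform also
preserves positive definiteness by construction. Truncation is by rejection
(redraw violating rows, preserving distributional shape) with clipping only
as a bounded fallback after 1,000 rounds; at the default mean ± 4 SD bounds
a rejection is a ~1-in-3,000 event per row and the truncation bias on the
moments is negligible, which is why marginal means at n = 10,000 reproduce
their targets within Monte-Carlo error.

**Assessment data.** Students in schools in countries. Latent achievement
is \(\mu_A + \sigma_A(\sum_k \beta_k z_k + u_s + \epsilon_i)\) with the
predictors z-scored *across the realized countries* (so the configured
\(\beta_k\) are exact in-sample standardized effects), school intercepts
\(u_s\) and residuals \(\epsilon\) splitting the remaining
\(1-\sum\beta_k^2\) variance at ratio `icc_school` (default 0.3, a typical
between-school share in such assessments); each of the 10 domains yields 5
PV columns = latent + N(0, `pv_noise_sd`) noise (default 15 score points,
giving PV SDs a shade above the latent 110, as in the marginals being
emulated); weights are lognormal with mean 1 (log-SD 0.5). Defaults are 38
countries × 150 schools × 15 students ≈ 85,500 — the demonstration scale.

What the generator does **not** emulate: correlated macro predictors (they
are drawn independently, so "true slope" stays well-defined per predictor);
domain-specific effect sizes (one latent score drives all 10 domains,
whereas a real analysis shows, e.g., a predictor helping mathematics more
than science); the original survey's stratified sampling design and
jackknife zones; and any country-level residual beyond the predictors. A
green parameter-recovery test therefore establishes that the pipeline
recovers a known standardized country-level effect under school clustering
and informative-ish weights — not that it reproduces any particular real
dataset's coefficients, which are unobtainable by design.

One consequence worth stating: because the predictor is constant within
countries, the honest sampling variability of \(\hat\beta\) is driven by
school- and country-level noise, which the naive OLS standard error
understates. The recovery tests therefore fit the same form used in the
demonstration analyses — weighted with a school random intercept — and the
clustered SE is asserted to exceed the naive one. With a single configured
predictor there is no country-level residual left over, so nominal 95%
coverage holds (measured 96/100 before the threshold was frozen; the
acceptance criterion requires ≥ 90/100).

## Command-line interface

`run_cli()` (wrapped by `inst/cli/betaforest`) exposes
`simulate / fit / pool / summarize / bootstrap / plot` with CSV interchange
at every boundary, fixed headers per stage, `--seed` wherever randomness
exists, logging to standard error only. Outcome/predictor lists accept
comma-separated values or `@file` with one name per line (50-name PV lists
are painful inline). The optional `--config` file is JSON rather than TOML:
no TOML parser exists in the supported dependency set, JSON round-trips
through `jsonlite` losslessly, and the config surface is small enough that
flags cover it entirely.

## Known limitations

- Multiple-predictor and logistic models are out of scope; the grid is
  strictly single-predictor linear.
- Mixed-model CIs use the \(n-2\) Wald approximation (no Satterthwaite df).
- No BCa or studentized bootstrap intervals — the displays show raw
  distributions, deliberately.
- The beta-range summary is descriptive; the only inferential statement in
  the forest plot is whether whiskers cross the null line.
- Sampling weights are used as given (no senate-style rescaling), since no
  rescaling rule is part of the stated world.
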