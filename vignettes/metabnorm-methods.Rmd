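---
title: "Methods: per-metabolite mixed-model normalization and inference"
author: "metabnorm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-metabolite mixed-model normalization and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabnorm)
```

## The normalization model

Targeted LC-MS metabolomics measures a panel of metabolites as per-sample
ion counts. Two kinds of technical variation contaminate those signals:
*fixed-effect* confounders with a directional, estimable influence (tissue
quantity, the internal-standard signal that tracks ionization efficiency)
and *random-effect* block factors whose levels are draws from a population
(run day, animal strain, technician). `metabnorm` fits, for every
metabolite independently and on the log2 scale,

$$y_i = \mu + \text{Group}_{g(i)} + \sum_j \beta_j x_{ij} + \sum_r b_{r(i)} + e_i,
\qquad b_r \sim N(0, \sigma_r^2), \quad e_i \sim N(0, \sigma_e^2).$$

With no random factors this is ordinary least squares (`stats::lm`);
otherwise a linear mixed model estimated by REML (`lme4::lmer`, the
standard estimator for variance components). Fitting per metabolite means
each metabolite gets its own confounder coefficients — the key advantage
over dividing every signal by a single internal standard, which assumes one
shared response.

Normalized data are reconstructed as **conditional residual plus adjusted
group mean**, $n_i = e_i + m_{g(i)}$. Two deliberate choices live in that
sentence:

* **Residuals are conditional**: the predicted random intercepts (BLUPs)
  are subtracted along with the fixed-effect predictions. Marginal
  residuals would leave the day offsets in the data, defeating the purpose
  of declaring `Day` random. The BLUP for a level shrinks its raw mean
  offset by $\sigma_r^2 / (\sigma_r^2 + \sigma_e^2 / n_r)$, so a little of
  a block offset survives normalization; with 30 samples per day and
  $\sigma_e = 0.2$ the leftover is well under 1% of the offset.
* **Group means are adjusted (least-squares) means**: the model prediction
  for each group at the global mean of every continuous covariate, with
  fixed factors averaged over their observed level proportions and random
  effects at their mean of zero. Covariate means are computed per
  metabolite over the rows usable for that metabolite; under balanced
  missingness this coincides with global means, and it keeps each
  metabolite's reconstruction self-contained.

A random variance estimated at the zero boundary is kept at zero, and the
fit then coincides with the fixed-effect fit (verified in the tests to
1e-6 on balanced designs). Negative variance estimates are never reported.
Categorical terms use treatment contrasts with the lexicographically first
level as reference; predictions and adjusted means are invariant to that
choice.

### Degenerate inputs

Signals must be positive or missing — a zero reads as "undetected", which
the input format records as `NA`, and is rejected by validation so it
cannot silently distort a log2 fit. Metabolites are skipped, with a logged
warning and an entry in the result's `skipped` list, when: any usable group
has a single observation; residual degrees of freedom fall below 1; the
design is rank-deficient; the mixed model fails to converge (tolerance
1e-8, the `lme4` default profile); or residual variance is numerically zero
(a constant column, which would break every downstream test). Group levels
with *no* usable observations are dropped from that metabolite's design;
their adjusted mean is `NA` and their pairwise comparisons are skipped
rather than invented.

## Tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `transform` | `log2` | signal transform; `log2` stabilizes the variance of multiplicative ion-count noise and makes fold-changes differences |
| `criterion` | `p` | screening rule: `p`, `q`, `fc`, `p_and_fc`, `q_and_fc` |
| `alpha` | 0.05 | cutoff on the Tukey p- or Storey q-value, in (0, 1) |
| `fc_threshold` | 1 | minimum fold-change, applied two-sidedly as `max(FC, 1/FC)` |
| `center` (diagnostics) | median | Brown–Forsythe group center; `mean` gives classic Levene |
| heatmap distance/linkage | Euclidean / complete | defaults of the standard hierarchical clustering routine |

## Inference on normalized data

Inference is deliberately two-stage, mirroring common practice in this
pipeline style: Tukey HSD runs as a one-way ANOVA on the *normalized*
values with $\nu = N - k$ error degrees of freedom, taking no deduction for
the parameters spent during normalization and no mixed-model degrees of
freedom. This is a statistical simplification — the random-day variance
that widens honest confidence intervals is not propagated into the pairwise
tests — and we state it rather than hide it. The pairwise statistic uses
the Tukey–Kramer form for unbalanced groups, with p-values from the
Studentized-range distribution; the test suite checks them against an
independent quadrature of that distribution to 1e-4 and against the pooled
t-test for $k = 2$ to 1e-6.

Storey q-values are computed on the pooled list of all metabolite × pair
p-values: $\hat\pi_0(\lambda)$ on $\lambda = 0.05, \dots, 0.95$, smoothed
by a cubic spline with 3 effective degrees of freedom and evaluated at
$\lambda = 0.95$, capped to $[0, 1]$. Below 100 p-values the estimator is
too unstable and $\hat\pi_0 = 1$ is used, which reduces q-values exactly to
Benjamini–Hochberg (asserted in the tests to 1e-12). q-values are made
monotone from the largest p-value downward and are invariant to input
order.

The compact letter display uses the insert-and-absorb algorithm: one column
initially holds all groups; each significant pair splits every column
containing both members; columns whose group set is contained in another
are absorbed. The surviving columns are exactly the maximal cliques of the
"not significantly different" graph; they are lettered in order of their
smallest group index, ties broken by the next members (the ordering is
otherwise ambiguous, e.g. columns {1,2,3} and {1,2,4}). The tests compare
the result against brute-force maximal-clique enumeration for *every*
significance pattern with $k \le 4$.

Fold-changes are back-transformed adjusted-mean differences,
$FC(a,b) = 2^{m_a - m_b}$ — a ratio of geometric means on the raw scale.
Under `transform = "none"` the plain ratio is used and a zero denominator
yields `NA` rather than infinity.

## What the simulator emulates — and what it does not

`simulation_spec()` generates data from exactly the fitted model: log2
signal = baseline + group effect + covariate slopes + block offsets +
Gaussian noise, exported as `2^(log2 signal)` with independent missingness.
The draw order (block offsets, then covariates, then per-metabolite noise,
then missingness) is fixed so that adding metabolites never perturbs
earlier draws. Defaults sketch a realistic three-group, eight-per-group
adipose experiment: baseline `mu = 20` (about 1e6 ion counts), residual SD
0.25 log2 units (≈19% CV), a tissue-quantity covariate of 50 ± 10 mg with
slope 0.02 log2 units/mg, three run days with between-day SD 0.5 log2
units, and 2% missing cells.

Because generator and model share one functional form, passing tests show
the estimator is *correct*, not that the model is *true* of real data. The
simulator does not produce: correlated metabolite networks, detection-limit
(signal-dependent) missingness, Poisson-like counting noise at low
abundance, retention-time drift, or outlier injections. Assumption
diagnostics exist precisely because real data violate the model in ways
this generator never will.

## Numerical choices

* REML convergence: `lme4` defaults (criterion tolerance about 1e-8);
  singular fits are accepted as boundary estimates, not errors.
* Residual-variance floor for "degenerate" skips: 1e-12 on the variance of
  the conditional residuals.
* CSVs are written with full double precision (15 significant digits,
  "." decimal, UTF-8), which makes re-runs byte-identical and round-trips
  accurate to at least 10 significant digits.
* Heatmap columns are mean-centered over observed values; missing cells are
  excluded from distances (pairwise-complete rescaling in `stats::dist`)
  and drawn blank.
* Diagnostics: normality is tested on residuals pooled across groups
  (per-group tests at n ≈ 8 would be nearly powerless); variance
  homogeneity on normalized values by treatment group with median
  centering.

## Problem sizes in the validation suite

The packaged checks run at: 100 metabolites × 90 samples (confounder
removal), 5 metabolites × 20 replicates × 20 samples (fold-change
recovery), 1000 metabolites × 24 samples (familywise type-I rate and
q-value behaviour), 200-replicate bias checks for slopes and group
differences, and exhaustive letter-display enumeration to $k = 4$. These
sizes give Monte-Carlo standard errors comfortably inside the asserted
bands while keeping the whole suite under a minute on a laptop core.

## Known limitations

* Independent random intercepts only: no random slopes, no nested or
  crossed structures beyond independence, no Kenward–Roger or Satterthwaite
  degrees of freedom.
* The two-stage Tukey test understates uncertainty when random-factor
  variance is large relative to residual variance (see above).
* No imputation: missing stays missing through every stage.
* The pathway-export CSV layout (metabolite, comparison, fold-change,
  colour token, dot size, p/q-value) is a documented best effort; the
  target service's exact upload schema is not published, so treat the
  format as provisional.
* Technical replicates are averaged *after* normalization (the model is fit
  on all rows); an explicit replicate column is required because replicate
  structure cannot be inferred from the input reliably.
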