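---
title: "Severity-weighted kappa and pooling over observation periods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Severity-weighted kappa and pooling over observation periods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kappool)
```

## The estimand and the model

Two trained raters independently rate the same staff–inpatient
interactions on an ordered k-category scale (by default the
five-category QuIS: `+s`, `+c`, `N`, `-p`, `-r`, from best to worst).
Inter-rater reliability is summarised by weighted kappa. Given the
cross-tabulation of the n jointly rated interactions, with cell
proportions $p_{ij}$ and margins $p_{i.}$, $p_{.j}$, and a symmetric
agreement-weight matrix $w_{ij} \in [0,1]$ with $w_{ii} = 1$,

$$\hat\kappa_w = \frac{p_{o(w)} - p_{e(w)}}{1 - p_{e(w)}}, \qquad
  p_{o(w)} = \sum_{ij} w_{ij} p_{ij}, \qquad
  p_{e(w)} = \sum_{ij} w_{ij} p_{i.} p_{.j}.$$

$p_{e(w)}$ is the weighted agreement expected if the two raters were
independent with the observed margins; $\hat\kappa_w$ is agreement in
excess of chance, scaled to 1 at perfect weighted agreement. Identity
weights give Cohen's unweighted kappa. The standard error is the
Fleiss large-sample estimate

$$\widehat{SE}(\hat\kappa_w) = \frac{1}{(1-p_{e(w)})\sqrt n}
  \sqrt{\sum_{ij} p_{i.} p_{.j}
        \left[w_{ij} - (\bar w_{i.} + \bar w_{.j})\right]^2
        - p_{e(w)}^2},$$

with $\bar w_{i.} = \sum_j p_{.j} w_{ij}$ and
$\bar w_{.j} = \sum_i p_{i.} w_{ij}$, and intervals are Wald,
$\hat\kappa_w \pm z_{\alpha/2}\,\widehat{SE}$.

When the study comprises $g \ge 2$ observation periods, the per-period
estimates $\hat\kappa_{wm}$ with variances
$\hat V_{wm} = \widehat{SE}(\hat\kappa_{wm})^2$ are combined by

* **collapsing**: kappa on the cellwise sum of the g tables — simple,
  but confounded by between-period differences in the rating mix;
* **fixed effects**: $\hat\kappa_{w\,fixed} = \sum \omega_m
  \hat\kappa_{wm} / \sum \omega_m$ with $\omega_m = 1/\hat V_{wm}$ and
  $SE = (\sum\omega_m)^{-1/2}$, assuming one common true value;
* **random effects**: weights $\hat\Omega_m = 1/(\hat V_{wm} +
  \hat\tau^2)$, where the between-period variance $\tau^2$ is
  estimated by the DerSimonian–Laird moment estimator
  $$\hat\tau^2 = \frac{\chi^2_{het} - (g-1)}
    {\sum\omega_m - \sum\omega_m^2 / \sum\omega_m},$$
  truncated at 0 when the heterogeneity statistic
  $\chi^2_{het} = \sum \omega_m (\hat\kappa_{wm} -
  \hat\kappa_{w\,fixed})^2$ falls below its $g - 1$ degrees of
  freedom;
* **simple averaging**: $\sum \hat\kappa_{wm} / g$ with
  $SE = (\sum \hat V_{wm})^{1/2} / g$.

The random-effects summary is the recommended presentation: it
estimates the *mean* of the distribution of true reliability across
the conditions the periods sample, and its interval widens honestly
when periods disagree. The simple average up-weights the periods with
fewest interactions; where sparse periods also show the highest
agreement (fewer overlapping conversations are easier to rate), it
overestimates reliability. Heterogeneity is reported as
$\chi^2_{het}$ on $g-1$ df with its upper-tail p-value, alongside the
conventional rejection threshold at the 0.95 percentile.

## Weighting schemes

`weight_scheme()` names fifteen matrices. Linear and quadratic weights
($1 - |i-j|/(k-1)$ and $1 - ((i-j)/(k-1))^2$) depend only on distance,
which misrepresents the QuIS: a one-step disagreement within the
positive block is far milder than the one-step `+c`/`N` confusion. The
lettered schemes are block-structured, fully determined by three
parameters (weight $a$ within the positive pair, $b$ between neutral
and either block, $c$ within the negative pair; positive–negative
weights are always 0):

| scheme | a | b | c |
|---|---|---|---|
| A1–A6 | 1, .9, .8, .75, .7, .6 | .5 | = a |
| B1–B3 | .66, .5, .5 | .33, .25, 0 | = a |
| C1–C3 | .5, .6, .66 | .25, .4, .5 | .75, .8, .83 |

A4 is the default throughout. The A and B schemes are invariant under
reversing the scale; the C schemes deliberately are not (they weight
the negative pair as more similar than the positive pair). Because A1
gives full credit within both blocks, an A1 analysis is *exactly* the
merged positive/neutral/negative three-category analysis under the
induced block weights (which coincide with linear weights at k = 3) —
the package's tests verify this identity on fuzzed tables. Schemes
should be fixed before seeing results; scanning schemes for the
highest kappa invalidates the estimate, and no data-driven weight
selection is provided.

Custom matrices load from CSV (`read_weights()`); construction
enforces symmetry, unit diagonal and the [0, 1] range, and
`validate_weights()` reports violations for diagnostic use.

## Numerical conventions and degenerate inputs

* All k categories are retained in every period, even when unused;
  zero margins contribute zero to $p_{e(w)}$. Collapsing unused
  categories would change the chance correction inconsistently across
  periods.
* $p_{e(w)} = 1$ (all probability mass in weight-1 cells, e.g. a
  single period containing one agreeing interaction) makes kappa
  undefined; this raises an explicit error rather than propagating
  NaN. `kappa_study()` catches it per period, excludes the period
  from inverse-variance and averaged pooling with a warning naming
  the period and reason, and keeps its counts in the collapsed table.
  Zero-variance periods are excluded the same way, since
  inverse-variance weights would be infinite.
* Wald bounds are clipped to [−1, 1] for display; unclipped bounds
  are retained in the fitted object (`ci_unclipped`).
* Displayed values round to 2 decimals half-away-from-zero, matching
  the convention of published reliability tables; machine-precision
  values are always carried alongside, and exported JSON/TSV reports
  contain both.
* The Fleiss standard error is the large-sample form built from
  margin products. It reproduces published confidence intervals for
  this class of study, but on strongly diagonal tables it understates
  the resampling standard deviation of kappa — by about 10% on the
  shipped 354-interaction collapsed table (against a multinomial
  bootstrap), and by much more on small, highly concentrated tables.
  Bootstrap comparisons of the SE are therefore meaningful only where
  the large-sample approximation holds; point estimates are exact and
  are verified against brute-force summation at 1e−12.
* The DL denominator $\sum\omega_m - \sum\omega_m^2/\sum\omega_m$ is
  strictly positive whenever $g \ge 2$ and variances are finite, so
  $\hat\tau^2$ needs no further guarding beyond truncation at 0.

## The synthetic-data generator

`simulate_study()` realises the random-effects model directly. For
period m it draws $\delta_m \sim N(0, \tau^2)$, sets
$\lambda_m = \mathrm{clip}(\kappa_{mean} + \delta_m, 0, 1)$, and
samples the period's $n_m$ rating pairs multinomially from the
mixture

$$P_m = \lambda_m\,\mathrm{diag}(\pi) + (1-\lambda_m)\,\pi\pi^\top :$$

with probability $\lambda_m$ the raters agree on a category drawn
from the margin profile $\pi$; otherwise they rate independently.
This family was chosen because its population weighted kappa equals
$\lambda_m$ *exactly for every unit-diagonal weight matrix* (the
weighted observed agreement is
$\lambda_m + (1-\lambda_m)p_{e(w)}$), so ground truth is closed-form
and scheme-free — `true_kappa()` exposes it, and a property test
verifies the identity to 1e−12 over random draws.

Defaults are the design of the motivating QuIS study: g = 18 periods
of about 20 interactions each, $\pi = (59, 201, 70, 14, 10)/354$ (the
first rater's margins of its collapsed table, i.e. mostly positive
care, with rare negatives), mean agreement 0.6 and between-period SD
$\tau = 0.1$. One master seed drives per-period substreams derived
deterministically, so enlarging g leaves earlier periods bit-for-bit
unchanged. The option `pair_lambda_n = "inverse"` sorts the drawn
$\lambda_m$ against $n_m$ to emulate the empirical pattern that
sparse periods show the highest agreement; the test suite uses it to
demonstrate the upward bias of the simple average relative to fixed
effects.

What the generator does *not* emulate: rater-specific margins (both
raters share $\pi$; real raters can differ systematically),
interactions missed by one rater (inputs are assumed already paired),
negative true kappa (the mixture cannot represent below-chance
agreement, as $\lambda$ is clipped at 0), and correlation induced by
the same rater pair serving in several periods. Passing
parameter-recovery tests therefore shows the estimators work under
clean multinomial sampling with shared margins, not that they are
robust to those violations.

Two quantitative caveats, both visible in the test suite, temper
parameter-recovery expectations at the study's own design size. At
$n_m = 20$ with the skewed QuIS margins, plug-in weighted kappa is
biased low by roughly 0.02 per period ($O(1/n)$ bias of the ratio
estimator), and inverse-variance weighting with variances estimated
from the same small samples adds a further downward pull, so the mean
pooled random-effects estimate sits about 0.025 below a true mean of
0.6. This is a property of the estimators at that sample size, not of
the generator; the bias shrinks with $n_m$ and with more balanced
margins.

## Problem sizes used in testing

The suite fuzzes 1,000 random tables (k = 5, n ≤ 50) against
brute-force double/triple-summation oracles for $p_{o(w)}$,
$p_{e(w)}$, kappa and the SE; cross-checks fixed and DL
random-effects pooling against an established meta-analysis
implementation on 20 random datasets at 1e−8; bootstraps the SE on
the shipped collapsed table (20,000 multinomial resamples); and runs
500 replicate simulated studies at the g = 18, $n_m$ = 20 design for
parameter recovery. These sizes keep the full test run to well under
two minutes on one core while leaving Monte-Carlo error far below the
asserted bands.
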