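---
title: "Decomposing between-group outcome gaps across the quantile scale"
author: "quantgap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing between-group outcome gaps across the quantile scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quantgap)
```

## The problem

Comparisons of health outcomes between social groups usually report a
difference in means, implicitly assuming that risk factors act
homogeneously across the whole outcome range. When the interest is the
full disparity — who is behind, by how much, and at which part of the
outcome distribution — a mean decomposition such as Blinder–Oaxaca is
not enough. `quantgap` decomposes the between-group gap at *every*
quantile of the outcome into

* a **covariates part** (composition effect): the portion explained by
  the two groups carrying different levels of the same risk factors
  under a common response process, and
* a **coefficients part** (structure effect): the portion explained by
  the groups responding differently to the same factors, evaluated at
  the disadvantaged group's factor levels.

The two parts map onto the population-health strategy debate: a
dominant covariates part supports *proportionate universalism*
(universal action with intensity proportional to disadvantage, in
Marmot's sense), while a dominant coefficients part signals the need
for a *targeted approach* specific to the disadvantaged group (in the
Frohlich–Potvin vulnerable-population sense). The per-quantile mix of
the two parts is read as the indicated mix of strategies across the
outcome range.

## The model and the decomposition

For each group $g$ the conditional quantiles of the outcome are modeled
as linear in covariates,
$$Q_{Y_g}(\tau \mid x) = x^{\top}\beta_g(\tau), \qquad \tau \in (0,1),$$
and $\beta_g(\tau)$ is estimated by minimizing the check (pinball) loss
$\sum_i \rho_\tau(y_i - x_i^{\top}\beta)$, $\rho_\tau(u) = u(\tau -
1\{u<0\})$, over a dense grid of quantiles (99 equispaced points
$0.01,\dots,0.99$ by default). The marginal distribution implied by a
coefficient process $\beta_j(\cdot)$ and a covariate sample $X_k$ is
built in the Machado–Mata / Chernozhukov–Fernández-Val–Melly fashion:
the prediction surface $x_i^{\top}\beta_j(\tau_m)$ is evaluated over
*all* sample rows $i$ and *all* grid points $m$, the $n \cdot M$ values
are pooled, and empirical quantiles of the pool give
$Q_{\langle j \mid k\rangle}(\tau)$. We use exhaustive pooling rather
than random draws, so the point estimate involves no resampling and is
exactly reproducible. With reference group $R$ (the coefficients donor,
by default the group with the larger median outcome) and comparison
group $C$:

$$\underbrace{Q_{\langle R|R\rangle} - Q_{\langle C|C\rangle}}_{\text{difference}}
 = \underbrace{Q_{\langle R|R\rangle} - Q_{\langle R|C\rangle}}_{\text{covariates part}}
 + \underbrace{Q_{\langle R|C\rangle} - Q_{\langle C|C\rangle}}_{\text{coefficients part}},$$

an identity that holds exactly at every $\tau$ by construction — the
package asserts it to machine rounding rather than estimating it.

Quantile crossing of the fitted curves is repaired by monotone
rearrangement (sorting in $\tau$), which preserves the multiset of
values; the raw curves remain available for diagnostics. Empirical
quantiles of pools use linear interpolation of order statistics
(`type = 7`) everywhere in the package, a convention that only matters
for very small pools.

### Per-covariate details

The published style of attributing each part to individual covariates
is not uniquely defined for distributional decompositions. We use
per-$\tau$ Oaxaca-style mean-covariate terms:
$(\bar x_{R,k} - \bar x_{C,k})\,\beta_{R,k}(\tau)$ for the covariates
part and $\bar x_{C,k}\,(\beta_{R,k}(\tau) - \beta_{C,k}(\tau))$ for
the coefficients part (the intercept contributes its raw coefficient
gap). Because these are mean-based summaries of a distributional
quantity, each part carries an explicit `(remainder)` term absorbing
the discrepancy; it is always reported, never hidden. This is a
declared convention of the package, not an inference about how any
particular published figure was produced.

## Estimation choices

The check-loss minimizer is a Frisch–Newton primal–dual interior point
method on the bounded-variables dual program, with Mehrotra
predictor–corrector steps, followed by a vertex polish (an exact fit
through the $p{+}1$ smallest-residual observations, kept when it lowers
the loss) — the solution is a true vertex solution in the generic case.
Columns are internally standardized for conditioning and the
coefficients mapped back exactly. A Hunter–Lange MM iteration serves as
a fallback for pathological instances. The contract tested is the
mathematical one — achieved loss at the brute-force optimum and the
subgradient count conditions — not a particular algorithm. Degenerate
instances (flat optima, even-$n$ medians) have non-unique minimizers;
the solver is deterministic, returning the same vertex for the same
input.

Inference is by the percentile bootstrap: resampling with replacement
*within* each group (groups are strata, so group sizes stay fixed), 100
replicates by default, re-running the entire pipeline per replicate and
taking pointwise empirical quantiles of each quantity. Percentile
intervals were chosen as the simplest method consistent with pointwise
bootstrap inference; normal-approximation and BCa variants, and uniform
bands over the quantile process, are out of scope. Each replicate draws
its resample under a seed derived from the root seed plus the replicate
index, so increasing the number of replicates never reshuffles earlier
ones. Replicates whose resampled design is rank-deficient are dropped
and counted; more than 10% failures aborts inference.

## Strategy classification

Two declared constants drive the strategy layer, since the underlying
qualitative reasoning ("major proportion", "substantially explained")
has no canonical numeric form:

* **dominant** part: contribution share strictly above 50%;
* **significant** part: pointwise CI excluding 0 at the fit's
  confidence level.

If both parts are significant the indication is `combined`; if exactly
one is, the indication is that part's strategy
(`proportionate_universalism` for the covariates part, `targeted` for
the coefficients part) *regardless of dominance* — this keeps the
classification aligned with the interpretation that a significant
covariates part at a tail quantile indicates proportionate universalism
as a supplement even where the coefficients part is the larger share.
If neither is significant the indication is `none`. Dominance is
recorded independently, and the indication can only change when a CI
endpoint crosses 0 or a share crosses 50%.

A covariate is flagged as **countervailing** at $\tau$ when its
covariates detail and coefficients detail both carry the sign of the
total gap and both exceed a noise floor (1% of the gap at that $\tau$
by default): equalizing its level would close part of the gap, but the
comparison group's weaker response would blunt a level-raising
intervention, so the flag recommends response-modifying (structural)
intervention instead. The intercept is excluded — it is not an
intervenable covariate — but when its coefficient gap exceeds half of
the coefficients part the report emits an unmeasured-factors caveat.

## Synthetic data and what the tests show

No public microdata accompany the methodology this package implements,
so validation rests on a location-scale generator with known truth:
$$Y = x^{\top}\beta + (x^{\top}\gamma)\,\varepsilon,$$
giving conditional quantiles $x^{\top}\beta +
(x^{\top}\gamma)F_\varepsilon^{-1}(\tau)$ that are exactly linear in
$x$ — the model's own assumption, with closed-form truth. Noise
families are restricted to standard gaussian and uniform so that
truths stay exact and cheap. Covariate families (log-normal, Poisson
counts, scaled Beta scores) mimic the measurement *types* of a
socioeconomic survey — skewed continuous income, small-count network
size, bounded support/literacy scores — without claiming to match any
real survey's marginals.

The demonstration fixture (`simulate_education_study()`) emulates a
two-group education-disparity study with 575 reference and 249
comparison subjects and four covariates, heteroskedastic noise growing
with income and literacy, and response heterogeneity concentrated in
the coefficients, so the decomposition attributes the majority share to
the coefficients part. Its parameters were fixed once, on that
qualitative design, and the realized truth is computed by the
Monte-Carlo oracle (`oracle_decomposition()`), never assumed. A fixed
scenario suite (`dgp_scenario()`: null, location shift, covariate
shift, response heterogeneity, mixed) gives analytically forced
structure for the test suite.

Passing these tests shows that the estimator recovers the estimands of
its own model class at realistic sizes and that its inference is
calibrated there. It does *not* show robustness to nonlinear quantile
processes, heavy-tailed noise outside the location-scale family,
measurement error, or informative missingness — real-data features the
generator deliberately omits.

## Problem sizes used by the validation suite

Chosen to exercise the asymptotics while staying comfortable on a
single CPU: parameter recovery at $n \in \{500, 2000, 8000\}$ on a
$\tau$ grid $0.1,\dots,0.9$; null-scenario calibration at $n = 5000$
per group against three quantile-sampling standard errors; oracle
agreement at $10^6$ simulation draws against a 199-point estimation
grid; bootstrap coverage over 200 simulated studies of the fixture's
size (575/249) with 100 replicates each on a 13-point estimation grid,
checking the 95% interval for the median difference. The estimation
grid for coverage is coarser than the analysis default because
pointwise coverage at the median is insensitive to grid density beyond
moderate resolution.

## Numerical and degenerate-input conventions

* Zero total difference at a $\tau$ makes contribution shares
  undefined; they are reported as `NA`/`undefined`, never as an error.
* Display tables round half-up to one decimal; the machine-readable
  twin file keeps full precision, avoiding the classic inconsistency
  where printed components fail to sum to the printed total.
* An empty estimation grid yields an empty (but valid) coefficient
  process; an empty bootstrap (0 replicates) yields point estimates
  with absent bounds.
* Outlier handling defaults to *none*: trimming is opt-in with explicit
  empirical-quantile bounds, because no universally accepted intake
  outlier rule exists; missingness is handled by complete-case deletion
  only, with a full row-accounting log.

## Known limitations

The decomposition is descriptive, not causal: reverse causality and
confounding pass straight through into both parts. The detailed
per-covariate terms are a mean-based approximation with an explicit
remainder, and extreme-quantile estimates inherit the larger sampling
error of quantile regression in the tails (visible as wider bootstrap
intervals at $\tau = 0.9$ than at the median). Only two-group
comparisons are supported, and coefficient-donor direction matters: the
package defaults to donating the advantaged group's coefficients, the
convention of the counterfactual literature it follows.
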