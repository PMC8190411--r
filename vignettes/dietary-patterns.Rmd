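---
title: "Extracting Zn/PUFA dietary patterns by reduced rank regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting Zn/PUFA dietary patterns by reduced rank regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrrdiet)
```

## The problem

Single-nutrient analyses of diet–biomarker relationships are easily
confounded by the food matrix: nobody eats isolated zinc. `rrrdiet`
implements a dietary-pattern alternative for one specific question — which
combinations of food groups carry zinc (Zn) and polyunsaturated fatty acid
(PUFA) intake, and whether adherence to those combinations shifts two serum
markers of the n-6 desaturation pathway, dihomo-γ-linolenic acid (DGLA) and
the linoleic-acid/DGLA (LA/DGLA) ratio. The biological rationale is that
the LA → GLA → DGLA conversion runs through Zn-dependent desaturase
activity, so a diet simultaneously rich in Zn and poor in PUFA should raise
DGLA and depress LA/DGLA.

The pipeline is sex-stratified throughout: standardization, pattern
extraction, quintile cut-points and regressions are all computed within one
sex at a time, because sex hormones modify long-chain PUFA synthesis.

## Reduced rank regression

Let $X$ be the $n \times 34$ matrix of z-standardized usual food-group
intakes (g/day) and $Y$ the $n \times 2$ matrix of z-standardized,
energy-adjusted Zn (mg/day) and PUFA (g/day) intakes. With $P$ the
orthogonal projection onto the column space of $X$, the fitted responses
are $\hat Y = P Y$. Factor $k$ is defined by the $k$-th eigenvector $v_k$
of $\hat Y^\top \hat Y$ (eigenvalues descending):

* response score $t_k = Y v_k$,
* predictor weights $a_k = (X^\top X)^{+} X^\top Y v_k$,
* factor score $f_k = X a_k$, which is exactly the least-squares projection
  of $t_k$ onto the predictor space.

This is the "maximize explained response variance" flavour of rank-reduced
regression: $f_1$ maximizes the mean over responses of
$\mathrm{cor}^2(Y_j, Xa)$ among all linear combinations of predictors, and
successive factors are orthogonal. The test suite checks this variational
characterization directly against a brute-force spherical grid search over
unit weight vectors on small instances ($p \le 4$). Canonical-correlation
weighting, partial least squares and principal-component extraction are
deliberately out of scope.

Numerical choices:

* $(X^\top X)^{+}$ is a symmetric-eigenvalue pseudo-inverse (relative
  tolerance $10^{-10}$), so collinear food groups degrade gracefully
  instead of failing.
* All standardization uses the sample SD ($n-1$ denominator). Constant
  columns cannot be standardized; they are dropped with a warning and
  recorded.
* Eigenvalues below $10^{-10} \lambda_1$ mark rank-deficient trailing
  factors; these are returned flagged, with zero loadings.
* Sign convention: each factor is flipped if needed so that it correlates
  non-negatively with the Zn response; an exact zero falls through to the
  PUFA response. This pins the "rich in Zn" pole to positive scores.

Two factors are retained by default (`K = 2`), matching the two patterns
the analysis interprets: factor 1 is typically an overall-volume pattern
(both nutrients high), factor 2 a contrast (rich in Zn, poor in PUFA). The
retention count is a configuration parameter, never inferred from the data.

## Loadings, simplified scores, quintiles

A loading is the Pearson correlation between a (standardized) food group
and a factor score. Some PLS-style software instead reports regression-type
X-loadings; both are available (`loading_type`), correlations are the
default. A simplified pattern keeps the groups with $|\text{loading}| \ge
0.20$ — the boundary is included — and scores each person by the signed sum
of their z-standardized intakes over those groups. The 0.20 threshold is
the conventional cut-off in factor-analytic diet studies and is a
parameter. Simplified scores are split into quintiles by rank (ties broken
by stable input order; group sizes differ by at most one); quintile 1 is
low adherence, quintile 5 high adherence.

## Upstream screening and exposure construction

**Inclusion filters**, applied in order: age below 20 y; pregnancy; missing
weight, height, PUFA intake, Zn intake, serum LA or serum DGLA; implausible
energy reporting. Low serum Zn (below 75 µg/dL) is flagged for prevalence
reporting but never used for exclusion. Whether "missing data" should also
cover covariates (race, PIR, education) was an open call; we exclude only
on the six listed variables, so adjusted regressions may use slightly fewer
rows than unadjusted ones.

**Misreporter screen.** Predicted total energy expenditure (MJ/day) comes
from the Vinken-type equation
$\mathrm{pTEE} = 7.377 - 0.073\,\mathrm{age} + 0.0806\,\mathrm{weight} +
0.0135\,\mathrm{height} - 1.363\,\mathrm{sex}$ (age in years, weight kg,
height cm, sex 0 = male / 1 = female). The plausibility band on the
EI/pTEE ratio is $1 \pm \sqrt{CV_{wEI}^2/d + CV_{wpTEE}^2 +
CV_{tmTEE}^2}/100$ with the published constants 32.3 %, 20.2 %, 8.2 % and
$d = 2$ recall days, i.e. $\pm 0.3157$. Energy intake enters as the mean of
the two recall days converted at 0.004184 MJ/kcal. Values exactly on a
bound count as plausible (the source equation is silent; we chose the
closed interval and document it). McCrory-style screens sometimes stratify
by physical activity level; only the single published equation set is
implemented.

**Usual intake.** Two recall days per food group are collapsed into a
usual intake by variance-component shrinkage: a one-way ANOVA on persons
splits each group's variance into between-person ($\sigma^2_b$) and
within-person ($\sigma^2_w$) parts (negative moment estimates truncated at
zero) and person $i$'s usual intake is
$\bar x + (\bar x_i - \bar x)\,\sigma^2_b/(\sigma^2_b + \sigma^2_w/2)$.
Fuller usual-intake machinery (e.g. two-part models for episodically
consumed foods) needs more than two days to identify and is intentionally
not implemented; downstream pattern extraction only needs the within-person
noise reduction. Shrinkage is applied to the food groups only, not to the
nutrient totals.

**Energy adjustment.** Nutrient responses are replaced by their residual
from an OLS regression on total energy plus the nutrient mean, before
z-standardization and pattern extraction; energy is additionally retained
as a model-2 covariate downstream. Adjusted values keep the original mean,
are exactly uncorrelated with energy in-sample, and may be negative. Zn is
treated in mg/day throughout (irrelevant to the fits, since responses are
z-standardized).

## Association layer

* Partial correlations between simplified scores and raw nutrient intakes,
  residualizing both on energy (t reference with $n-3$ df). A constant
  control degenerates to the plain Pearson correlation.
* Linear trend across quintiles: OLS of the outcome on the ordinal index
  1..5, energy-adjusted for food-group and nutrient rows, unadjusted for
  serum rows — exactly where the descriptive tables say. The trend variable
  can alternatively be the median score per quintile (`trend_variable`).
* Pearson chi-square (no continuity correction) for categorical variables
  across quintiles; cells with expected counts below 5 are flagged, not
  dropped.
* Outcome regressions for serum DGLA and LA/DGLA: model 1 is the score
  alone; model 2 adds age, energy, PIR, race, physical activity (two
  binary indicators), BMI, education, lipid-lowering medication and
  supplement use. Categorical covariates use the largest in-stratum
  category as reference, recorded in the result. p-values are two-sided;
  no multiple-testing correction is applied, matching standard practice
  for this design.

## The synthetic cohort generator

`generate_cohort()` exists so every stage is testable against a known
truth without external data. It emulates:

* log-normal person-level usual intakes around per-group medians
  (between-person CV 0.45) with independent log-normal day noise
  (within-person CV 0.5) — positive, right-skewed, like recall data;
* usual intake scaled by each person's predicted energy requirement, so
  reported energy is plausibly centred on expenditure for honest reporters
  of either sex;
* nutrient and energy totals as density-weighted sums of the day intakes
  plus 5 % measurement noise; the default medians and densities are
  calibrated so Zn lands near 9–13 mg/day, PUFA near 15–20 g/day and
  energy near expenditure, bracketing the quintile ranges published for
  US adults;
* a planted "rich in Zn, poor in PUFA" pattern: positive pole G1, G2, G3,
  G17 (dairy, red meat, ready-to-eat cereals — the Zn-dense groups),
  negative pole G13, G29, G30 (cakes, oils, salad dressing — the
  PUFA-dense groups); the true score is the signed sum of z-scored usual
  intakes over those groups;
* serum outcomes linear in the true score (default slopes −0.8 on LA/DGLA,
  +6 µmol/L on DGLA) with small fixed age and BMI terms so adjusted
  regression is exercised non-trivially, plus Gaussian noise (SD 5.5 and
  45 µmol/L; the LA/DGLA residual SD matches the spread observed in adult
  serum panels);
* a 15 % fraction of misreporters whose every reported quantity is scaled
  by 0.5 (under) or 1.6 (over) — a uniform multiplicative error, exactly
  the structure the EI/pTEE screen can detect;
* demographics (truncated-normal age 20–80, sex-specific anthropometry,
  uniform PIR, multinomial race/education, Bernoulli activity, medication,
  supplement and pregnancy indicators).

What it does **not** emulate: survey weights, household clustering,
nonresponse, episodic (zero-inflated) consumption, correlated food
preferences beyond the energy-requirement scaling, seasonal effects, or
differential misreporting by food group. Tests passing on this generator
therefore demonstrate internal correctness of the estimators — not that
real recall data satisfy the generating assumptions. The distributional
forms are modelling choices, not inferences about any survey.

## Problem sizes used in validation

The packaged checks run at desk scale: oracle comparisons on 20 random
instances of $n = 200$, $p = 4$; null calibrations at $n = 2000$; planted
pattern and effect recovery on cohorts of 800 per sex (about 620–650 after
filtering), with 20 seeds for pattern recovery and 100 simulations each
for effect recovery and null coverage. Effect-recovery simulations run at
a reduced outcome noise (SD 2) so the unadjusted model-1 regression
reflects the planted slope rather than residual biomarker variation;
pattern-recovery checks keep all defaults.

## Known limitations

* Two recall days identify only a two-component variance decomposition;
  the usual-intake estimator shrinks uniformly and cannot handle foods a
  person never reports.
* The quintile trend test uses person-level data with the ordinal index;
  analyses that computed trends on quintile summaries will differ.
* Real-data mode ships variable mappings and an XPORT reader but item-level
  food-group coding must be supplied by the user (the mapping template
  covers totals files only).
* With only two responses, at most two factors exist; `K` beyond 2 is
  rejected rather than padded.
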