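---
title: "Methods: growth exposures, trajectory peaks, and tiered association models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth exposures, trajectory peaks, and tiered association models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earlygrowth)
```

This vignette is the package's own account of its statistical machinery: the
models it fits, the constants it fixes, the places where the design was
genuinely open and what was decided, and what the synthetic-cohort tests do
and do not demonstrate about real data.

## Standardization

Raw weights are converted to SD scores against a reference model
$z = (x - \mu(\mathrm{age}))/\sigma(\mathrm{age})$. Internal references are
fitted from the cohort itself: $\mu$ by least squares on a natural cubic
spline basis of age with 4 interior knots at quantiles, and $\sigma$ from a
spline fit to absolute residuals scaled by $\sqrt{\pi/2}$ (which makes the
mean absolute deviation of a normal equal its SD). Three conventions are
deliberate:

* **Fetal weight is modelled on the log scale, adjusted for gestational age
  only.** Fetal weight dispersion grows roughly proportionally with
  gestation, and the adjustment set for fetal scores is gestational age
  alone, whereas birth and infant references are fitted per sex. This
  mirrors the usual convention in which fetal charts are unstratified and
  birth/infant charts are sex-specific.
* **The dispersion spline is stiffer than the mean spline** (2 interior
  knots rather than 4) and its predictions are floored at 25% of the
  stratum's median fitted $\sigma$. Dispersion varies more smoothly with age
  than the mean does, and a flexible variance spline can dip negative in
  sparse tails (e.g. very preterm births); the floor keeps every score
  finite with a bounded, conservative magnitude there.
* **Evaluation outside the fitted or tabulated age range is an error, never
  extrapolation.** SGA/LGA classification is percentile-sensitive, and a
  silently extrapolated tail percentile is worse than a refusal.

External charts are supported in two delimited dialects, `sex, age, L, M, S`
(LMS) and `sex, age, mean, sd`, linearly interpolated between grid ages. The
LMS score $z = ((x/M)^L - 1)/(LS)$ switches to its limit $\log(x/M)/S$ when
$|L| < 10^{-6}$, where the general form becomes numerically indeterminate.
Estimated fetal weight uses the three-parameter Hadlock HC/AC/FL model with
version-stamped coefficients so formula variants can be swapped.

Internally standardized scores have sample mean 0 and SD 1 *per reference
stratum on the fitting data* — the stratum being the unit the reference is
fitted on (both trimesters pooled for the fetal chart; each sex for birth
and infant charts). Sub-slices of a stratum (say, one visit within the
infant chart) can drift by ordinary sampling noise, which is why the
calibration tests evaluate the fitting unit at stratum sizes of at least
2000.

## Growth classification

Thresholds follow the printed conventions: term is the closed interval
[37, 42] weeks, normal birth weight [2500, 4500] g, and SGA/LGA strictly
below/above the 10th/90th percentile of the birth-weight SD score
(standard-normal percentiles by default, $\Phi^{-1}(0.10) = -1.2816$;
empirical cohort percentiles by option). Weight-change categories use the
0.67 SD-score threshold — the spacing of two percentile lines on a growth
chart — with *strict* inequality: a delta of exactly ±0.67 is normal growth,
because the defining phrase is "greater than 0.67" and a tie-break has to
land somewhere. The threshold is configurable but defaults locked at 0.67.

The infant window is birth to 24 months; when the 24-month score is missing
the endpoint falls back to 12, then 6 months, never the reverse, and the
endpoint actually used is recorded and counted. The 3×3 cross of fetal and
infant categories yields 9 patterns with fetal-normal × infant-normal as the
reference group.

## Conditional growth

For occasions $k = 2, \dots, K$ in fixed schedule order (never inferred from
ages), $z_k$ is regressed by OLS on $z_1, \dots, z_{k-1}$ with intercept and
the residual retained. Residuals are *standardized to unit sample SD* so
downstream coefficients read "per 1 SD-score unit of growth in that window";
the first occasion's conditional variable is its standardized score. OLS
makes the residuals exactly orthogonal to every earlier score (the normal
equations), which the tests assert at $10^{-10}$. Fitting is complete-case
— conditional variables only make sense on complete series — with the
analysis subset recorded, and a fitted set can be applied to new subjects
from the stored coefficients without refitting. Perfectly collinear
histories raise an error naming the occasions; a zero-variance residual
(perfect tracking) is flagged degenerate rather than divided by ~0.

## Trajectory peaks

**Reed1.** $W(t) = a + bt + c\ln t + d/t$ (kg, years) is linear in its
parameters, so it is fitted per sex as a linear mixed model on the basis
$\{1, t, \ln t, 1/t\}$ by REML, with per-subject coefficients = fixed
effects + BLUPs. Velocity $v(t) = b + c/t - d/t^2$ has an interior maximum
iff $c > 0$ and $d > 0$, at $t^* = 2d/c$ with $\mathrm{PWV} = b + c^2/(4d)$;
subjects violating the sign conditions (or with $t^*$ outside (0, 3] years)
are flagged and excluded from peak-based analyses with logged counts, never
silently assigned boundary values. Birth weight is included at
$t = 3/365.25$ years (a config constant): the basis is singular at $t = 0$,
and three days is small against the first visit spacing while keeping
$1/t$ finite.

**Adiposity peak.** $\log \mathrm{BMI} = \beta_0 + \beta_1 t + \beta_2 t^2 +
\beta_3 t^3 + \gamma\,\mathrm{male} + b_{0i} + b_{1i} t + \varepsilon$ over
14 days–1.5 years. The subject-level stationary points solve
$\beta_1 + 2\beta_2 t + 3\beta_3 t^2 = 0$; the admissible peak is the
in-window root with negative second derivative, and $|\beta_3| < 10^{-10}$
falls back to the quadratic vertex $-\beta_1/(2\beta_2)$. Age at peak is
reported in months ($12t$), BMI at peak as $\exp$ of the fitted log-BMI.

Two open design points were decided as follows:

* **Random-effects structure.** Nothing in the source conventions pins it
  down. The adiposity model uses random intercept + linear slope, because
  with an intercept-only structure every subject would share one age at
  peak, and the age-at-peak exposure would be degenerate. The Reed1 model
  defaults to random intercept + linear slope for the same reason applied to
  PWV (intercept-only would make PWV constant within sex, collinear with the
  sex covariate). Both are configurable, including `random = "none"` for
  exact single-curve fits.
* **Subject-level vs sex-level peaks.** Peaks are computed from
  subject-level (BLUP-augmented) coefficients; the sex-level fixed effects
  are reported alongside.

The closed forms are verified against purely numeric maximizers: for PWV,
the velocity is an exact parabola in $u = 1/t$, so the vertex of the
quadratic interpolant through three sampled points is an independent
maximizer to rounding error; for the cubic, a dense grid bracket refined by
finite-difference Newton steps (the central second difference is exact for a
cubic). Plain golden-section maximization cannot resolve a smooth maximum
beyond $\sqrt{\varepsilon}$ relative precision, which is why these sharper
oracles are used for the $10^{-6}$/$10^{-8}$ tolerances.

## Association models

All models are OLS. The tiers form a superset chain — basic (child sex, age
at outcome), confounder (+ maternal age, ethnicity, prepregnancy BMI,
education, household income, smoking, alcohol, folic acid), BMI (+ child BMI
SD score) — and categorical exposures are expanded against explicit
reference levels (term, normal weight, AGA, fetal-normal × infant-normal).
CIs are the normal approximation estimate ± 1.96·se for unpooled fits;
p-values are the usual two-sided t tests at α = 0.05 with no multiplicity
correction (the exposures and outcomes are strongly inter-correlated, so few
independent tests are expected). Unordered covariates enter with their most
frequent level as base; intracranial volume enters as a covariate (not a
ratio outcome) in post hoc models.

Sex interactions add an exposure × sex product term (Wald test; joint F for
categorical exposures). The nonlinearity check is a *deterministic* nested-
model F test — the tier's linear model against the same model with the
exposure replaced by a natural cubic spline (3 knots, 2 extra df) — chosen
over a penalized additive model because it is exactly assertable in tests;
its null calibration is itself verified by simulation. One behaviour worth
knowing: when the exposure is an *estimated* SD score, mild curvature
against the estimated exposure can appear even when the generated
dose–response is linear in the latent score, because estimation modulates
the exposure by age; the calibration tests therefore use directly observed
exposures.

## Imputation and pooling

Covariates are imputed by chained equations: each incomplete covariate in
turn is drawn from a fitted conditional given all other variables — Bayesian
linear draws (variance from the scaled inverse-χ², coefficients from their
normal posterior) for continuous variables, logistic draws for binary,
multinomial probability draws for unordered factors. This replaces a
multivariate-normal MCMC scheme deliberately: the covariate set mixes
categorical and continuous variables, which chained equations handle
natively. Exposures and outcomes are never imputed (missingness there is an
error), observed cells are never altered, and the default run is m = 30
datasets × 10 sweeps with per-imputation sub-seeds fanned out
deterministically from one master seed. Pooling follows Rubin's rules
($\bar Q$, $W$, $B$, $T = W + (1+1/m)B$) with Barnard–Rubin small-sample
degrees of freedom when the complete-data df is finite.

## The synthetic cohort: what it emulates and what it does not

The generator reproduces the *statistical skeleton* the analysis assumes:
one latent growth $z$ per weight occasion following an AR(1) chain with
lag-1 tracking 0.7, shifted additively by confounders (smoking −0.30 SD,
prepregnancy-BMI z +0.15, higher education +0.10); lognormal fetal/birth
weights around a gestational-age median curve; infant weights as a
sex-specific Reed1 curve plus an occasion-scaled $z$ offset plus 0.1 kg
measurement noise; a BMI series from the generating cubic; outcomes linear
in the configured effects (20 cm³ total brain volume per birth-weight SD,
4.7 cm³ per gestational week, plus confounder effects) with Gaussian noise;
covariate marginals and missingness rates matching a large pregnancy cohort
(50.3% girls, 20.4% smoking, 22% missing income, ...); and 24-month weights
missing at random given income so the endpoint fallback is exercised
non-trivially. Fetal biometry is constructed so the Hadlock formula
reproduces the true fetal weight exactly (a common scale factor solved in
closed form), keeping the estimated-fetal-weight step on-path.

Defaults were calibrated once against published cohort marginals (birth
weight 3446 (553) g, fetal weight medians 362/1602 g, infant weights
7.8/9.6/12.8 kg, adiposity peak at 8.4 months with BMI 17.6 (0.8)) and then
frozen; all tests compare against the *config*, which is the generating
truth. Two calibration notes:

* The Reed1 family cannot both track the median weight schedule through a
  birth point at 3 days and keep its implied peak velocity near commonly
  reported cohort means (~12 kg/y): pinned to the weights, the fitted curve
  concentrates a high velocity peak (~28 kg/y) in the first weeks, where the
  $c\ln t + d/t$ terms dominate. The generator keeps fidelity to the weight
  schedule and treats its own curve as truth; the discrepancy is a
  documented sensitivity of the functional form near its time origin, not a
  target of any test.
* The adiposity cubic was solved in closed form from the peak anchors
  (stationary maximum at 0.7 y, second stationary point outside the window),
  with random-effect SDs chosen to reproduce the printed 95% age-at-peak
  range; the simulated median is asserted as the band [7.8, 9.6] months,
  never a point.

What passing tests do **not** show: the generator has linear dose–response,
correctly specified conditional models, MCAR/MAR-by-income missingness only,
and no unmeasured confounding. Real cohorts violate all of these to unknown
degrees; the tests demonstrate that the machinery is correct where its
assumptions hold, not that the assumptions hold anywhere.

## Problem sizes and numerical settings

The default test and verification runs use: 1000 random coefficient sets per
closed-form oracle; n = 3000 subjects for orthogonality; 500 replicates at
n = 2000 for coverage and omitted-variable bias (with a strong confounder,
chosen ex ante so the 5% bias tolerance sits ~3.5 Monte-Carlo SEs from the
null); 2000 replicates at n = 300 for type-I calibration of the three tests
(enough that a true 5% rate stays inside 4–7% with high probability); 200
replicates with m = 5 × 3 sweeps for MCAR pooling; n = 10 000 for category
probabilities; and stratum sizes ≥ 2000 for standardization calibration.
The pipeline requires ≥ 3 weight measurements per subject for trajectory
fits (birth + at least two infant visits) and ≥ 3 in-window BMI values;
subjects below these, or without an interior peak, are excluded with logged
counts, so per-analysis n's differ by design.

## Limitations

Internal references are only as good as the cohort they are fitted on and
are not substitutes for national charts; the sd floor trades a small bias in
sparse tails for boundedness. The multinomial imputation draw conditions on
fitted probabilities without propagating coefficient uncertainty (a mild
understatement of between-imputation variance for many-level factors).
Conditional-growth fitting is complete-case by construction; combining it
with imputation of *weights* (as opposed to covariates) is out of scope.
The Reed1 and cubic models are the only trajectory families implemented —
no Jenss–Bayley or SITAR — and childhood BMI enters only as a covariate.
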