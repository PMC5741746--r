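---
title: "Occupancy and N-mixture models for monitoring elusive snakes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occupancy and N-mixture models for monitoring elusive snakes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occumix)
```

## The problem

Snakes are among the hardest vertebrates to monitor: they are cryptic,
occur at low density, and spend most of their time concealed. A survey
that finds nothing therefore says little on its own — the species may be
absent, or present and simply undetected. This package implements the
hierarchical-model workflow used to assess such populations from repeat
transect surveys with artificial cover objects (ACOs): models that
separate the *state* process (is a transect occupied; how many animals
are associated with it) from the *observation* process (was the species
seen on a given visit), followed by the design questions that matter for a
monitoring scheme — how many repeat visits justify declaring absence, and
how many sites are needed to detect a decline.

The motivating design is an insular grass snake (*Natrix helvetica*)
population: 19 site-years (a site surveyed in two years counts twice and
is treated as independent — a stated simplification that risks
underestimating model error), 3–8 visits each, transects of 0.28–19.1 km
walked with 6–436 ACOs per site, four habitat classes. That design is
shipped as the package fixture (`jersey_transects()`) and drives the
synthetic-data generator's defaults.

## Models

**Occupancy.** For site-year $i$ with detections $y_{it} \in \{0,1\}$ over
its $K_i$ visits,
$$L_i = \psi_i \prod_t p_{it}^{y_{it}} (1-p_{it})^{1-y_{it}}
        + (1-\psi_i)\,\mathbf 1\{\text{no detection at } i\},$$
with $\mathrm{logit}(p_{it})$ linear in detection covariates and
$\mathrm{logit}(\psi_i) = \beta_0 + \beta' z_i + \ln L_i$, where $L_i$ is
the transect length in km. The log-length term is an *offset* (fixed
coefficient 1), so $\mathrm{invlogit}(\beta_0)$ is an occupancy *per km of
transect*. The offset is placed on the logit scale because that choice
reproduces the study's published transect-level occupancy column exactly
from its per-km density of 0.44 (0.18 at 0.28 km through 0.94 at 19.1 km);
a complementary log-log link does not.

**Abundance.** The binomial N-mixture model treats the latent abundance
$N_i$ associated with a transect as one draw from a count mixture
(Poisson, negative binomial, or zero-inflated Poisson) with
$\log \lambda_i = b_0 + b' z_i + \ln L_i$, and each visit's count as a
binomial thinning $y_{it} \mid N_i \sim \mathrm{Bin}(N_i, p_{it})$. The
marginal likelihood sums $N_i$ out up to a truncation bound `kmax`
(default 50, the value the study found sufficient; `check_kmax()`
re-evaluates the fitted likelihood with the bound doubled and reports the
change). Both models assume closure — constant state across a season's
visits — and independent detections; the generator's `availability`
option deliberately violates closure for robustness experiments.

**Key parameters and defaults.** Probabilities are modelled on the logit
scale, abundance on the log scale; continuous covariates are centred and
scaled to unit SD (`scale_covariates()`, which stores the training mean
and SD so that design points such as "10 ACOs" can be projected back onto
the model scale). The study's operating points, used as generator
defaults, are: per-km occupancy 0.44; per-survey detection 0.33 at the
mean effort of 95 ACOs and 0.19 at 10 ACOs (the two anchors determine the
generator's logit-linear ACO effect, `study_detection_coefs()`);
abundance 0.44 animals per km.

## Estimation and numerical choices

Likelihoods are maximised by BFGS from a zero-coefficient start plus four
seeded random restarts (objective tolerance `1e-8`); the covariance matrix
is the inverse observed information at the optimum, and the convergence
flag is reported honestly rather than assumed. Confidence intervals for
probabilities are computed on the linear-predictor scale and
back-transformed, which keeps them inside $[0,1]$ and reproduces the
asymmetric intervals typical of published tables. Data on the likelihood
boundary (no detections anywhere, or detections everywhere) trigger a
warning. Bootstrap refits are warm-started at the original estimates for
speed and stability, and failed refits are dropped and counted (a >10%
failure rate warns). Ties in model ranking are broken toward fewer
parameters.

Model selection uses AICc — the study's convention sets the effective
sample size to the number of surveys (132) when ranking detection
structures and the number of site-years (19) for occupancy and abundance
structures — with Akaike weights $e^{-\Delta_i/2}/\sum_j e^{-\Delta_j/2}$.
Goodness of fit is the Pearson $\chi^2$ over site-by-visit cells compared
against a parametric-bootstrap null distribution; the overdispersion ratio
$\hat c$ is the observed statistic over the bootstrap mean. When
$\hat c > 1$, ranking switches to QAICc with the deviance scaled by the
$\hat c$ of the most complex candidate and one extra parameter booked per
model for the $\hat c$ slot — that bookkeeping is why the study's
constant-abundance model is listed with three parameters, and with the
ranking $\hat c$ at its clamp of 1 it reproduces the printed criterion
value 166.11. $\hat c < 1$ (underdispersion) is clamped to 1 with a
message.

Per-transect abundance is summarised by the empirical-Bayes posterior
$P(N_i = n \mid y_i) \propto f(n;\lambda_i,\theta)\prod_t
\mathrm{Bin}(y_{it}\mid n, p_{it})$: the point estimate is the posterior
mean and the interval is the central 95% integer interval, which matches
the integer bounds of the published per-transect table (the study does not
state whether its per-transect intervals are posterior or bootstrap
intervals; posterior intervals are implemented because their integer form
matches). Total abundance sums the posterior means; its interval is a
parametric bootstrap (simulate from the fit, refit, re-sum). A minimum
number of animals known alive from individual identification can raise the
interval's lower bound (`raise_lower_bound()`), never the upper.

## Survey design calculators

With per-survey detection $p$, the chance of at least one detection in
$K$ surveys of an occupied site is $p^* = 1-(1-p)^K$, and
`min_surveys(p, confidence)` returns the smallest integer $K$ with
$p^* \ge$ the target. Ceiling is the rounding convention: it is the
defining inequality, and it reproduces the published requirement of
8/11/15 surveys at $p = 0.19$ for 80/90/95% confidence. (Published values
derived from *unrounded* detection estimates — e.g. the "4 surveys" lower
band endpoint at the printed $p = 0.33$, which requires $p \ge 0.3313$ —
cannot be reproduced from the rounded figures under any single rounding
rule and are not used as anchors.) Survey-number bands map detection
bands anti-monotonically: the upper survey bound comes from the lower
detection bound.

The two-period power analysis uses the asymptotic variance of the
occupancy MLE under imperfect detection,
$$v = \psi\Big[(1-\psi) + \frac{1-p^*}{p^* - K p (1-p)^{K-1}}\Big],$$
which collapses to the binomial variance $\psi(1-\psi)$ at $p = 1$. For a
proportional decline $R$ (so $\psi_2 = \psi_1(1-R)$), the sites needed per
period at one-tailed level $\alpha$ and power $1-\beta$ are
$S = \lceil (z_{1-\alpha}+z_{1-\beta})^2 (v_1+v_2)/(\psi_1-\psi_2)^2 \rceil$,
with $\psi_1$ evaluated from the fitted offset model at a reference
transect length (1.5 km, the regional scheme's mean). The test is
one-tailed because the alternative is a decline; a two-tailed option is
provided. Since the source study prints no equation for this procedure,
the implementation is validated against a brute-force oracle:
`simulate_decline_power()` simulates two-period detection histories, fits
each period by maximum likelihood and applies the z-test, and the
formula's $S$ lands within Monte-Carlo error of the target power.
Interval bands for $S$ propagate the detection CI endpoints with the
occupancy held at its point estimate — this choice reproduces the
published lower band of 222 sites exactly, whereas propagating the
occupancy endpoints as well would overshoot it. Cells whose design
carries no information about occupancy ($K = 1$, or $p^*$ at its
degenerate bound) are reported as unattainable rather than dropped.

## The synthetic-data generator

Because the study deposited no raw detection histories, every
likelihood-level result in this package is exercised on generated data.
`generate_design()` resamples whole site-year rows (visits, ACOs, length,
habitat, area) from the fixture with replacement — preserving the joint
skew of effort and length, which independent column resampling would
destroy — and `simulate_occupancy_history()` / `simulate_counts()` draw
from exactly the hierarchical models above, with seeds mandatory
everywhere. What the generator does *not* emulate: unmodelled detection
heterogeneity between individuals, temporary emigration (except through
the explicit `availability` dial), non-independence of repeated sites
across years, and observer variation. Passing recovery tests on generated
data therefore demonstrate that the estimators are correct for the model
class at the study's sample sizes — not that the model class is correct
for real snakes; the study's own N-mixture fits were overdispersed, a
regime covered by the generator's NB option.

## Problem sizes used in the checks

The test suite runs parameter recovery at the study scale (19 site-years)
over 200 seeded replicates for both model families, checks the bootstrap
GOF p-value for uniformity over 200 replicates of a 99-simulation
bootstrap, verifies the power formula against 200 simulated two-period
datasets at three design cells, and checks the likelihoods against
brute-force enumeration on instances of up to 4 sites (where the
$2^n$-state / $\sum_N$ sums are exact). The analysis scripts use 100–400
bootstrap simulations where the study used 1000; both are configurable
arguments.

## Known limitations

Site-years are treated as independent, as in the source design; there is
no random effect for repeated sites and no multi-season dynamic model.
Abundance estimates inherit the N-mixture assumptions (closure, binomial
thinning, known mixture family) and refer to animals *associated with* a
transect — the effective sampled area is unknown without spatially
explicit methods, which are out of scope. Wald intervals at 19 sites can
be appreciably asymmetric-in-truth; the bootstrap interval for total
abundance is the more trustworthy summary at that scale. The NB mixture's
dispersion can drift to the boundary (flagged via `boundary_dispersion`),
the known instability that led the study to prefer the Poisson mixture
for reporting.
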