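---
title: "Statistical methods behind clustrial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind clustrial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`clustrial` implements the pre-specified design and analysis machinery of a
two-arm, parallel-group cluster randomised superiority trial in which primary
schools are randomised 1:1 and children are recruited through a class-wide
screening funnel. The primary outcome is the presence of an anxiety disorder
twelve months after randomisation (binary); secondary outcomes are
questionnaire totals. Because the package is built before any trial data
exist, every stage is driven by a synthetic-data generator that reproduces
the statistical structure the analyses assume, and the whole pipeline is
validated by parameter recovery, oracle equivalence and coverage studies
rather than by published outcome results.

## Design calculations

**Power.** The power of the design is computed by a normal-approximation
two-proportion test applied to an effective sample size. Children analysed
(enrolled x follow-up rate, split 1:1 between arms) are divided by the
variable-cluster-size design effect

$$\mathrm{DE} = 1 + \{(\mathrm{cv}^2 + 1)\,\bar m - 1\}\,\rho,$$

where $\bar m$ is the mean number of *enrolled* children per school, cv their
coefficient of variation and $\rho$ the intra-school ICC. With a fixed
cluster size (cv = 0) this reduces to $1 + (\bar m - 1)\rho$. Two conventions
were genuinely open and are pinned here: attrition is applied to the numerator
(analysed children) while $\bar m$ uses the enrolled counts, and the variance
of the difference in proportions uses the unpooled form
$p_1(1-p_1) + p_2(1-p_2)$. This combination exactly reproduces the design's
published power figures (74% at 60 schools with 611 enrolled; 88% at 86
schools with 876 enrolled and 701 analysed; >90% for the original
1080-child fixed-cluster design), which is why it was selected; it is a
reconstruction, since the source states its assumptions but not its formula.

**Projections.** Funnel projections multiply stage rates and round half-up to
the nearest integer at each stage, the convention that reproduces the
published 9720/1652/611/489 and 13932/2368/876/701 chains. `required_schools()`
scans school counts upward; under these conventions 80 schools already give
85% power, and the 86-school expansion target corresponds to roughly 87.7%
computed power (printed as "approximately 88%"). The smallest count with
computed power of at least exactly 0.88 is 87 — a reminder that the printed
88% is itself rounded.

**Randomisation.** Schools are randomised within deprivation strata (above or
below 15.8% free-school-meal eligibility, the national primary-school median)
using randomly mixed permuted blocks of two and four. Block sizes are chosen
uniformly, constrained so that the list length aligns with the stratum size
whenever reachable; therefore an even-sized stratum is always exactly
balanced and the arm imbalance never exceeds two anywhere. Within each batch
and stratum, schools are ordered by their recruited pupil count before
consuming list entries, which balances pupil numbers across arms without
covariate-adaptive methods. Class sampling selects exactly two classes per
year group uniformly without replacement.

## Questionnaire scoring

Scoring follows the instrument table exactly: items are summed after
reverse-scoring (value ↦ min + max − value), partially completed measures are
prorated as mean(observed) × n_items when the completion minimum is met, and
measures with too many missing items are treated as missing. Prorated totals
are kept fractional: no rounding rule is specified and all downstream models
are continuous. The SDQ externalising score prorates each 5-item subscale
separately (at least three completed items per subscale) before summing; the
instrument table also contains a "two or more missing per subscale" clause
that contradicts the three-completed rule at exactly 3 completed / 2 missing,
and the prorating clause was implemented. CQ-P is scored as its first item
only. At the screening stage no missing items are allowed for PAS, STSC-A or
GAD-7. Screen-positive status is PAS ≥ 34, STSC-approach ≥ 30 or GAD-7 ≥ 8.
Household ties (several screen-positive siblings) are broken by the highest
PAS, then the highest STSC-approach, then — a case on which the source is
silent — deterministically by the lowest child identifier.

## The synthetic trial generator

`generate_cohort()` realises the funnel: invited children in two sampled
classes per year group (Poisson class sizes, mean 27), household-level
screening participation (17%), item-level screening responses, screen-positive
eligibility, household deduplication, enrolment (an 8% decline rate keeps the
eligible-non-participant comparison non-degenerate), stratified blocked
randomisation, principal-stratum compliance, a continuous mediator and the
clustered binary outcome.

Item responses come from a graded probit model: each child carries one latent
trait per instrument ($\theta \sim N(0,1)$, correlated 0.5 across the three
screening instruments through a shared child factor, and 0.3 between siblings
through a household factor), and item $k$ scores category $c$ when
$\theta + e_{k}$ falls between fixed thresholds chosen from per-instrument
base category probabilities. The source reports only marginal rates, so a
single location shift common to the three screening instruments is calibrated
numerically (Monte Carlo with 100,000 children under a fixed internal seed,
cached per configuration) so that the *enrolled*/screened fraction — net of
household deduplication and enrolment decline — matches the configured 37%.
The inter-instrument correlation of 0.5 is a documented assumption, not a
reported quantity; it is configurable and nothing downstream pins it.

Cluster-size variability: enrolled cluster sizes must have CV ≈ 0.68, far
above what Binomial thinning alone produces. The generator multiplies each
school's participation probability by a gamma variate with mean one and shape
$1/(\mathrm{cv}^2 - 1/\mu)$, where $\mu$ is the expected enrolled cluster
size — the closed-form choice that makes the enrolled counts approximately
negative-binomial with the target CV.

The outcome is generated on the latent-logistic scale:
$\mathrm{logit}\,P(Y{=}1) = \delta + c'X + bM + \gamma X C + u_j$, with
$\mathrm{Var}(u_j) = \rho/(1-\rho) \cdot \pi^2/3$ so the latent-scale ICC is
exactly $\rho$ (0.05 by default). $C$ is the latent complier stratum, drawn
independently of school with probability 0.6 — a realistic adherence rate for
supported online parenting interventions; the source specifies no value. The
default effect acts only through compliance ($\gamma = -1.05$,
$c' = a = b = 0$), chosen so the marginal arm contrast approximates the
0.50 vs 0.35 design alternative; the exclusion restriction of the
instrumental-variable analysis is therefore built in. Compliers in the
intervention arm complete 5–8 modules, never-takers 0–4, control children 0.
The mediator is $M = aX + v_j + \varepsilon$ with the same variance-share
convention for $v_j$.

What the generator does *not* emulate: informative cluster size, non-ignorable
(MNAR) missingness, measurement non-invariance over time, year-group or
seasonal effects, and within-class (as opposed to within-school) correlation.
Passing tests therefore demonstrate that the estimators are correct under the
trial's stated assumptions, not that those assumptions hold in real data.

`impose_missingness()` blanks whole measures with probability
$\mathrm{logit}^{-1}\{\mathrm{logit}(r_t) + 0.3(X - \tfrac12) +
0.3\,z(\mathrm{PAS}_{t0})\}$ (missing-at-random by construction, since both
predictors are observed), plus independent item-level blanks; latent
simulation-only fields are never blanked. `simulate_outcome_data()` is a
reduced generator — no funnel, direct enrolled cohort — used for the method
validation studies at controlled sizes.

## Estimation

The primary intention-to-treat analysis is a marginal logistic model fitted
by GEE with an exchangeable working correlation clustered on school and
robust sandwich standard errors. No GEE implementation ships with the
package's dependencies, so `gee_logit()` implements Fisher scoring with the
moment estimator of the working correlation; it is validated against
ordinary logistic regression (exact agreement when clusters are singletons)
and by a 500-replicate null simulation whose type-I error must stay within
3–7% at nominal 5%. The adjusted model covariates are the stratification
factor, recruited cluster size (continuous, reflecting its role in
randomisation), gender, year group, cohort and IMD decile. Continuous
outcomes use school random-intercept linear models (lme4), reported as mean
differences and standardised mean differences; the SMD denominator is the
pooled baseline SD of the outcome (the source does not define the
standardiser; the baseline SD is invariant to treatment). ICCs are reported
crude and adjusted — variance-partition for continuous outcomes, the
latent-threshold scale $\sigma_u^2/(\sigma_u^2 + \pi^2/3)$ for binary ones —
alongside the one-way ANOVA estimator that planners of future trials need.
Rubin's rules pool estimates across imputations (odds ratios on the log
scale), with the standard degrees-of-freedom formula. Moderators are tested
by robust Wald tests of arm-by-moderator interactions with per-subgroup
effects; the within-window sensitivity analysis keeps twelve-month
assessments at most 12 weeks late.

## Multiple imputation

`fit_joint_model()`/`draw_imputations()` implement joint-model multilevel
multiple imputation: all analysis variables form one multivariate normal
vector with school-level random intercepts,
$y_i = \mu + u_{j(i)} + e_i$, $u_j \sim N_p(0, \Psi)$,
$e_i \sim N_p(0, \Sigma)$, sampled by data-augmentation Gibbs with
inverse-Wishart priors ($\nu = p + 2$; scale matrices from the observed
column variances, the between-school prior at a tenth of the residual one) —
the source names the model class but not the algorithm or run lengths, so the
defaults here (burn-in 1000, thinning 100 between the 50 retained datasets)
are the package's own, reducible for tests. Fully observed variables — arm,
design covariates, and the auxiliary module-completion count, which must be
zero throughout the control arm — condition the draws of missing cells.
Binary imputations are set to 0 below 0.5 and to 1 otherwise; a k-level
categorical variable is imputed through k−1 dummies, the reference value
reconstructed as $1 - \sum m_i$, and the level with the largest value
assigned (argmax ties to the lowest index). Continuous draws outside the
plausible range are retained unrounded, and skewed variables can be
log-transformed before fitting and back-transformed afterwards. Convergence
is summarised by Geweke z-scores of the grand-mean chain; validation covers
observed-cell preservation, MCAR unbiasedness and recovery of a simulated
between-school variance component.

## Bayesian mediation

Each candidate mediator (a 12-week questionnaire total) is analysed by a
three-equation path model: a school random-intercept linear regression of
the mediator on arm ($a$ path), and school random-intercept logistic
regressions of the outcome with ($b$, $c'$) and without ($c$) the mediator.
A cluster-specific (random-effects) outcome model is used here even though
the primary analysis is population-averaged, because the posterior-sampling
construction requires it. Models are fitted by Gibbs sampling in JAGS with
weakly informative priors — normal(0, 2.5) coefficients on standardised
predictors, normal(0, 10) intercepts, half-normal(2.5) scales — which are
recorded verbatim on every result object. The indirect effect is formed
draw-by-draw as $ab$ and the proportion mediated as $ab/(ab + c')$; pooling
across imputed datasets simply concatenates posterior draws. Two documented
caveats: the proportion mediated mixes a linear-scale $a$ with logistic-scale
$b$ and $c'$ exactly as constructed, with no rescaling; and when $ab$ and
$c'$ oppose in sign the proportion falls outside [0, 1] and is reported
unmodified with a warning — the source defines no behaviour for that case.
Split-chain R-hat (threshold 1.01) and effective sample sizes gate results:
exceedances warn by default and error under `strict = TRUE`. Default
sampling is 4 chains of 1000 post-warmup draws per imputation; the test
suite and reduced pipeline use 2 x 400.

## Complier average causal effect

Compliance is completing at least the first five online modules (0–4);
control-arm children cannot comply. Stage 1 regresses compliance on arm (and
the pre-specified covariates) by a *linear* school random-intercept model and
keeps each child's residual total — observed compliance minus the
fixed-effects prediction, i.e. the estimated cluster effect plus the
individual residual. Stage 2 is the primary-analysis GEE of the outcome on
compliance status, that residual total and the covariates; the compliance
coefficient $\beta_1$ is the CACE log-odds. In the full-compliance limit the
residual covariate is identically zero, is dropped, and the procedure
reproduces the ITT estimate exactly (a tested identity). Standard errors come
from a cluster bootstrap that resamples schools with replacement — stratified
by arm to preserve the 1:1 design, a choice the source leaves open — rerunning
both stages per replicate (default 1000); Rubin's rules then pool
$\beta_1$ across imputations using the bootstrap variances, bootstrap inside
imputation, matching the order in which the procedures are described. The
recovery study shows the expected behaviour: with a conditional complier
log-odds of 0.8 and 60% compliance the estimator centres near 0.76 (logistic
non-collapsibility shrinks conditional effects on the population-averaged
scale) while the ITT estimate attenuates towards 0.47; the residual
coefficient $\beta_2$ is reported but not interpreted.

## Reporting and orchestration

`build_flow()` produces CONSORT-style counts (schools and children by stage
and arm, losses between timepoints, cluster-size mean/SD by arm per
timepoint, recomputed from raw data); `baseline_table()` summarises
characteristics as mean (SD) or median [IQR] and count (percent, one decimal,
half-up); `missingness_summary()` reports percent missing per
outcome/timepoint/arm with prorating counts separated; and
`nonparticipant_comparison()` contrasts screening measures between eligible
participants and eligible non-participants descriptively (no tests — the plan
calls for assessment, not testing). `run_pipeline()` chains all stages with
counter-based sub-seeds derived from one global seed, so identical
configurations give byte-identical manifests and stage re-runs do not depend
on execution order. The reduced mode (10 schools, m = 5, 200 bootstrap
replicates, 2 x 400 MCMC) exists so the full chain can be smoke-tested in
about a minute; it also trims the adjustment set to variables a 10-school
design can support. Problem sizes used in the validation suite (e.g. 500
null replicates for the GEE, 200 for CACE recovery, 50 reduced replicates
for mediation coverage, 60 x 10–15 cluster layouts) were chosen to keep
Monte-Carlo error well inside each test's tolerance.

## Known limitations

The power formula is a reconstruction pinned to the published figures;
alternative conventions (pooled variance, attrition inside $\bar m$) give
values a point or two away. 2SRI for a binary outcome is an approximation —
exact identification holds in the linear case — so CACE recovery is judged
on the population-averaged scale. The joint imputation model is normal;
binary/categorical variables are handled by the stated rounding rules rather
than latent-threshold likelihoods. The generator's item responses share one
trait per instrument (no item-specific difficulty correlations), and its
inter-instrument correlation default is an assumption. Health-economic
outcomes, acceptability data and diagnostic-interview logistics are out of
scope throughout.
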