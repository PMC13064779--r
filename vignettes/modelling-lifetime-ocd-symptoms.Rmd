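---
title: "Modelling lifetime OCD symptoms: hierarchical structure, testlet scoring, and agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling lifetime OCD symptoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(testletr)
```

## The scientific problem

Obsessive–compulsive disorder is heterogeneous: over a lifetime, patients
accumulate symptoms from several recognisable domains (doubt/checking,
contamination, symmetry/ordering, hoarding, taboo thoughts), yet most
patients' exact symptom patterns are unique to them. Two views of this
heterogeneity compete: symptoms as expressions of a handful of distinct
domain factors, or symptoms as graded indicators of a single underlying
propensity to develop OCD, with domains adding structure on top. `testletr`
implements the statistical machinery to adjudicate between these views on
a binary lifetime symptom checklist (64 items by default), to score
individual OCD propensity from the winning hierarchical model, and to
compare that score against an independent clinician severity rating scale
(10 ordinal items).

## Latent structures for binary symptom data

Let $y_{ij} \in \{0, 1\}$ indicate lifetime presence of symptom $j$ in
person $i$. Three nested-or-competing measurement models are fitted by
marginal maximum likelihood:

1. **Unidimensional 2PL.**
   $P(y_{ij}=1) = \mathrm{logit}^{-1}(a_j \theta_i + c_j)$ with a single
   propensity $\theta_i \sim N(0,1)$.
2. **Correlated five-factor.** Each item loads on its domain factor only;
   the five factors have unit variance and a free correlation matrix.
3. **Hierarchical bifactor.** Every item loads on a general OCD factor and
   on exactly one orthogonal domain-specific factor
   ($P(y_{ij}=1) = \mathrm{logit}^{-1}(a_{j0}\theta_{i0} +
   a_{jd}\theta_{id} + c_j)$, all factors independent standard normal).

Model fit is compared by AIC, BIC and chi-square likelihood-ratio tests
for nested pairs; `leave_one_domain_out()` refits the bifactor model five
times with one domain's specific factor removed, ranking domains by their
log-likelihood contribution beyond the general dimension.

### Estimation

The marginal likelihood is integrated by Gauss–Hermite quadrature and
maximised by EM. Each M-step solves one small weighted logistic regression
per item by damped Newton iterations; for the correlated model the
correlation matrix is updated from the posterior second moment of the
factors, standardised back to unit variances. Design choices worth
knowing:

* **Dimension reduction.** The bifactor likelihood factorises, given the
  general factor, over domains; each domain needs only a two-dimensional
  grid (defaults: 21 general x 15 specific nodes). The correlated model
  uses a full five-dimensional grid (default 5 nodes per dimension,
  `nodes_correlated` is the accuracy/cost switch; the heavy simulation
  studies in the test-suite use 3).
* **A deterministic optimizer.** The estimand is the ordinary marginal-ML
  solution; a deterministic quadrature EM (rather than a stochastic
  optimizer) makes every fit exactly reproducible from fixed starting
  values (intercepts at the logit of the endorsement rate, slopes at 1).
* **Moving-grid caveat.** The correlated model's quadrature grid moves
  with the correlation matrix, so a raw moment update can *decrease* the
  discretised likelihood. The update therefore backtracks (full step,
  then damped steps) and is only accepted if the quadrature
  log-likelihood does not drop; with this guard the EM ascends
  monotonically, which the tests assert at every iteration.
* **Identification and tie-breaks.** Factors have unit variance; specific
  slopes are sign-fixed positive per domain (the likelihood is invariant
  to a domain's sign flip). Items endorsed by nobody or everybody are
  given a weak ridge penalty (default `1e-3`) and flagged rather than
  allowed to diverge.
* **Standardised loadings.** Slopes convert to factor loadings on the
  normal-ogive metric, $\lambda_{jk} = (a_{jk}/1.702) / \sqrt{1 +
  \sum_k (a_{jk}/1.702)^2}$. An item "retains" a salient domain
  relationship when its standardised specific loading is at least 0.35 —
  the threshold is a package choice (`loading_threshold`), set at the
  lower end of loading ranges conventionally reported as significant, and
  is configurable because no universal criterion exists.

## The Bayesian testlet response model

For scoring, the package uses the testlet parameterisation of the
hierarchical model:

$$P(y_{ij} = 1) = \mathrm{logit}^{-1}\!\big(a_j(\theta_i - b_j -
\gamma_{i,d(j)})\big), \qquad \gamma_{i,d} \sim N(0, \sigma_d^2),$$

where $b_j$ is the propensity level at which symptom $j$ is endorsed with
probability one half (its "severity"), $a_j$ its discrimination, and the
person-by-domain testlet effects $\gamma$ absorb the extra dependence of
symptoms within a domain. Posterior inference is by
Metropolis-within-Gibbs MCMC (`run_mcmc()`), with compiled inner loops.

**Priors** (all configurable; the model description the package follows
does not state them, so these are package defaults): $\log a_j \sim
N(0, 1)$, $b_j \sim N(0, 2^2)$, $\sigma_d^2 \sim$ Inverse-Gamma(2, 1),
$\theta_i \sim N(0,1)$ fixed for identification.

**Sampler.** Each sweep updates persons, testlet effects, item pairs
$(\log a_j, b_j)$, and testlet variances (the only conjugate block).
Random-walk proposal scales adapt by Robbins–Monro toward 0.44 acceptance
during burn-in only, preserving detailed balance afterwards. Because
$\theta_i - \gamma_{i,d}$ is all the likelihood sees, a joint shift of a
person's propensity and testlet effects is likelihood-invariant and
prior-Gaussian; the sampler Gibbs-draws this shift exactly each sweep,
removing the slowest-mixing direction. Chains start overdispersed
($\theta \sim N(0, 2^2)$, $\log a \sim N(\pm 0.5, 0.5^2)$ with the sign
alternating by chain).

**Convergence.** With at least two chains, every item parameter and
testlet SD is monitored by the Gelman–Rubin potential scale reduction
factor, computed as $\sqrt{((n-1)/n\,W + B/n)/W}$ so that duplicated
chains give exactly $\sqrt{(n-1)/n}$. The run passes when all monitored
PSRFs are below 1.2 (the conventional threshold); `summarize_items()` and
`score_persons()` refuse to summarise a failed run unless explicitly
overridden, and the 50th/97.5th percentiles of the item-parameter PSRFs
are reported. The documented production configuration is 40&nbsp;000
iterations per chain with the first 10&nbsp;000 discarded, two chains;
the test-suite runs desk-scale chains (4&nbsp;000/1&nbsp;000 at
$n = 2000$, shorter on toys), which the recovery checks show to be
sufficient at those sizes.

Person scores are posterior means of $\theta_i$ with the posterior SD as
the score's standard error. Persons endorsing no symptom are flagged: the
checklist cannot rank-order them further, so their scores shrink toward
the low end with wide uncertainty.

## The clinician severity scale

The 10 ordinal (0–4) clinician ratings are modelled by a graded response
model, $P(Y_{ij} \ge k) = \mathrm{logit}^{-1}(a_j(\eta_i - b_{jk}))$ with
ordered thresholds $b_{j1} \le \dots \le b_{j4}$, fitted by EM with 41
Gauss–Hermite nodes. Standard errors come from the outer-product (BHHH)
estimate of the observed information — deterministic and cheap at this
scale. Rating categories never observed for an item are merged downward
with a recorded remapping; items with fewer than two observed categories
are dropped with a warning. `eap_scores()` returns posterior means and
SDs of $\eta$; persons with no administered rating fall back to the prior
(0 ± 1) and are flagged.

The severity scale's own latent structure can be compared the same way
as the checklist's: `fit_graded_structure()` fits unidimensional,
two-correlated-factor and hierarchical (general + group factors) graded
models on a full quadrature grid, with the obsession/compulsion item
split (first five vs last five ratings) as the default grouping — the
conventional halves of the instrument, configurable because alternative
partitions (a resistance/control grouping) have also been proposed. The
hierarchical fit necessarily nests the unidimensional one, which the
tests assert.

A study-design rule connects the two instruments: persons with no
lifetime diagnosis, no endorsed checklist symptom, and no administered
severity scale are assigned ratings of 0 on all ten items
(`impute_zero_severity()`); missingness is otherwise retained, since
absence of assessment is not absence of symptoms.

## Agreement between the two scoring routes

With no gold standard, the checklist-derived and severity-derived scores
are compared on the scale of their joint uncertainty: per person, the
difference (checklist minus severity) is plotted against the common mean,
and the two routes *agree* when $|\mathrm{diff}| \le z\sqrt{SE_1^2 +
SE_2^2}$ with $z = 1.96$ (a 95% region; configurable). The summary
reports the percent agreeing, the Spearman rank correlation of the two
estimates (average-rank ties), and the flagged disagreements;
`autoplot()` draws the Bland–Altman plot and plot coordinates are exported
so any smoother can be layered on top.

## What the synthetic generator emulates — and what it does not

Real lifetime-symptom data of this kind are access-restricted, so
`sim_config()`/`simulate_study()` generate the study conditions the
package targets: 999 persons, 37.5% of them unaffected relatives; 64
checklist items in domain blocks of 16/13/15/2/18 (the three published
domain sizes, completed by a 13-item contamination and 2-item hoarding
split; the per-item assignment is synthetic); discriminations uniform on
0.5–3 and severities on 0.3–2.7, bracketing the published severity range
0.54–2.65; moderate within-domain testlet dependence (SD 0.75 per
domain); a severity item bank anchored to published values where printed
and mirrored where not; and a latent correlation of 0.8 between the
checklist and severity traits. The unaffected stratum is shifted down by
3.5 SD, a value fixed once by forward simulation so that roughly a
quarter of persons endorse no symptom.

Deliberate simplifications: no family or genetic structure, no real item
content, no per-symptom worst-period ratings, and the unaffected mixture
is a stand-in for a response process the source material does not
describe. One consequence worth knowing: the mixture makes the marginal
$\theta$ distribution non-normal, while the estimation models assume
$N(0,1)$ — fitting them to mixture data compresses the latent scale
(testlet SDs shrink by roughly the factor by which the sample's latent SD
exceeds 1). Parameter-recovery checks therefore generate from the pure
model (`unaffected_frac = 0`); pipeline runs on the full mixture exercise
realism, not recovery. Passing tests show the machinery is correct under
its assumptions; they cannot show that real checklist data satisfy them.

## Problem sizes and numerical settings used by the checks

The package's own validation (test-suite and `scripts/acceptance.R`)
uses: dense-grid likelihood oracles on 4-person toys (relative error
below $10^{-6}$); model-selection studies at $n = 1500$ with 10 seeds
(3 in the faster acceptance script) at reduced quadrature (11 x 7
bifactor nodes, 3 correlated nodes per dimension, EM tolerances
$10^{-2}$–$3\times10^{-2}$); domain-ablation studies at $n = 1000$;
testlet MCMC recovery at $n = 2000$ with two chains of 4&nbsp;000
(burn-in 1&nbsp;000) and testlet SDs alternating 0.5/1.0; GRM recovery at
$n = 2000$; and agreement coverage at $n = 400$ across seeds with the two
traits set perfectly correlated and scores computed under true item
parameters, so the posterior SEs are honest and the nominal 95% region
should cover roughly 90–99% of persons. These sizes are the package's
choices for routine verification; all are configurable upward.

## Known limitations

* The correlated five-factor model reports the best-iterate solution of a
  discretised likelihood; at very coarse grids its absolute
  log-likelihood carries quadrature bias of the order of tens of units
  (model *comparisons* at matched settings are far more stable).
* EAP scoring of the correlated model is not provided; score on the
  unidimensional or bifactor structure.
* The sampler's person-level draws are stored densely; at much larger
  $n$ than the defaults, thin the chains.
* No 3PL guessing parameter, covariates, or limited-information (WLSMV)
  estimators; exploratory factor analysis and rotation are out of scope.
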