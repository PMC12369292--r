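---
title: "Benchmark dose estimation from case-control summary tables: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmark dose estimation from case-control summary tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccbmd)
```

## The problem

Regulatory benchmark dose (BMD) analysis is built for toxicological
bioassays: groups of animals at controlled doses, a response count or a
continuous measurement per group. Published case-control studies report
something else — adjusted odds ratios (ORs) with confidence intervals per
exposure *range*, raw case/non-case counts, and a referent group that is
itself exposed (background exposure never vanishes in human populations).
`ccbmd` turns such summary tables into BMD estimates along two parallel
tracks and quantifies how well the tracks agree:

1. **Dichotomous track** — the adjusted ORs are converted into "effective"
   case/non-case counts (counts that would reproduce the confounder-adjusted
   ORs as crude ratios), which are then modeled as quantal dose-response
   data.
2. **Continuous track** — the adjusted OR itself is treated as a lognormal
   continuous response, using the reported CI to recover a log-scale mean
   and SD per group.

The packaged fixtures are ten case-control studies of bladder and lung
cancer versus inorganic arsenic in drinking water (five studies per
endpoint, spanning Taiwan, Chile, Finland, Bangladesh and the USA).

## Exposure pre-treatment

Reported exposure ranges are collapsed to points and scaled by drinking
water intake, `adjusted_midpoint()`: a closed interval maps to its
midpoint, an open-below first group to half its upper bound, an open-above
last group to 1.5 times its lower bound (the midpoint of `(l, 2l)`), and a
reported median to itself; everything is multiplied by the ratio of the
study population's intake rate to a 2 L/day baseline, so exposures are
comparable across populations with different water consumption.

Two of the ten source tables print midpoints that do not follow these
rules: the Pu bladder referent row scales the *full* upper bound rather
than half of it, and the Mostafa interior rows use the previous group's
upper bound in the midpoint. We read these as source-table dialect rather
than evidence about the rule (the same tables follow the standard rules
everywhere else). `adjust_dataset(..., use_printed = TRUE)` keeps the
stored printed values so the published tables can be reproduced verbatim;
the default recomputes everything from the interval bounds.

## Effective counts

The referent group's effective split $(A_0^e, B_0^e)$ is not identified by
any single OR; it is estimated by a grid search in the spirit of the
OR-to-relative-risk conversion algorithm for partially reported studies.
All treatment groups are collapsed into one pseudo-group carrying the
arithmetic mean OR and mean CI bounds; for each candidate split of the
referent subjects, the pseudo-group's counts follow from OR-equivalence,
and a Woolf CI is reconstructed around the mean OR. The objective is the
squared log-discrepancy between reconstructed and reported mean bounds.

Two numerical facts shaped the implementation, both visible in
`wang_referent()` output:

* The objective is generically **bimodal**: a low-incidence branch and a
  mirrored high-incidence branch produce nearly the same interval widths
  (the Woolf SE is symmetric in $1/A_0 + 1/B_0$). The published referent
  counts consistently sit on the low-incidence branch, so the search
  returns all local minima and selects the smallest candidate count;
  every candidate is kept in the result for inspection.
* The published sum-of-squares integrand is cited, not printed. Under the
  objective above, the printed referent splits are reproduced exactly for
  five of the ten fixtures and within one or two counts for three more;
  two studies (Mostafa, Smith) disagree by more. Disagreements are
  *reported*, never silently replaced — fixture runs use the printed
  counts, which are calibration targets, not outputs.

Treatment-group effective counts then follow deterministically from
`propagate_group()`: subject totals are preserved and the crude OR of the
effective counts equals the adjusted OR, giving
$A_i^e = N_i q/(1+q)$ with $q = OR_i A_0^e / B_0^e$. Counts may be kept
real-valued (the default; the likelihood is Gamma-extended) or rounded to
the nearest integer with the pair sum repaired through the non-case count.
One printed cell is inconsistent with its own table (the lung
Ferreccio 2000 third group prints 48 where its printed referent propagates
to 47.47); the fixture stores the printed value verbatim and the tests
document the one-count gap.

## Likelihoods

**Dichotomous.** A binomial likelihood per group with the binomial
coefficient extended to real arguments through the Gamma function, so
real-valued effective counts are first-class:
$$\ell(\theta) = \sum_i \log\tbinom{n_i}{y_i} + y_i \log f(d_i|\theta)
  + (n_i - y_i)\log(1 - f(d_i|\theta)).$$
Models: quantal-linear $g + (1-g)(1-e^{-\beta d})$ and dichotomous Hill
$g + (v - vg)\,\mathrm{logit}^{-1}(a + b\log d)$.

**Continuous.** The log OR per group is a normal sample mean with known
group size; the reported CI yields the log-scale SD
$s_i' = \log(OR_U/OR_L)/(2z)$. The likelihood is the standard
summary-statistics form with a common within-group SD $\gamma$:
$$\ell(\theta,\gamma) = \sum_i -\tfrac{n_i}{2}\log(2\pi\gamma^2)
 - \frac{(n_i-1)s_i'^2 + n_i(\bar y_i' - f(d_i|\theta))^2}{2\gamma^2},$$
with the referent contributing only its mean term ($s_0' \equiv 0$, since
its OR is identically 1). Models: linear $a + bd$ and Hill
$a + v d^n/(k^n + d^n)$, both on the log-OR scale. The variance treatment
is isolated in `loglik_continuous()` so an alternative convention can be
swapped in if one were preferred.

## Benchmark response calibration

The dichotomous BMR is extra risk measured from the referent *group* (not
zero dose): $BMR_D = (f(BMD) - f(d_{ref}))/(1 - f(d_{ref}))$, at the
standard levels 0.1%, 0.5% and 1% — chosen because they correspond to
roughly 1–20 extra cases per million at the BMD for these cancer
endpoints. The continuous BMR is the relative change in OR. The two are
calibrated to describe the same incidence change *before fitting*, from
the input data alone: with the referent incidence
$f_{ref} = A_0^e/N_0^e$ and the referent OR fixed at 1,
$$BMR_C = \frac{BMR_D(1 - f_{ref}) + f_{ref}}{f_{ref}} - 1 .$$
For example, referent effective counts of 18/128 give
`convert_bmr(0.001, 18/128)` $\approx 0.61\%$. Fixture runs compute
$f_{ref}$ from the printed (integer) effective counts.

BMD inversion (`bmd_from_theta()`) is bracketed root finding on
$[d_{ref}, 50\,d_{max}]$, expanded once to $500\,d_{max}$ before a draw is
declared unattainable; the quantal-linear and linear closed forms serve as
independent oracles in the tests (agreement to $10^{-9}$ relative).

## Bayesian fitting

No MCMC engine is available in the target environment, so the sampler is
a self-contained adaptive random-walk Metropolis (`fit_bmd()`): proposal
covariance and global scale adapt during warmup (Robbins-Monro toward
23.4% acceptance with the empirical-covariance proposal), then freeze;
defaults are 4 chains of 10,000 iterations with the first half discarded.
Convergence is checked by split-Rhat (< 1.05) and Geyer-initial-sequence
effective sample size (> 400); violations warn rather than error, because
a long right tail in a weakly identified Hill power is expected behavior
on 3–6 group datasets, not a usage error.

Doses are internally rescaled by the maximum observed dose, so one set of
weakly informative priors serves exposure ranges from 0.04 to 1080 µg/L:
uniform(0,1) backgrounds and asymptotes, half-normal slopes on the scaled
axis, normal(0,10) intercepts, uniform(1,18) Hill power, half-Cauchy(1)
residual SD (all stated per-parameter in `default_priors()`, all
overridable, and recorded in the fit object). The source analysis defers
its priors to supplementary material that is not recoverable; exact
reproduction of its per-study BMD tables is therefore not claimed — the
cross-track *consistency* structure is the reproducible claim.

`summarize_bmd()` applies the BMD inversion to every retained draw: BMD is
the posterior median, BMDL/BMDU the 5th/95th percentiles (one-sided 95%
bounds, the regulatory convention; configurable). Unattainable draws are
excluded with a logged count; beyond 50% the estimate is flagged
unreliable.

## Cross-track agreement and the synthetic world

`run_paper_pipeline()` runs both tracks over all ten fixtures at the three
BMR levels for the simple pair (quantal-linear vs linear) and the complex
pair (dichotomous Hill vs Hill), pooling BMD, BMDL and BMDU into the
correlation as the source analysis does. `agreement()` reports pooled
Pearson r on the raw dose scale (the default, with a log-scale companion
always reported, since the published analysis does not state its scale),
plus Spearman's rho and tie-corrected Kendall's tau-b computed per dataset
and aggregated by Fisher's Z transform (coefficients clamped at
$1 - 10^{-6}$ before atanh; per-dataset values are reported raw).

A caveat the numbers force on us: the raw-scale pooled Pearson r is
dominated by whichever dataset produces the largest estimates. The Mostafa
lung study (near-flat ORs of 1.13 and 1.28, but large samples) yields a
wide dichotomous posterior against a tight continuous one, and its upper
bounds can pull the pooled raw-scale r well below the rank-based
coefficients, which sit near 1. Both scales are therefore always printed.

**Synthetic generator.** `simulate_case_control()` draws group case counts
binomially from a known dichotomous curve and republishes them exactly the
way the fixtures look: crude ORs with Woolf 95% CIs, referent first
(zero cells are redrawn up to a retry cap, then continuity-corrected with
0.5 and flagged). Recovery tests use the stated world of the validation
design: 4 groups at 10/100/300/700 µg/L (the span of the arsenic tables),
500 subjects per group, quantal-linear background 0.05 and slope 0.002 per
µg/L; the cross-track recovery property draws slopes log-uniformly over
5e-4–8e-3 so that true BMDs spread the way the real studies do. What the
generator does *not* emulate: confounding (its ORs are crude by
construction, so effective counts equal raw counts), exposure
misclassification, and interval-censored dose reporting — a green
recovery test establishes internal consistency of the two tracks, not
robustness to those features.

## Numerical choices and limitations

* Interval parsing treats strict and non-strict comparators identically;
  midpoint formulas cannot distinguish them.
* The Wang grid search defaults to integer steps (step 1) with a
  real-valued option (step 0.1); minimization over integer vs real
  candidates is unstated in the source, so both are supported; smallest
  local minimum wins, deterministically.
* Likelihood evaluations at pinned responses return $-\infty$ rather than
  erroring inside the sampler; parameter-constraint violations at extreme
  proposals are treated as zero posterior mass.
* Root finding uses a relative tolerance of ~$10^{-15}$ of the bracket and
  is verified against closed forms to $10^{-9}$ relative.
* BMDL/BMDU levels and the source analysis's priors are assumptions, not
  reproductions (see above); per-study BMD tables are emitted for
  inspection, not asserted.
* Low-prevalence is assumed where OR stands in for relative risk; no
  numerical correction is applied (none is defined in the source
  framework).
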