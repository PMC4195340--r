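---
title: "Models and methods behind nmabayes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nmabayes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmabayes)
```

This vignette documents the statistical model, the numerical choices, and
the design decisions in `nmabayes`, in the spirit of a methods appendix. It
states no empirical result that the package's test suite does not itself
compute.

## The binomial-logit NMA family

All models share the arm-level likelihood
$r_{ik} \sim \mathrm{Binomial}(p_{ik}, n_{ik})$ with
$\mathrm{logit}(p_{ik}) = \mu_i + \delta_{ik}$ and
$\delta_{i,\text{baseline}} = 0$. The baseline arm of a study is the arm
whose treatment has the lowest index; treatment 1 is the network reference,
ideally the treatment appearing in the most studies (the package defaults
to that choice, with ties broken by registry order).

* **Fixed effects, consistency.**
  $\delta_{ik} = d_{t_{ik}} - d_{t_{i1}}$ with basic parameters
  $d_2,\dots,d_K$ and $d_1 \equiv 0$. Every pairwise contrast is
  $d_j - d_i$, so the consistency identity
  $\mathrm{OR}_{AB}\cdot\mathrm{OR}_{BC} = \mathrm{OR}_{AC}$ holds per
  posterior draw by construction.
* **Random effects, consistency.** The $\delta_{ik}$ of one study are
  jointly normal around the fixed-effects means with variance $\sigma^2$
  and pairwise covariance $\sigma^2/2$ — the homogeneous-variance
  exchangeable structure that induces the correct correlation between arms
  of multi-arm trials. The sampler works with the equivalent sequential
  conditionals: arm position $k \ge 2$ has conditional mean
  $(d_{t_{ik}} - d_{t_{i1}}) + \tfrac{1}{k-1}\sum_{j<k}\big[\delta_{ij} -
  (d_{t_{ij}} - d_{t_{i1}})\big]$ and variance $\sigma^2 k / (2(k-1))$,
  reducing to $\sigma^2$ for two-arm trials.
* **Unrelated mean effects (UME).** The inconsistency model assigns one
  independent mean-effect parameter to each *observed* baseline-relative
  comparison (multi-arm trials contribute contrasts against their own
  baseline only, so a pair observed merely "sideways" gets no parameter).
  The random-effects variant shares a single $\sigma$ across comparisons
  with independent trial-specific effects, the convention of the standard
  technical-support-document code for this model. On a loop-free network
  UME and consistency carry the same information comparison-wise, which the
  test suite exploits as a cross-check.

Outcome direction ("bad" such as mortality, versus "good") affects ranking
and reporting only — never the likelihood.

## Priors

Baselines and mean effects get vague normals with mean 0 and variance
$10^4$ (sd 100). We read the conventional `dnorm(0, 10000)` notation of
spreadsheet/WinBUGS workflows as a *variance* of $10^4$: the precision
reading (sd 0.01) would be anything but vague, contradicting both the
stated intent and the NICE-TSD convention (`dnorm(0, 1.0E-4)` precision,
i.e. sd 100). Both variances are configurable in `nma_priors()`.

Heterogeneity: `sd ~ Uniform(0, 2)` by default — 2 is already an enormous
between-study sd on the log-odds-ratio scale — or an informative lognormal
prior on the variance $\sigma^2$ selected by outcome and comparison
category via `turner_prior()`. The shipped category table
(`inst/extdata/turner_heterogeneity_priors.csv`) carries representative
values of the published empirical predictive distributions for log-odds-ratio
heterogeneity; it is deliberately a plain, editable CSV and users applying
informative priors in earnest should verify the entries against the source
publication or substitute their own. No default analysis depends on these
values.

## Zero cells

Trials with a zero-event (or all-event) arm leave the odds ratio formally
estimable in a Bayesian analysis, so the correction is optional and off by
default. When requested, `correct_zero_cells()` applies an adjusted
continuity correction centered around 0.5 and sensitive to sample-size
imbalance: within any study containing such a cell, arm $a$ receives
$c_a \propto 1/\bar n_{-a}$ (reciprocal of the mean size of the *other*
arms), normalized so $\sum_a c_a = A/2$ for $A$ arms — corrections average
exactly 0.5 and equal-sized arms get exactly 0.5 each, the classical value.
$c_a$ is added to the events and $2 c_a$ to the denominator. The correction
applies to *all* arms of an affected study (not only the zero cell), no
study is ever dropped, and all-zero studies trigger a warning since they
cannot inform relative effects. Corrected counts are fractional; the
likelihood uses the log-Gamma continuous extension of the binomial
coefficient so they are handled exactly. The rule is intentionally a
documented, reproducible choice: the literature contains several "adjusted"
corrections and reasonable implementations differ in detail. Re-applying
the function to already-corrected data is *not* a no-op if corrected cells
still sit at zero; on data without zero/all-event cells it is the identity.

## Sampling

The posterior is sampled by adaptive random-walk Metropolis within Gibbs,
implemented in C++: scalar blocks for each $\mu_i$, each mean-effect
parameter, each $\delta_{ik}$ (random effects; updated baseline-to-last
within each study), and $\sigma$. Per-block Gaussian step sizes adapt
toward an acceptance rate of about 0.44 — the scalar-update optimum — in
windows of 50 iterations during burn-in only, with diminishing adaptation
gain $\min(0.1, 1/\sqrt{\text{window}})$; after burn-in all step sizes are
frozen so the retained kernel is strictly stationarity-preserving. The
$\sigma$ block is proposed five times per sweep: it couples to every
trial-specific effect, and the extra (cheap) proposals reduce its
autocorrelation substantially. A split-half agreement test and acceptance
rates logged per block guard these choices.

Initial values follow the customary randomized scheme: $\mu_i$ and $d$
uniform on configurable ranges (default $(-2, 2)$), $\delta$ at its
conditional means, $\sigma$ uniform over the central half of its prior
mass. Chain $c$ seeds R's RNG with `seed + c`, making every draw — and
therefore the entire pipeline through the league table — bit-reproducible.
Non-finite starting posteriors are re-drawn up to 50 times.

Defaults are 3 chains, 20,000 burn-in and 40,000 retained iterations
(thinning optional). On the shipped 12-study network this takes a few
seconds and passes the Monte-Carlo-error rule with a comfortable margin.

Sampler correctness is established against an independent oracle: for
two-treatment fixed-effects networks the marginal posterior of $d_2$ is
computed by dense grid integration (study baselines marginalized by 1-D
quadrature), and MCMC means and quantiles must agree within three Monte
Carlo errors, where the quantile MC error uses the batch-means error of the
exceedance indicator scaled by a kernel density estimate at the quantile.

## Diagnostics and model criticism

* **PSRF** is the classic potential scale reduction factor
  $\sqrt{((n-1)/n\,W + B/n)/W}$ on retained draws; the interval-based
  refinement is out of scope since the within/between variance ratio is
  what the workflow specifies. Degenerate constant chains raise an error
  rather than returning a number.
* **Monte Carlo error** uses batch means with 50 batches (configurable),
  chains concatenated, trailing remainder dropped; the adequacy rule is
  MC error < 5% of the posterior sd for every effect estimate and the
  between-study sd.
* **Residual deviance and DIC** follow the binomial saturated-deviance
  convention with $0\ln 0 = 0$; $\hat D$ evaluates at posterior *means of
  the fitted probabilities* (probability scale), the standard convention
  for binomial NMA; $pD = \bar D - \hat D$, $\mathrm{DIC} = \bar D + pD$.
  Per-point posterior mean deviances sum to $\bar D$ exactly and are
  labeled (study, treatment) so any point of the dev–dev plot can be
  identified. The dev–dev flag marks points whose consistency deviance
  exceeds their inconsistency deviance by a configurable margin, default 1
  deviance unit (about one poorly fit data point). Fit statistics computed
  on continuity-corrected data carry a warning, since corrected zero cells
  make deviance summaries look artificially favorable.

## Reporting conventions

Posterior summaries use R's default type-7 quantile convention, stated here
because league tables are sensitive to tie-handling folklore. League-table
cells are computed once per unordered pair and mirrored as exact
reciprocals, so `cell(i,j) * cell(j,i) = 1` identically; the grid is
labeled "row versus column, read top to bottom and left to right" in the
object itself to avoid the classic orientation ambiguity. Ranking ties
(measure-zero for continuous draws) break by treatment index. SUCRA follows
the cumulative-rank formula, averaging exactly 0.5 over treatments;
reversing the outcome direction maps SUCRA to 1 − SUCRA. The evidence
network layout places nodes on a circle with radius proportional to
$\sqrt{\text{participants}}$ — area-proportional, the visually honest
reading of "node size proportional to sample size" — and edge width linear
in trial count. Figures are optional render targets; the exported plot
*data* are the tested contract.

## The synthetic-data generator

`simulate_nma()` is the forward version of the random-effects consistency
model: uniform study baselines, trial-specific effects drawn *jointly* from
the exchangeable covariance (not via the sampler's sequential conditionals,
keeping recovery tests independent of that decomposition), binomial counts
at the implied probabilities. Defaults — baseline log-odds in
$(-2, -0.5)$, arm sizes 200–400, two-arm studies cycling through the
non-reference treatments — mimic a moderately sized trial network with
event rates around 10–40%. An optional scalar `inconsistency_bump` offsets
comparisons in studies whose baseline is not the reference, injecting loop
inconsistency for dev–dev testing.

What the simulator does *not* emulate: small or unbalanced trials, rare
events and the zero cells they produce, heterogeneity that varies by
comparison, effect modification, or publication bias. Passing recovery
tests therefore demonstrates internal statistical correctness of the
model-sampler pair, not robustness to the pathologies of real evidence
bases.

Test problem sizes are deliberately modest — recovery runs use 30 studies
and 20 replicates with shortened chains (1,500 burn-in, 3,000 retained),
which the Monte-Carlo-error rule shows is ample for these well-identified
toys — so the full suite runs in well under a minute.

## Known limitations

Binomial outcomes only (no continuous, count or survival likelihoods); no
meta-regression or covariate adjustment; inconsistency assessment by
UME-versus-consistency comparison only (no node splitting); no
effective-sample-size machinery; a single shared $\sigma$ across
comparisons in random-effects models. The 15-treatment/50-study caps of
spreadsheet-hosted workflows are surfaced as warnings, not errors — they
are a tooling limit, not a statistical one.
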