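---
title: "Variable-rates phylogenetic regression: model, priors, and operating characteristics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variable-rates phylogenetic regression: model, priors, and operating characteristics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratescape)
```

## The model

`ratescape` studies how fast a trait evolves *relative to an allometric
expectation*. The running example is testes mass across vertebrates: after
log10-transforming both masses, testes mass is regressed on body mass in a
phylogenetic GLS,

$$ y = X\beta + \varepsilon, \qquad
   \varepsilon \sim \mathcal{N}\!\big(0,\; \sigma_b^2\, V(T_r)\big), $$

where $V(T)$ is the Brownian-motion covariance of tree $T$ (entry $(i,j)$ =
shared root-to-MRCA path length) and $\sigma_b^2$ is the *background rate* of
residual evolution (units: squared log10-grams per unit branch length, e.g.
per Myr). The design matrix $X$ can hold continuous covariates, categorical
factors with treatment coding, and interactions, so the same engine fits the
bivariate allometry, per-class slopes (`testes ~ body * class`), and the
trends models described below.

Rate heterogeneity enters through per-branch scalars $r_i \ge 0$: branch $i$'s
time length $\ell_i$ is replaced by $\ell_i r_i$, giving the *rate-scaled*
tree $T_r$. A branch with $r > 1$ has experienced more residual trait change
than its duration predicts — the signature of rapid adaptive change; $r < 1$
marks decelerated evolution. The *optimized rate* of a branch is
$\sigma_v^2 = \sigma_b^2 r$.

### Two kinds of rate shift, two kinds of scalar parameter

A scalar configuration must be able to express the two biological patterns
the method is meant to find:

* a **one-off burst** confined to a single branch (for example, a lineage
  whose allometric intercept changed — see "mean shifts" below); and
* an **inherited shift**, where a clade's ancestor moved to a new rate and
  every descendant kept it — a radiation of trait diversity.

The sampler therefore places two potential scalar *sites* on every branch: a
branch-local scalar multiplying only that branch, and a clade scalar
multiplying the branch and all of its descendants as a single parameter. A
branch's effective $r$ is its local scalar times the product of all clade
scalars anchored on its root-ward path. One activated clade scalar is enough
to represent a whole inherited shift; representing the same pattern with
independent branch-local scalars would require activating every branch of
the clade simultaneously, which the sparsity prior (below) correctly
penalizes into invisibility. Early versions of this package used
branch-local scalars only and could not recover planted clade shifts for
exactly that reason; the clade site is what makes heritable-shift detection
work, and it mirrors how the established implementations of this model
family parameterize whole-subtree shifts.

All posterior output (`run_chain()`) exposes the per-branch *effective*
scalars, so downstream summaries never need to know where anchors sat.

## Priors and their defaults

| Parameter | Prior | Default | Why |
|---|---|---|---|
| site activation | Bernoulli($p_a$) per site | $p_a = 0.025$ | with two sites per branch, ~5% of branches carry a scalar a priori: rate shifts are rare events |
| active $\log r$ | Normal($0, \tau^2$) | $\tau = 1$ | centred on "no deviation", an 8-fold shift sits ~2 sd out |
| $\sigma_b^2$ | half-Cauchy(scale) | scale = 1 | heavy-tailed, weakly informative on the variance scale |
| $\beta_j$ | Normal($0, s^2$) | $s = 10$ | effectively flat on the log10 scale, but *proper* — stepping-stone sampling integrates from the prior, so every prior must be proper |

Inactive sites have $r \equiv 1$ exactly. This makes posterior statements
like "$r > 1$ in more than 50% of samples" directly countable, with no
density estimation.

The likelihood is invariant under $(r \to c\,r,\ \sigma_b^2 \to
\sigma_b^2/c)$; identifiability comes from the prior alone (sparse
activation anchors most branches at $r = 1$). The test suite checks this
invariance at machine precision.

## The sampler

Each MCMC sweep performs:

1. Gaussian random walks on each $\beta_j$ (step 2.4× the GLS standard error);
2. a multiplicative random walk on $\sigma_b^2$ (O(1) given the cached
   likelihood factorization);
3. reversible-jump birth/death moves over the $2E$ scalar sites. Births draw
   $r^\ast$ from its prior, so prior and proposal densities cancel and the
   acceptance ratio is the (tempered) likelihood ratio times the prior odds
   $p_a/(1-p_a)$;
4. multiplicative random walks on active scalars; and
5. a *mass-transfer* move between nested active clade scalars: anchoring is
   only weakly identified ("shift at the stem" vs. "split between stem and a
   subclade" fit almost equally), leaving plain birth/death walks stuck on
   the ridge $r_a \cdot r_d \approx$ const. The transfer move proposes
   $\log r_a \mathrel{+}= \delta$, $\log r_d \mathrel{-}= \delta$ — symmetric,
   unit Jacobian — and lets the prior's preference for a single anchor
   resolve the ambiguity.

The Brownian likelihood is evaluated in $O(n)$ per proposal by Felsenstein's
pruning algorithm on the residuals (compiled code), factorized into $n-1$
contrast terms plus a root term; the dense multivariate-normal density is
kept in the test suite as an independent oracle. Chains are deterministic
given a seed. Effective sample sizes use Geyer's initial monotone sequence
estimator; `run_chain()` warns when any falls below 500, the conventional
adequacy bar for this model family. Desk-scale default settings are 200k
sweeps, 50k burn-in, thinning 20; `vr_settings(production = TRUE)` scales
these tenfold for real analyses.

## Marginal likelihoods and Bayes factors

Rate heterogeneity is assessed by comparing the variable-rates model (m1)
with the single-rate model (m0, scalar moves disabled) via stepping-stone
sampling. Powers are the $i/K$ quantiles of Beta(0.4, 1) — concentrated near
the prior, where the integrand changes fastest — with tempered chains warm-
started stone to stone and each transition estimated by a log-sum-exp
stabilized mean. The estimator itself is validated against a conjugate
normal–normal model with a closed-form marginal.

The Bayes factor is reported as $\mathrm{BF} = 2(\log m_1 - \log m_0)$,
oriented so positive values support rate heterogeneity, with the usual
reading of BF > 10 as very strong support. The literature sometimes prints
this statistic with a leading minus sign while still reporting large
positive values as support for the richer model; this package documents and
uses the orientation consistent with that reading, and both conventions are
a sign flip apart.

## Posterior summaries and shift classification

* A branch is classified a rate **increase** when $r > 1$ in *more than* 50%
  of samples, a **decrease** when $r < 1$ in more than 50%, otherwise
  **background**. Ties at exactly 50% are background: the inequalities are
  strict.
* A **heritable rate shift** is a clade satisfying, per posterior iteration
  on $\sigma_v^2$ (within an iteration $\sigma_b^2$ is common, so the
  comparisons reduce to $r$): (1) the stem differs from its ancestor branch
  in >50% of iterations, in the direction of the stem's own classification,
  and (2) no branch inside the clade differs from the stem in >50% of
  iterations — the clade inherits the new rate. Clades of ≥10 tips are
  *heritable*; 2–9 tips *incipient*; single tips *single-species*. Where a
  clade and a subclade both qualify in the same direction, the largest clade
  wins. Branches attached to the root have no ancestor and are skipped.
* A stem that deviates while every branch of its clade stays at background
  fails criterion (2) in a diagnostic way: the rate change is not inherited.
  These anchors are reported as **mean-shift candidates** — the signature of
  an intercept change in the allometry masquerading as a rate increase —
  and `flag_mean_shift()` confirms them by refitting the regression on the
  original time tree with a clade-membership intercept dummy (likelihood-
  ratio test at 0.05). This is a deliberately simple post-hoc diagnostic,
  not a full mean-shift model.
* **Path-wise rates** sum the rate-scaled branch lengths from root to tip,
  per posterior draw; per-tip summaries (median, mean, mode) are taken over
  the posterior of per-draw sums — *not* path sums over a summary tree,
  which would be a different (and not generally equal) quantity.
* The **median rate-scaled tree** multiplies each branch by its posterior
  median scalar; the trends analyses run on it.

## Trends analyses

For one taxonomic group at a time, the trends model is

`testes ~ body + mating + pathrate + mating:pathrate`

fitted by ML phylogenetic GLS on the median rate-scaled tree, with monogamy
as the reference level. Per-category slopes of trait on path-wise rate come
from the interaction coefficients; their p-values are Bonferroni-adjusted
with m = the number of mating-system categories fitted in the group.
Following the ten-data-points-per-parameter rule, categories with fewer than
20 species are merged per configuration (e.g. monogamy + polygyny where both
are sparse) or excluded with an explicit record. When no category's adjusted
slope is significant at 0.05, the fallback intercept model
`testes ~ body + mating` is fitted and tested against `testes ~ body` by a
likelihood-ratio (D) test with df = levels − 1, with pairwise intercept
contrasts signed so that a positive value means the second system has the
larger average relative trait mass. The pipeline records which branch was
taken; the adjusted p-value governs the fallback (the raw-p variant is
recorded alongside).

GLS point estimates use the ML variance $\hat\sigma^2 = \mathrm{RSS}_V/n$
(required for likelihood-ratio and marginal-likelihood comparisons), while
standard errors and t-tests use the unbiased $\mathrm{RSS}_V/(n-p)$ with
$n-p$ degrees of freedom — the convention of standard GLS software. $r^2$ is
defined as $1 - \mathrm{RSS}/\mathrm{TSS}$ in the whitened space, with TSS
from the intercept-only GLS fit on the same covariance. No additional
covariance transform (such as Pagel's λ) is applied anywhere: the rate-
scaled tree is the device that absorbs rate heterogeneity.

## The synthetic test bed

`sim_config()` / `simulate_dataset()` generate data with exactly the
structure the analysis assumes: a birth–death tree conditioned on the tip
count (default 100 tips, pure birth); body mass evolving by Brownian motion
on the same tree (so the predictor carries realistic phylogenetic signal;
an i.i.d. option exists for oracle tests); a response linear in body mass
per class (default slope 0.67, intercept −2 on the log10 scale) with
Brownian residuals at background rate 0.05; planted variance shifts
(a clade — the MRCA of the anchor tips — whose stem and descendants are all
multiplied by a common factor); planted mean shifts (an intercept offset for
a clade, no branch-length change); mating systems assigned multinomially
within class (optionally in clade-contiguous blocks); and planted
directional trends, where the response of one mating-system category is
shifted by `coef ×` (centered true path-wise rate). Everything is
byte-deterministic in the config seed.

What the generator does **not** emulate: measurement error, within-species
variance, non-Brownian trait models (OU, early burst), fossil/extinct
sampling, and real taxonomic covariance between mating system and
phylogeny. Passing tests therefore demonstrate correctness of the machinery
under its own assumptions, not robustness to their violation.

## Numerical choices and degenerate inputs

* Zero-length terminal branches are allowed but warned about (they carry
  zero residual variance and zero path-wise rate); sibling tips that are
  *both* at zero make the covariance singular and error out. Negative branch
  lengths are a hard error; missing branch lengths are never defaulted.
* Polytomies are accepted as-is — the GLS covariance and the pruning
  algorithm handle them naturally.
* Pruning a tree to the species with data preserves every retained tip's
  root-to-tip path length: the basal path removed by pruning is kept as a
  root edge and counted as shared ancestry in the covariance.
* Species matching is exact after whitespace→underscore normalization and
  case folding; no fuzzy matching.
* Constant path-wise rates (no rate heterogeneity) make the trend slope
  inestimable; the trends code refuses with a clear message rather than
  returning a rank-deficient fit.
* `Px` is the fraction of draws on the minority side of zero (exact zeros
  count toward crossing, values capped at 0.5); `Pxdiff` is the `Px` of
  per-iteration differences, with the all-zero case fixed at 0.5 and
  flagged degenerate.

## Operating characteristics and known limitations

The test suite measures the pipeline's operating characteristics on the
synthetic test bed (problem sizes chosen to keep the default suite quick:
100-tip trees and 50k-sweep chains for detection runs; 50-tip trees, 15
stones × 3k sweeps for model comparison; 80-tip groups for trends; the
conjugate toy and all oracle checks at 5–30 tips):

* On homogeneous-rate data the false-heritable-shift rate is at or near
  zero, and Bayes factors stay below the "positive support" band.
* A planted 8-fold shift on a 10-tip clade in a 100-tip tree is decisively
  supported by Bayes factors, but certifying it as a *heritable* shift
  succeeds in roughly half of realizations. The reason is a power ceiling of
  the strict classification criteria at this clade size, not sampler
  failure: chains initialized at the planted truth abandon it on the
  failing datasets, because the finite residual draws distribute the
  shift's information unevenly — sometimes concentrating it in a subclade
  (reported as incipient), sometimes carrying essentially no excess
  variance. Users should read heritable-shift counts as conservative:
  certification requires the whole clade to testify uniformly.
* Planted directional trends of −0.5 per unit path-wise rate in an 80-tip
  group are recovered with adjusted p < 0.05 in well over 80% of runs, with
  the per-category slope test calibrated near its nominal 5% level under
  the null.

* Path-wise rates estimated from the posterior are a noisy, shrunken
  version of the generative ones (branches whose shifts are not certified
  keep median scalars near 1). Used as a regressor in the trends models,
  this attenuates trend slopes toward zero — classical regression dilution —
  so end-to-end trend estimates are conservative relative to trends fitted
  on the true path-wise rates. The trends module's own calibration and
  power are therefore measured against the generator's true rates.

A further limitation: anchor placement of a detected shift is identified
only up to branches whose rearrangement the likelihood cannot distinguish
(in particular a stem and its immediate children when subtending branch
lengths are short), and the reported clade may be one or two tips larger or
smaller than the generative truth.
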