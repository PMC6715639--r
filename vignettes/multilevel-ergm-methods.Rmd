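---
title: "Multilevel ERGMs for collaboration over causal loop diagrams: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel ERGMs for collaboration over causal loop diagrams: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The modelling problem

Community-based systems interventions are steered by committees of local
leaders. Two structures carry much of the intervention's machinery: the
collaboration network among committee members, and the causal loop
diagram (CLD) the committee builds to map the drivers of the problem and
on which members locate their actions. Analysing either alone discards
the interplay between them; this package models them jointly.

The data are one multilevel network per community:

* `A` (`n_A x n_A`, directed, binary, zero diagonal) — collaboration
  nominations among the committee members who responded to the survey;
* `B` (`n_B x n_B`, directed, binary, zero diagonal) — the CLD, an arc
  meaning a direct causal effect between drivers;
* `X` (`n_A x n_B`, binary) — action ties from members to CLD
  variables. Each member–variable pair carries a single tie variable
  (the layer is non-directed);
* `Y` — categorical member attributes: organisation type, education
  level, gender.

`B` and `Y` are *exogenous*: the model conditions on them and explains
`(A, X)`. The probability model is the multilevel exponential random
graph model

$$P_\theta(A=a, X=x \mid B=b, Y=y) \;=\; \frac{1}{\kappa(\theta)}
\exp\Big(\sum_Q \theta_Q\, z_Q(a, x, b, y)\Big),$$

with one statistic `z_Q` per configuration type `Q` and `kappa` summing
over all `2^(n_A(n_A-1) + n_A n_B)` joint states. Ties are conditionally
dependent: the probability of a tie depends on the surrounding ties, as
configured by the chosen statistics.

## The statistic catalogue

`effect_catalogue()` registers 23 effects. Within `A`: arc count
(Density), mutual dyads (Reciprocity), in-two-stars (In2Star),
alternating in- and out-stars (AinS, AoutS), the in/out-degree
correlation statistic (AinAoutS), alternating transitive and cyclic
closure (ATT, ACT), and homophily counts on education and organisation
type (Edu_Match, Org_Match). On `X`: the tie count (DensityX),
alternating member-side and variable-side stars (ASA, ASB), and the
alternating shared-choice statistic over member pairs (ACA). Cross
level: the activity interaction ATXAX, the CLD-degree interactions
In2StarBX and Out2StarBX, the cross-level triangle TXBX, the three-paths
L3XBXreciprocity and L3AXBin, and the four-cycles C4AXBentrainment,
C4AXBexchange and C4AXBreciprocity.

With $r = 1 - 1/\lambda$ and degrees taken in the relevant layer, the
closed forms are, for example:

* $\mathrm{AinS}(\lambda) = \lambda^2 \sum_j \big[r^{d^{in}_j} - 1 +
  d^{in}_j/\lambda\big]$, and AoutS, ASA, ASB analogously on the other
  degree sequences;
* $\mathrm{AinAoutS}(\lambda) = \lambda^2 \sum_i
  \big(1 - r^{d^{in}_i}\big)\big(1 - r^{d^{out}_i}\big)$, and ATXAX the
  same on out-degree and action-degree;
* $\mathrm{ATT}(\lambda) = \lambda \sum_{i \ne j} a_{ij}
  \big(1 - r^{P_{ij}}\big)$ with $P_{ij} = \sum_k a_{ik} a_{kj}$, and
  ACT with the cyclic path count $\sum_k a_{jk} a_{ki}$;
* $\mathrm{ACA}(\lambda) = \lambda \sum_{i < j}
  \big(1 - r^{s_{ij}}\big)$ with $s_{ij}$ the number of variables
  chosen by both members;
* $\mathrm{TXBX} = \sum_i \sum_{u \ne v} x_{iu} x_{iv} b_{uv}$;
  $\mathrm{L3AXBin} = \sum_{i,v} d^{in}_A(i)\, x_{iv}\, d^{in}_B(v)$;
  $\mathrm{C4AXBentrainment} = \sum_{i \ne j} \sum_{u \ne v}
  a_{ij} x_{iu} x_{jv} b_{uv}$, exchange with $b_{vu}$, and reciprocity
  with $a_{ij} a_{ji} b_{uv} b_{vu}$.

Design choices that were genuinely open, and how they were fixed:

* **Explicit forms for pictorially defined effects.** AinAoutS, ATXAX,
  ACA, L3XBXreciprocity and the C4 family circulate mainly as diagrams.
  The formulas above were chosen so that each statistic (a) counts its
  minimal pictured configuration as exactly 1 and (b) matches the
  verbal reading of the effect — e.g. entrainment joins a collaboration
  arc to action targets that are CLD-adjacent in the direction of the
  arc. They are declared forms of this package, not confirmed clones of
  any other implementation's internals.
* **Ordered-tuple counting, no symmetry division.** Every directed B
  arc is counted once, so a reciprocated CLD dyad under one member
  contributes 2 to TXBX; C4AXBreciprocity counts each closed cycle from
  both member orderings. The convention is fixed, documented, and
  enforced identically in the closed forms, the change statistics and
  the brute-force oracle.
* **ACA is anchored on member pairs** (pairs of members sharing chosen
  variables), the reading that matches "variables chosen by sets of
  common committee members"; a variable-pair anchoring would be ASB-like
  redundancy.
* **Missing attributes never match.** An `NA` in `Y` contributes no
  homophily count — conservative for Edu_Match and Org_Match.
* **`lambda = 2` for all alternating statistics**, the long-standing
  default in ERGM practice; configurable per spec (`config_spec("AinS",
  lambda = 3)`), with `lambda > 1` required.

Three independent routes compute every statistic: vectorised closed
forms in R (`evaluate_statistics`), local change statistics in C++
(`change_statistics`, also driving the sampler), and a subset-enumeration
oracle (`brute_force_count`) that evaluates alternating statistics as
the alternating sum $\sum_k (-1)^k S_k / \lambda^{k-2}$ over raw
k-configuration counts. The suite verifies all three agree to 1e-9 on
random networks, which is the package's main defence against formula
errors.

## Simulation

`mcmc_sample` runs a single Metropolis tie-toggle chain over the free
tie variables of `(A, X)`; `B` and `Y` are never touched. A proposal
picks one tie variable uniformly at random — by default the A/X split
equals the proportion of A tie variables among all free tie variables,
so the joint space is sampled uniformly — and the toggle is accepted
with probability $\min(1, \exp(\theta \cdot \Delta z))$. Statistics are
tracked incrementally through the change statistics. Layers that carry
no modelled effect are held fixed rather than drifting as pure noise.
Chains are reproducible from `set.seed()`; the default burn-in (1e5
updates) and thinning interval (1e4) correspond to the study-scale
convention of 5000 graphs per 5e7 updates, and tests use sweep-scaled
values instead.

`exact_enumeration_moments` computes `kappa` and exact expected
statistics by summing over every joint state (up to 20 tie variables).
It exists as the sampler's independent oracle: sampled means are checked
against exact moments on the 64-graph directed-triad space and a
4096-state joint `(A, X)` space.

## Estimation

`fit_mergm` implements Robbins–Monro stochastic approximation of the
MCMC maximum-likelihood estimate, with the standard three phases plus a
refinement:

1. **Phase 1** simulates at the initial parameters (density effects
   start at the logit of the observed layer densities, everything else
   at 0) and estimates each statistic's variance for diagonal scaling.
   Diagonal scaling was preferred over a full Newton matrix here for
   robustness at small samples.
2. **Phase 2** runs `subphases` (default 5) blocks of
   `iter_per_subphase` (default 100) iterations
   $\theta \leftarrow \theta - a\,(z_{sim} - z_{obs})/\mathrm{diag}(D)$,
   halving the gain `a` (initial 0.1) at each block and averaging the
   final block's iterates.
3. **Newton polish.** Robbins–Monro alone leaves the estimate a few
   hundredths of a simulated SD away from the MLE, which is visible in
   goodness-of-fit t-ratios. Up to `polish_max` (default 8) damped
   Newton steps $\theta \leftarrow \theta - \tfrac12
   \Sigma^{-1}(\bar z_{sim} - z_{obs})$ are taken, each from a fresh
   phase-3-sized sample, until all convergence t-ratios fall below
   `polish_tol` (default 0.04).
4. **Phase 3** draws `phase3_n` (default 1000) thinned samples at the
   estimate. Convergence t-ratios are $(\bar z_{sim,Q} - z_{obs,Q}) /
   \mathrm{sd}(z_{sim,Q})$; standard errors are
   $\sqrt{[\hat\Sigma^{-1}]_{QQ}}$ with $\hat\Sigma$ the sampled
   statistic covariance (the estimated Fisher information of an
   exponential family).

A parameter is starred significant when `|estimate/se| > 2`
(`classify_significance`), and `check_convergence` applies the
`|t| < 0.1` rule per effect. Degenerate trajectories (a layer simulating
all-empty or all-full throughout a phase) and singular statistic
covariances (collinear effects) are reported as errors naming the
offending layer or statistics rather than returning numbers; effects
with zero observed count and zero simulated variance surface the same
way instead of being dropped silently. `refits` (default 1) restarts
phase 2 from the current estimate while the convergence check fails.

The estimator's accuracy is validated two ways: the density-only model,
whose MLE is the logit of the observed density in closed form, and a
100-replicate recovery study at (Density −2.0, Reciprocity 1.5) on
20-member networks checking bias against Monte Carlo error and 2-SE
coverage against its binomial band.

## Goodness of fit

`run_gof` simulates `n_graphs` networks at the estimate (defaults 5000
graphs spaced over 5e7 updates, scaled down in tests) and reports GOF
t-ratios for the fitted effects plus an auxiliary battery — by default
the remaining catalogue plus the in/out-degree standard deviations and
directed clustering of `A`. Thresholds follow ERGM practice: fitted
effects should sit at `|t| < 0.1` (the estimate must reproduce what it
fitted), auxiliary statistics at `|t| < 2` (the model should not be
contradicted by features it did not fit). A simulated SD of zero with a
non-zero deviation is reported as an infinite t-ratio and flagged
inadequate. Model selection itself — growing a specification until the
auxiliary battery is adequate — is exercised manually through these
tools, not automated.

## The synthetic generator

The study's survey data are not public, so the generator stands in for
them in every test and experiment. A `community_profile` fixes what the
data would have fixed: committee size and respondents (18 or 20 of 27
invited in the two presets), CLD size (58 and 64), target mean
collaboration out-degree (7.1, 6.0), target mean actions per member
(5.4, 10.7), and attribute category probabilities at the published
frequencies. `generate_cld` grows a directed graph with a preferential
attachment bias (`hub_bias`, default 1) on arc targets, because the
cross-level statistics (L3AXBin especially) are only exercised when some
variables are genuinely central; `hub_bias = 0` reduces to an
Erdős–Rényi draw, which the tests use as the variance baseline. The
default CLD arc density (0.03) keeps the expected arc count near 1.7
per variable, the sparse regime typical of hand-built CLDs.

`generate_community` draws `(A, X)` by MCMC from a declared true
parameter vector (default: densities plus Reciprocity 1), after
calibrating the two density parameters by coordinate bisection. The
calibration drives the *chain mean* to within half the tolerance of the
degree targets, then accepts a final draw only if the realized network
itself lands within the tolerance (15% by default) — calibrating to the
full tolerance and drawing once would let single-network sampling noise
push realized networks outside the band. Bisection is justified by the
monotonicity of expected density in the density parameter, which the
suite checks empirically over the bracket.

What the generator does *not* emulate: real CLD loop structure (only
degree heterogeneity and connectivity), true attribute–tie dependence
(attributes are drawn independently of ties unless match effects are put
into the generating model), and non-response patterns (profiles generate
respondents directly). Passing tests therefore demonstrate that the
machinery recovers known truth at the study's scale, not that any
substantive estimate from the original communities is reproduced —
those networks are not available, and their published estimates are not
targets of this package.

## Scale choices and limitations

Test and experiment sizes were chosen so the whole suite exercises every
claim at desk scale: oracle comparisons at `n_A, n_B <= 6` (where
exhaustive enumeration is exact and fast), sampler validation on 64- and
4096-state spaces, recovery at `n_A = 20` with 100 replicates, and GOF
experiments at `n_A = 12` with 500 graphs per run. The estimator and
sampler themselves run comfortably at the full study scale (27 members,
64 variables, 19 effects).

Known limitations: `lambda` is fixed, not estimated (no curved-ERGM
machinery); ties are binary and unsigned, so CLD polarity is collapsed
on input; a single chain is used (multiple chains are a harness
concern); and near-degenerate specifications are reported, not rescued.
The two bundled presets `community1_effects()` (17 effects) and
`community2_effects()` (19) reflect the effect sets of the two
community-style model specifications; where the available record is
ambiguous about which single-community effects belong to which model,
the split adopted here keeps the B–X star interactions with the first
preset and the remaining interaction effects with the second. The
pipeline's interface is the exported functions plus the thin
`inst/scripts/run-study.R` wrapper; an elaborate subcommand CLI would
duplicate `run_study` without adding control.
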