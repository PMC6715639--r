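# mergm

Multilevel exponential random graph models (MERGMs) for community
steering-committee collaboration networks embedded in causal loop
diagrams (CLDs).

Community-based systems interventions — for example whole-of-community
childhood obesity prevention — are typically led by a steering committee
of local leaders, who map the drivers of the problem as a causal loop
diagram and then assign themselves actions on parts of that map. This
package models the joint structure of three linked layers:

* **A** — the directed collaboration (nomination) network among the
  `n_A` committee members: `A_ij = 1` if member *i* named *j* as a
  regular collaborator;
* **B** — the directed CLD among `n_B` system variables: `B_uv = 1` if
  variable *u* was mapped as a direct cause of *v* (held exogenous);
* **X** — the bipartite "action" network: `X_iv = 1` if member *i*
  reports working to improve CLD variable *v* (non-directed, one tie
  variable per member–variable pair);

together with an exogenous categorical attribute table **Y** per member
(organisation type, education level, gender).

The model is

```
P_theta(A = a, X = x | B = b, Y = y) = (1/kappa) exp( sum_Q theta_Q z_Q(a, x, b, y) )
```

where each `z_Q` counts (or geometrically smooths) a small configuration
— reciprocated dyads, alternating in/out-stars (AinS, AoutS),
alternating transitive and cyclic closure (ATT, ACT), attribute
homophily, bipartite activity stars (ASA, ASB), and cross-level
triangles, three-paths and four-cycles (TXBX, L3AXBin,
C4AXBentrainment/exchange/reciprocity) — and `kappa` normalizes over the
whole graph space. Because `kappa` is intractable, estimation uses
Robbins–Monro stochastic-approximation MCMC maximum likelihood with a
Metropolis tie-toggle sampler, followed by simulation-based
goodness-of-fit t-ratios. An effect is starred as significant when
`|estimate / se| > 2`.

The package provides:

* the validated three-layer data model with tab-delimited edge-list and
  CSV attribute I/O (`multilevel_network`, `read_multilevel`,
  `write_multilevel`, `restrict_to_respondents`,
  `descriptive_summary`);
* the full 23-effect statistic catalogue with closed-form evaluation,
  exact change statistics (Rcpp), and a brute-force enumeration oracle
  (`evaluate_statistics`, `change_statistics`, `brute_force_count`);
* Metropolis MCMC simulation and an exact-enumeration oracle for tiny
  graph spaces (`mcmc_sample`, `exact_enumeration_moments`);
* Robbins–Monro estimation with convergence diagnostics and the
  significance rule (`fit_mergm`, `check_convergence`,
  `classify_significance`);
* simulation-based GOF over fitted and auxiliary statistics
  (`run_gof`);
* a synthetic community generator calibrated to the two study
  communities' published scale, plus a parameter-recovery harness
  (`generate_community`, `community1_profile`, `recovery_experiment`);
* an end-to-end pipeline (`run_study`) and model presets
  (`community1_effects`, `community2_effects`).

## Worked example

Generate a synthetic community at the scale of study Community 1
(18 respondents of 27 invited, a 58-variable CLD, mean out-degree 7.1,
mean actions 5.4), fit a small model, and test its fit:

```r
library(mergm)

net <- generate_community(community1_profile(seed = 11))
descriptive_summary(net, invited = 27)
#> Respondents: 18 of 27 invited (67%)
#> Collaboration out-degree: mean 7.4 (min 3, max 10)
#> Actions per member: mean 4.7 (min 1, max 8)
#> CLD variables: 58
#> ...

fit <- fit_mergm(net,
                 spec_list(c("Density", "Reciprocity", "DensityX",
                             "ASA", "TXBX")),
                 estimation_settings(seed = 11))
fit
#> Multilevel ERGM fit (converged)
#> Effect                    Est.  Std.Err.       t
#> Density                 -0.841     0.188  -0.017 *
#> Reciprocity              1.293     0.342  -0.032 *
#> DensityX                -1.931     1.495  -0.004
#> ASA                     -0.225     0.823   0.003
#> TXBX                    -0.411     0.338  -0.034
```

The generating model included `Reciprocity = 1`: the fit recovers a
significant positive reciprocity effect (estimate 1.29, SE 0.34,
ratio > 2), while the effects not present in the generator stay
non-significant. The `t` column holds convergence t-ratios (simulated
mean minus observed, in simulated SDs); values near zero mean the
estimate reproduces the observed statistics.

```r
run_gof(net, fit, auxiliary = spec_list(c("In2Star", "ATT")),
        n_graphs = 500, total_updates = 5e5)
#>       statistic      role observed sim_mean sim_sd tratio adequate
#>         Density    fitted  134.000  134.960  9.735 -0.099     TRUE
#>     Reciprocity    fitted   41.000   41.196  5.455 -0.036     TRUE
#>        DensityX    fitted   84.000   84.590  8.355 -0.071     TRUE
#>             ASA    fitted  101.797 102.924  15.370 -0.073     TRUE
#>            TXBX    fitted    8.000    8.056   3.216 -0.017     TRUE
#>         In2Star auxiliary  461.000 475.678  68.880 -0.213     TRUE
#>             ATT auxiliary  214.938 217.617  29.080 -0.092     TRUE
#>   SD_indegree_A auxiliary    1.854    1.993   0.312 -0.445     TRUE
#>  SD_outdegree_A auxiliary    1.822    2.025   0.334 -0.607     TRUE
#>    Clustering_A auxiliary    0.434    0.437   0.036 -0.094     TRUE
```

Fitted effects are adequate at `|t| < 0.1`, auxiliary statistics at
`|t| < 2`. `run_study(run_config(profile = community1_profile(seed = 1),
out_dir = "out", seed = 1))` runs the whole workflow and writes
descriptives, the estimates table with significance stars, the GOF
table, a machine-readable `results.json` and a log.

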