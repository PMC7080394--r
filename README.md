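# panelcausal

Estimators of the average treatment effect on the treated (ATT) for
**controlled pre-post panel designs**: a balanced panel of units (hospitals,
regions, providers) observed before and after a subset of them adopts a
policy at a common date. Typical users are health-economics and
policy-evaluation analysts comparing estimation strategies when the
parallel-trends assumption is in doubt, effects may be heterogeneous, or
few pre-treatment periods are available.

All four estimators are built on the linear factor model for the untreated
potential outcome,

    Y_it = X_it' b + lambda_t' mu_i + D_it tau_it + eps_it,

with unit loadings `mu_i`, time factors `lambda_t`, covariates `X_it`, and
block exposure `D_it = D_i * 1[t > t']`. The estimand is
`ATT = E[tau_it | D_it = 1]` over post periods.

| Method | Function | Counterfactual | Inference |
|---|---|---|---|
| Difference-in-differences | `fit_did()` | additive two-way fixed effects (parallel trends) | CR1 cluster-robust |
| Synthetic control | `estimate_sc_att()` | convex donor weights matched on all pre-period outcomes | in-space placebo tests |
| Interactive fixed effects | `estimate_ife_att()` | factor model on all units, homogeneous tau, iterative principal components | CR1 cluster-robust |
| Generalized synthetic control | `estimate_gsc_att()` | factor model on controls only + per-unit loading projection | parametric bootstrap |

A Monte Carlo harness (`scenario_config()`, `generate_panel()`,
`run_study()`) benchmarks the estimators under parallel/nonparallel trends,
homogeneous/heterogeneous effects, convex-hull violations, and
treated-only post-period shocks, with a known per-replicate truth. A
`parallel_trends_test()` pre-trends diagnostic is included.

## Worked example

Generate one benchmark panel with diverging group trends (scenario B:
treated units trend upward faster than controls; true ATT = 1) and compare
DiD with GSC:

```r
library(panelcausal)

cfg <- scenario_config("B", "homogeneous", T_pre = 18)
sim <- generate_panel(cfg, rep_seed = 1)

fit_did(sim$panel)
#> Difference-in-differences ATT estimate
#>   ATT: 7.046  (se 0.4494)
#>   95% CI: [6.155, 7.936]
#>   p-value: < 2.2e-16 (cluster_robust)
#>   per-period effects: 7.046 7.046 7.046 7.046

estimate_gsc_att(sim$panel, inference = "bootstrap", B = 500, seed = 1)
#> Generalized synthetic control ATT estimate
#>   ATT: 1.435  (se 0.3499)
#>   95% CI: [0.7486, 2.12]
#>   p-value: 4.144e-05 (bootstrap)
#>   per-period effects: 1.422 1.076 2.140 1.101
```

DiD is badly biased (7.05 against a true effect of 1) because the groups'
untreated outcome paths diverge — exactly the failure its parallel-trends
assumption warns about; the pre-trends test rejects overwhelmingly
(`parallel_trends_test(sim$panel)$p_value` is about 4e-19). GSC models the
diverging trends with an interactive factor (cross-validation selects one
factor on this panel) and estimates 1.44 with a bootstrap interval that
covers the truth; averaged over replications its error is two orders of
magnitude below DiD's on this design.

Long-format CSV panels are read with `load_panel(path, mapping)`; a thin
command-line front end over the same functions lives at
`inst/cli/panelcausal.R` (subcommands `estimate`, `simulate`, `compare`).

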