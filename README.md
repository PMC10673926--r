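# indilife

Tools for quantifying **individuality** — consistent among-individual
differences — in behavior, growth, and reproduction from longitudinal
experiments on clonal fish reared in near-identical environments (the
Amazon molly, *Poecilia formosa*, is the motivating system). The package
covers the full analysis chain:

1. **Trajectory metrics** — daily activity (cm/s, total path length over
   valid elapsed time) and daily feeding time (minutes inside a fixed
   5 × 13 cm zone around a stationary food patch) from 0.2-s position
   series.
2. **Repeatability** — random-intercept linear mixed models fitted by
   profiled REML (written from the ground up and cross-checked against
   `lme4`), with `R = V_ID / (V_ID + V_res)` and 95% confidence intervals
   from 1000 parametric model simulations. Raw (intercept-only) and
   adjusted (covariate-conditioned) repeatabilities for activity, feeding,
   brood size, and offspring size.
3. **Growth** — individual von Bertalanffy curves
   `L(t) = Linf (1 − exp(−K (t − t0)))` by Levenberg–Marquardt least
   squares, with predicted sizes used for all size-at-parturition
   covariates and the negative K–Linf relationship.
4. **Reproduction** — onset, brood sizes, offspring lengths, cumulative
   output, and the offspring size–number trade-off estimated while
   controlling for onset, female size, and descent.
5. **Linkage** — stepwise-backward likelihood-ratio model selection across
   the behavior → growth → reproduction chain, with protected covariates
   (mother identity; size at parturition where mandated) and partial R².

A configurable **synthetic cohort generator** (`sim_config()`,
`simulate_study()`) reproduces the statistical structure of such an
experiment — latent individual effects, correlated daily behavior, growth
tied to feeding, broods at ~30-day gestation intervals, a negative
size–number trade-off — so the entire pipeline is testable end to end
without any external data.

## Worked example

```r
library(indilife)
cfg    <- sim_config(seed = 42)      # 34 individuals, 28 days, 280-day horizon
study  <- simulate_study(cfg)
bundle <- run_all(study, n_sim = 1000, seed = 42)
print(bundle)
```

```
<results_bundle> version 0.1.0, seed 42
Repeatabilities:
           trait     kind      R ci_low ci_high significant
1       activity      raw 0.3802 0.2407   0.483        TRUE
2       activity adjusted 0.3812 0.2476   0.492        TRUE
3        feeding      raw 0.2296 0.1371   0.319        TRUE
4        feeding adjusted 0.2243 0.1279   0.313        TRUE
5 offspring_size      raw 0.2479 0.0904   0.406        TRUE
6 offspring_size adjusted 0.2074 0.0183   0.389        TRUE
7     brood_size      raw 0.0881 0.0000   0.242       FALSE
8     brood_size adjusted 0.1584 0.0000   0.322       FALSE
Activity ~ feeding: slope -0.227 (p = 8.28e-19, marginal R2 = 0.081)
K-Linf model: coef(K) = -92.87, R2 = 0.769
```

Reading the output: activity is strongly repeatable (R = 0.38, CI
excluding 0 — individuals differ consistently in how much they move),
feeding less so; offspring size remains repeatable even after adjusting
for the trade-off, onset, body size, and mother (R = 0.21) — individual
differences in life-history productivity. Daily activity and feeding are
negatively related (−0.23 cm/s per minute of feeding: time at the
stationary patch competes with swimming), and individuals with larger
asymptotic size grow toward it more slowly (negative K coefficient).
`bundle$linkage$table` lists, per linkage model, which candidate terms
survived stepwise selection — with the default generator the
feeding → Linf → offspring-size chain is retained while direct
behavior → reproduction links are dropped.

Real datasets enter through the same tables (`read_behavior_csv()`,
`read_sizes_csv()`, `read_broods_csv()`, `read_offspring_csv()`); external
column headers can be adapted with `read_mapped_table()` and the template
in `inst/extdata/deposit_mapping_template.csv`.

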