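---
title: "Quantifying behavioral and life-history individuality in clonal fish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying behavioral and life-history individuality in clonal fish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indilife)
```

## The scientific problem

Genetically identical animals reared in near-identical environments still
develop consistent among-individual differences — in behavior, and, as this
package's pipeline is built to quantify, in traits that matter directly for
fitness: how many offspring a female produces per brood, how large those
offspring are, and when she starts reproducing. The canonical experimental
system is a clonal, live-bearing fish (the Amazon molly, *Poecilia formosa*)
separated at birth into standardized individual tanks and followed for 280
days: daily high-resolution video tracking over the first 28 days of life
(an 8-hour activity phase and a 2-hour feeding phase at 0.2-second
resolution), weekly standard-length measurements, and a complete record of
every brood and every offspring produced.

`indilife` implements the full analysis chain for such experiments —
trajectory metrics, variance-component repeatabilities with
simulation-based confidence intervals, individual growth curves,
reproductive analytics, and the linkage models connecting the three layers —
together with a synthetic cohort generator so that every stage can be
validated end to end without access to any particular dataset.

## The central quantity: repeatability

Individuality is quantified as repeatability, the intraclass correlation of
a random-intercept linear mixed model

$$y_{ij} = \mathbf{x}_{ij}^\top\beta + b_i + \varepsilon_{ij}, \qquad
  b_i \sim N(0, V_{ID}), \quad \varepsilon_{ij} \sim N(0, V_{res}),$$

$$R = \frac{V_{ID}}{V_{ID} + V_{res}}.$$

With no covariates this is the *raw* repeatability; with covariates (body
size, age, trade-off terms) it is the *adjusted* repeatability — the
consistency that remains after conditioning away variation those covariates
explain. Adjusted repeatability is not bounded by raw repeatability in
either direction: covariates can absorb among-individual variance (pushing
R down) or within-individual noise (pushing R up), and both directions
occur in practice in this pipeline.

### How the mixed model is fitted

`fit_lmm()` estimates the variance components by restricted maximum
likelihood, profiling the variance ratio $\lambda = V_{ID}/V_{res}$. For
fixed $\lambda$ the generalized-least-squares problem is closed-form; with a
single grouping factor the required inverses reduce to per-group rank-one
(Woodbury) corrections, so one likelihood evaluation costs $O(n p^2)$. The
restricted profile likelihood in $\log\lambda$ is scanned on a coarse grid
over $[-18, 12]$ and polished with Brent's method (argument tolerance
1e-10); the $\lambda = 0$ boundary is evaluated exactly and reported as
$V_{ID} = 0$ whenever the profile maximizes there (variances are never
reported negative). The test suite verifies this engine three independent
ways: against a dense-matrix brute-force grid evaluation of the restricted
likelihood, against closed-form ANOVA moment estimators on balanced
designs, and against `lme4::lmer` (which agrees to ~1e-5 in components,
coefficients, and log-likelihood).

### Confidence intervals and significance

Uncertainty in $R$ is quantified by parametric model simulation: 1000
responses are drawn from the fitted model (fixed effects + group effects +
residuals), each refitted, and the 2.5/97.5 percentile bounds
(type-7 quantiles) of the simulated $R$ distribution form the 95% interval.
Among-individual differences are called significant when the interval
excludes zero. At the study's sampling design (34 individuals × 28 daily
records) the empirical coverage of these nominal 95% intervals is ~93%
(measured in the acceptance suite over 100 replicate cohorts at 200
simulations each) — inside the 90–98% band we treat as acceptable for a
percentile-type interval at this group count.

Fixed-effect terms are tested by maximum-likelihood likelihood-ratio tests
between nested refits on the complete-case rows of the full model. The
original analyses in this field typically use Satterthwaite-type t-tests;
we chose LRTs because they are self-contained and exactly defined, at the
cost of mild anticonservatism at small group counts — a difference that
matters little at the effect sizes of interest, and one reason the package
reports estimates and intervals alongside p-values. Model selection is
stepwise-backward: the least significant removable term with $p \ge \alpha$
(default 0.05) is removed until all remaining candidates are significant.
Marginality is enforced (an interaction is always tested before the main
effects it contains), and *protected* covariates — mother identity
everywhere, female size at parturition where mandated — are never removed,
regardless of significance. Effect sizes are reported as partial $R^2$
(semi-partial $\Delta RSS/RSS_{reduced}$ for plain regressions, equal to
$t^2/(t^2+df)$ for single-df terms; the drop in Nakagawa marginal $R^2$,
floored at zero, for mixed models).

## Trajectory metrics

Two daily measures summarize each recording. *Activity* is the average
distance moved per second: total path length over consecutive valid sample
pairs divided by total valid elapsed time. *Feeding time* is the time spent
inside a fixed 5 × 13 cm rectangle around the stationary food patch: each
sample inside the zone (boundary inclusive) contributes one sampling
interval (0.2 s) of dwell.

Numerical conventions, fixed once and tested: consecutive pairs separated
by more than 3 sampling intervals are treated as recording gaps and excluded
from both distance and duration — nothing is interpolated, because
interpolation would fabricate movement; zone membership on the boundary is
inclusive; units are centimeters and seconds internally, with minutes only
at the reporting boundary. Activity is log-transformed for the
repeatability models (daily activity is strongly right-skewed); the
adjusted behavioral models condition on predicted body size, age class
(weeks 1–4 as a 4-level factor, `ceiling(day/7)`), and their interaction.

## Growth

Each individual's weekly lengths are fitted with the von Bertalanffy
growth curve

$$L(t) = L_\infty\,(1 - e^{-K (t - t_0)}),$$

by Levenberg–Marquardt nonlinear least squares. (Field papers sometimes
describe this model as "a logistic function"; it is not — the standard von
Bertalanffy form above is what is implemented.) Starting values come from
the classical linearization of $\log(1 - L/L_\infty^0)$ against age with
$L_\infty^0 = 1.05 \max L$; three deterministically perturbed restarts
guard against local minima and the best-RSS solution is kept. Flat series,
all-starts failures, and boundary solutions ($K$ at its lower bound,
$L_\infty$ far beyond the data) are flagged unconverged rather than
returned silently. All downstream size covariates — including female size
at parturition for every brood — use predicted sizes from these curves
rather than raw measurements, and individual growth is characterized by
$K$ and $L_\infty$.

## Reproduction

Reproductive profiles collect, per female: onset (age at first
parturition), the ordered broods with their sizes and parturition ages,
per-brood mean offspring length (the response used for offspring-size
models — per-offspring rows are kept for description only, so brood is the
unit of analysis), and the cumulative offspring count as a right-continuous
step function. Broods whose offspring were counted but not measured stay in
all brood-size analyses and drop only out of offspring-size models; the
package asserts this bookkeeping explicitly.

The size–number trade-off is estimated from two mixed models on per-brood
rows with individual as random intercept: mean offspring length on brood
size, onset, female size at parturition, and mother identity; and brood
size on the mirror-image set. Their variance components are the adjusted
repeatabilities of the two traits — consistent differences in
*life-history productivity* that remain after the trade-off, body size,
onset, and descent are accounted for.

## The linkage stage

Three model families connect the layers, each reduced by
stepwise-backward selection:

1. *direct*: brood size and offspring size (mixed, per-brood, with female
   size at parturition protected) and onset (plain regression) on mean
   activity and mean feeding (per-individual means over the 28 days,
   untransformed);
2. *behavior → growth*: $L_\infty$ and $K$ on mean activity and mean
   feeding ($L_\infty$ protected in the $K$ model, since larger fish
   approach their asymptote more slowly);
3. *growth → reproduction*: brood size, offspring size (with female age at
   parturition as a removable covariate) and onset on $K$ and $L_\infty$.

No multiple-testing correction is applied across models, matching
per-model reporting conventions in this literature. Individuals missing
any stage are dropped listwise with a logged manifest.

## The synthetic cohort generator

`sim_config()` defines the study conditions; `simulate_study()` draws a
complete experiment from one master seed (bit-identical under the same
seed). Each individual carries four latent effects: a log-activity
intercept and a feeding intercept (bivariate normal, correlation
`rho_act_feed`), and two productivity effects (brood size on the log
scale, offspring size in cm). The same negative activity–feeding
correlation is applied to the daily residual pair: at a stationary food
patch, roaming and feeding compete for time both between and within
individuals, which is what lets the daily activity-on-feeding mixed model
recover a negative slope.

The chain built into the generator — and the null around it — is: feeding
raises asymptotic length (`beta_feed_Linf`, cm per minute of mean daily
feeding), asymptotic length raises mean offspring length and delays onset,
and *no* reproductive quantity depends on behavior directly. Growth
coefficient and asymptotic length are negatively coupled
(`k_linf_slope`). Brood size is Poisson with a log-link on the individual
effect, female size, and log-normal over-dispersion, truncated at one;
mean offspring length carries the trade-off term
`tradeoff_slope * (brood size − mean)` with default −0.013 cm per
offspring.

Defaults were set once to the published study conditions where stated (34
individuals, 28 recording days, 280-day horizon, 0.2-s steps, 8 h + 2 h
phases, 5 × 13 cm zone, ~30-day gestation, ~4.5 broods per female, 3
mothers, optional dropout at the reported recording-loss rates) and to
field-realistic values where not: a 20 × 20 cm arena (only the zone size is
standard), newborn standard length ~0.95 cm, asymptotic length ~4.5 cm,
$K \approx 0.017$/day with $t_0 \approx -14$ d, onset ~168 days, mean brood
size 16, and variance components that put the behavioral and reproductive
repeatabilities in the published ranges (raw activity ~0.37, raw feeding
~0.18, adjusted offspring-size ~0.13, adjusted brood-size ~0.11).

Trajectories are generated by a correlated random walk (turning-angle SD
0.6 rad) with reflecting arena walls, per-step speed scaled by
$\exp(u_{act} + e_{day})$, and a two-state roam/forage switch during the
feeding phase whose stationary foraging probability increases with the
latent feeding effect on the logit scale. This movement model is
*structurally*, not quantitatively, faithful: no tank dimensions or
movement statistics are available to calibrate against, so
trajectory-level tests check structure (speed scaling, zone attraction,
recovered repeatability) rather than magnitudes. The generator therefore
validates the estimators, not the biology: passing tests show the pipeline
recovers known parameters from data with the assumed structure
(Gaussian latent effects, a single grouping factor, von Bertalanffy mean
growth), and real data can of course deviate from all of these.

The fast route `simulate_behavior()` draws the daily behavior table
directly from the latent model (exact variance components, no movement
simulation); `simulate_trajectories()` is the slow route through positions
for exercising the metrics layer. `sim_config_scaled()` shortens recording
phases and coarsens the time step so a full cohort of trajectories
simulates in seconds.

## Problem sizes used in validation

The package's own checks run at deliberately chosen sizes: REML oracle
comparisons on 20 random datasets of ≤ 35 rows (dense-matrix grid
evaluation is quadratic in *n*); repeatability recovery at the study scale
(34 × 28) with generator $R \in \{0.2, 0.4, 0.6\}$, 50 replicates each,
mean error within ±0.1; CI coverage at 100 replicate cohorts × 200
simulations; trajectory-metric oracle equivalence on 100 random tracks at
1e-9 relative tolerance; and chain-structure recovery over 50 replicate
studies, where each true link must be retained — and each direct
behavior–reproduction link dropped — in a majority of replicates.

## Known limitations

- One grouping factor only: no crossed or nested random effects, no GLMMs
  (brood size is analyzed on the Gaussian scale, as is conventional in this
  literature, despite being a count).
- LRT p-values are mildly anticonservative at 34 groups; intervals and
  estimates are the primary inferential output.
- The percentile simulation interval slightly undercovers (~93% at nominal
  95% at this design); a basic/bias-corrected variant is not implemented.
- The generator's movement model and several reproductive magnitudes are
  field-realistic choices, not measured quantities; conclusions about real
  data require the real tables (see the column-mapping adapter
  `read_mapped_table()` and the template in `inst/extdata/`).
- Male and breeding-tank identities are carried as optional columns but no
  dedicated robustness analysis is implemented.
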