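---
title: "Bias-aware meta-analysis of goal-priming field studies: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bias-aware meta-analysis of goal-priming field studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primingmeta)
```

## The scientific question

Goal-priming field experiments ask whether a subtle achievement cue — most
often a photograph of an athlete winning a race, displayed in a call centre
or classroom — improves real workplace or academic performance. The packaged
dataset (`priming_studies()`) holds the 13 published two-group field
experiments in this literature: per-group sample sizes (median 30 per cell)
and a standardized mean difference each. A naive random-effects synthesis of
these effects is moderate-to-large, but the literature is small, the studies
are small, and publication keyed to significance is plausible. The package
therefore implements a *sensitivity analysis*: run the full battery of
bias-aware estimators, and trust only the estimators whose worst-case
false-positive rate under plausible conditions stays below a threshold.

## Models and estimators

**Random-effects model.** Observed effects $y_i \sim N(\theta_i, v_i)$ with
true effects $\theta_i \sim N(\mu, \tau^2)$. $\tau^2$ is estimated by REML
(Fisher scoring on the profiled restricted likelihood, projected at
$\tau^2 \ge 0$, converged when successive values differ by $<10^{-10}$,
at most 100 iterations); $\hat\mu$ is the inverse-variance weighted mean with
weights $1/(v_i + \hat\tau^2)$ and a Wald $z$ interval. Heterogeneity is
summarized by Cochran's $Q$ (fixed-effect weights, so identical across
$\tau^2$ estimators) and by $I^2 = 100\,\hat\tau^2/(\hat\tau^2 + s^2)$ with
Higgins' typical within-study variance
$s^2 = (k-1)\sum w_i / ((\sum w_i)^2 - \sum w_i^2)$, $w_i = 1/v_i$.
DerSimonian–Laird, ML and fixed-effect variants are available;
Knapp–Hartung intervals sit behind a flag and are off by default because the
published intervals this package reproduces are $z$-based.

**Funnel regressions.** The Egger-type test fits the mixed-effects
meta-regression $y_i = \beta_0 + \beta_1 \mathrm{se}_i$ with REML $\tau^2$;
$\beta_1/\mathrm{SE}(\beta_1)$ referred to the standard normal tests the
small-study effect. PET is the same regression's intercept — the
extrapolated effect of an infinitely precise study. PEESE replaces
$\mathrm{se}_i$ by $v_i$. The conditional PET-PEESE estimator switches from
PET to PEESE when the PET intercept differs from zero at two-tailed 0.05;
this two-tailed rule is the default because it is the rule under which the
battery's published application is internally consistent (its PET-PEESE row
equals its PEESE row despite a negative PET estimate). A classical WLS
variant (`model = "wls"`) is kept for cross-checks.

**Three-parameter selection model.** Publication is modelled as certain for
studies with one-tailed (normal-scale) $p \le 0.025$ — the directional twin
of two-tailed 0.05 — and as probability $\omega$ otherwise. The weighted
likelihood normalizes each study's density by
$A_i = P(Y \ge c_i) + \omega P(Y < c_i)$ with $c_i = 1.96\,\mathrm{se}_i$
(closed-form normal CDF differences, no quadrature), and is maximized over
$(\mu, \tau^2 \ge 0, \omega \ge 0)$ by multistart quasi-Newton with a
Nelder–Mead polish. The likelihood-ratio test compares against the ML (not
REML) random-effects fit because restricted likelihoods are not comparable
across fixed-effect structures; at $\omega = 1$ the selection model reduces
to that baseline exactly. The CI for $\mu$ is Wald from the inverse observed
information — on the packaged data this reproduces the published interval,
so it is the default — with a profile-likelihood fallback when the Hessian
is not positive definite.

**Trim-and-fill.** Classical Duval–Tweedie with the $L_0$ estimator and
fixed-effect centering during trimming (average ranks on ties), then a REML
refit on observed plus mirror-imputed effects. The default side is `left`
(suppressed small negative studies), matching the funnel's appearance; an
`auto` rule picks the side with the smaller deviation rank-sum. A reference
implementation that re-centers with the model's REML fit instead of the
fixed-effect fit shifts the adjusted estimate by under 0.01 on the packaged
data; the classical centering is kept.

**p-curve and p-uniform.** Both estimate the true effect from only the
significantly positive studies via conditional probabilities
$q_i(\delta) = P(T > t_i \mid \text{significant}; \delta)$, which are
Uniform(0,1) at the true $\delta$ — and, usefully for root-finding,
monotonically *increasing* in $\delta$ (as the assumed effect grows, both
tails approach 1 and their ratio rises toward 1). p-uniform (method P) uses
the normal-approximation $q_i$ conditioned on the directional two-tailed
0.05 gate ($z_i > 1.96$) and solves the Irwin–Hall moment condition
$\sum q_i = n/2$, with CI bounds at the Irwin–Hall 0.025/0.975 quantiles
(exact alternating-series CDF up to $n = 12$, normal approximation beyond).
p-curve minimizes the Kolmogorov–Smirnov distance between the $q_i$ set and
uniformity over a 0.01 grid with golden-section refinement; both its
inclusion gate and its conditioning boundary are the one-tailed 0.05 t
threshold. The two boundaries differ in general but select the same ten
studies on the packaged data; matching each estimator's gate to its own
conditioning is what makes each unbiased in recovery simulations (a
mismatched gate leaves the $q_i$ non-uniform at the truth). The one-tailed
0.05 conditioning for p-curve is deliberate: under the textbook 0.025
boundary the packaged-data estimate drops to ~0.44, far from the published
application of this battery, so the package follows the simulation
framework's variant and exposes `crit_alpha`.

**Power.** Exact noncentral-t power for the equal-$n$ two-sample test
($\mathrm{ncp} = d\sqrt{n/2}$, $df = 2n-2$), inverted by bisection for the
detectable effect. The printed planning numbers (0.31, 0.61, $d = 0.65$ for
0.80 power) are reproduced to two decimals; the normal approximation is off
by up to 0.02 at $n = 30$, which is why the exact distribution is the
default.

## The effect-size scale

Study tables in this literature print the small-sample-corrected effect
(Hedges' $g$, usually still labelled $d$). The package's default convention
(`small_sample = "printed_g"`) treats the stored `d` column as corrected and
analyses $y_i = d_i / J_i$ with $J = 1 - 3/(4\,df - 1)$ and the standard
large-sample SMD variance $v_i = (n_1+n_2)/(n_1 n_2) + y_i^2/(2(n_1+n_2))$;
forest and funnel exports return to the printed scale with
$\mathrm{se}_g = J \cdot \mathrm{se}_y$. This convention was adopted because
it is the one under which the packaged table reproduces the published
downstream results (pooled estimate, heterogeneity, Egger $z$, PET/PEESE,
selection model, trim-and-fill, and the widest forest interval) to their
stated precision; analysing the printed values uncorrected
(`small_sample = "none"`) misses several of them by many times their
tolerance. Two residual gaps remain and are worth stating plainly: Cochran's
$Q$ computes to 30.22 against a printed 30.33, and the p-uniform lower bound
to $-0.82$ against $-0.86$. Both are artifacts of the table printing effects
to two decimals — $Q$'s sensitivity to $\pm 0.005$ input rounding is about
$\pm 0.2$, and the Irwin–Hall statistic is nearly flat in $\delta$ near the
lower bound — so no convention computable from the printed table pins them
tighter.

## What the simulator emulates — and what it does not

`simulate_literature()` generates two-group experiments with true effects
$\theta_i \sim N(\mu, \tau^2)$, unit-variance normal outcomes, per-group $n$
resampled from the packaged studies' own sizes (median 30), selective
publication keyed to directional significance (retention probability 1.0 /
0.2 / 0.05 for nonsignificant results at bias level none / medium / strong),
and three researcher-degrees-of-freedom operators: optional stopping (up to
two extra batches of 10 per group, stopping at significance), outlier
removal (up to three observations beyond 2 SD of their group mean), and
DV-switching (a second outcome correlated at $r = 0.5$, reporting the
smaller $p$). At QRP level `medium` one operator is chosen at random per
study; at `high` all three run in the order stop → outlier → switch, each
only while the result is nonsignificant. The retention map and operator
parameters are this package's choices, kept in the configuration rather
than the code.

The simulator exists for property-level validation — estimator calibration,
bias-reduction, parameter recovery — and for user-defined false-positive
grids via `fpr_grid()`. It does not attempt to reproduce the external
400-condition framework behind the packaged worst-case false-positive
column, which `packaged_fpr_table()` ships as constants with explicit
provenance. Two simulator caveats matter when reading test results: the
rejection rule in `fpr_grid()` is direction-positive (estimate above zero
with the CI excluding zero), whose nominal rate under calibration is
$\alpha/2 = 2.5\%$, not 5%; and passing recovery tests on normal outcomes
with honest $n$ says nothing about non-normal outcomes, clustered designs,
or shared control groups, none of which the simulator models (the packaged
literature itself contains one shared-pool study, treated as independent
here as in the published analysis).

## The admissibility gate

`admissible_methods()` filters estimators whose worst-case false-positive
rate is *strictly* below the threshold (default 20%). Strictness is
deliberate: with the packaged rates it admits exactly PET (16%) and the
3PSM (14%) while excluding PET-PEESE at 22%, matching the published verdict
that only two methods perform satisfactorily under the plausible conditions
(heterogeneity near $\tau = 0.4$, bias none-to-medium, QRPs none-to-high,
$k$ near 10). Lowering the threshold below 14% rejects every method — the
trade-off between conservatism and applicability is the user's to make, and
the gate is monotone in the threshold by construction.

## Numerical choices and degenerate inputs

Fractional sample sizes (one study splits a pool 40.5/40.5) flow through
variance formulas and t degrees of freedom but are never used as loop
counts. Meta-analytic operations require $k \ge 2$; regressions and the
selection model require $k \ge 3$; identical precisions make asymmetry
untestable and raise an error. When every study lands in one selection
interval, $\omega$ is unidentified and the 3PSM warns rather than fails.
Conditional-probability ratios are computed in log space and clipped to
$[0,1]$, with underflowing tails mapped to 0. p-uniform roots are bracketed
in $[-2, 3]$ and widened once to $[-8, 8]$ before erroring. Trim-and-fill
breaks rank ties by average ranks and returns the last stable $k_0$ with a
warning if the iteration oscillates. All simulation is deterministic given
the configuration seed.

## Problem sizes used in validation

The test suite fits every estimator on the 13-study table, cross-checks the
REML, Egger and trim-and-fill machinery against an independent reference
implementation, and validates the selection likelihood against brute-force
numerical integration on random small datasets. Simulation-based properties
use desk-scale sizes chosen to keep Monte Carlo noise below the asserted
margins: 200 replicates of $k = 60$ literatures for the 3PSM bias-reduction
property (where the naive bias is large relative to the selection MLE's
noise), 40 replicates of $k = 200$ for REML parameter recovery, 200
replicates for FPR calibration, and 150 for the bias-inflation check. The
analysis scripts under `analysis/` rerun the complete pipeline and write
their tables to `results/`.

## Known limitations

The package analyses univariate standardized mean differences only — no
correlation or odds-ratio conversions, no cluster-robust or multilevel
variances, no multi-cutpoint or moderated selection models, no Bayesian
variants. Moderator columns beyond prime modality are not printed in the
source table and default to `"unknown"`, so the published moderator-adjusted
results can only be checked against the one printed coding. The worst-case
false-positive column is a packaged constant, not a recomputation; users
wanting gate rates under their own plausible conditions should build them
with `fpr_grid()` and pass the result to `run_full_analysis()`.
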