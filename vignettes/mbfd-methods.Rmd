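---
title: "Multiple baseline factorial designs: models, estimators and simulation methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple baseline factorial designs: models, estimators and simulation methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbfd)
```

## The design

The individually randomized multiple baseline factorial design (MBFD)
evaluates two interventions, A and B, and their sequential combination AB
against a standard-of-care control in settings — typically rare diseases —
where a conventional four-arm factorial trial is infeasible and where every
participant should eventually receive every intervention. Each participant is
randomized to one of at least six *sequences*. Every sequence starts under
control; at a staggered period the participant switches to a single
intervention (A for half the sequences, B for the other half), stays on it
for a fixed number of periods, and then receives the combination until exit.
The outcome is measured once at the end of every period.

`mbfd_design()` builds the minimal standard layout: six sequences, five
periods, single-intervention starts at periods 2, 3 and 4 within each arm,
one period on the single intervention, and a common exit. The start periods
are a design choice of this package: they are the unique minimal
configuration compatible with at least five periods, a one-period
single-intervention phase, a one-period stagger, and every sequence reaching
the combination. `mbfd_design_extended()` exposes the knobs that practical
applications vary: more sequences per arm, longer single-intervention
phases (when one post-switch measurement is not enough), wider staggers
(which reduce confounding by coincidental events), and a `fixed_ab_len` exit
policy under which every sequence receives the combination for exactly one
period and exits early, producing a ragged grid. Validation is strict and
happens at construction: phase order can never revert, every sequence must
reach the combination, and each arm needs at least three sequences.

```{r design}
design_summary(mbfd_design())
```

## Analysis models

With $Y_{ij}$ the continuous outcome of participant $i$ at period $j$, all
three analysis models share a participant-level random intercept
$\alpha_i \sim N(0, \tau^2)$, an independent residual
$\varepsilon_{ij} \sim N(0, \sigma^2)$, and a linear period trend that
absorbs the secular drift the staggered rollout would otherwise confound
with treatment:

* **Model 1 (additive):**
  $Y_{ij} = u + \beta_T j + \beta_A X_{Aij} + \beta_B X_{Bij} + \alpha_i + \varepsilon_{ij}$,
  where $X_{Aij}, X_{Bij}$ are factorial exposure indicators that are *both*
  1 during the combined phase. The combined effect is implicitly
  $\beta_A + \beta_B$.
* **Model 2 (interaction):** adds $\beta_I X_{Aij} X_{Bij}$, so the combined
  effect is $\beta_A + \beta_B + \beta_I$ and $\beta_I$ measures the
  departure from additivity under sequential delivery.
* **Model 3 (multi-arm):** uses mutually exclusive indicators
  $Z_{Aij}, Z_{Bij}, Z_{Cij}$ for the A-only, B-only and combined phases;
  $\beta_C$ is the combined effect directly, averaged over delivery orders.

The parameterizations are linked by the identity
$\beta_C = \beta_A + \beta_B + \beta_I$, which `effect_parameters()`
enforces. The data-generating mechanism in `simulate_trial()` always uses
the multi-arm parameterization, so interaction scenarios are expressed
through $\beta_C$.

## Estimators

**REML linear mixed model.** `fit_lmm()` maximizes the restricted likelihood
of the compound-symmetry model. The implementation profiles the variance
ratio $\gamma = \tau^2/\sigma^2$: for fixed $\gamma$ the GLS coefficients
and $\hat\sigma^2$ are closed-form via the Sherman–Morrison identity
(each cluster's $V_i^{-1}$ is a scaled identity minus a rank-one term), so
REML reduces to one-dimensional optimization over $\log\gamma$, with the
boundary $\hat\tau^2 = 0$ permitted and negative variance estimates
truncated there. Wald t-tests use Satterthwaite degrees of freedom:
$\mathrm{df} = 2\,(c'\hat V c)^2 / \widehat{\mathrm{Var}}(c'\hat V c)$, the
variance obtained by the delta method from a central finite-difference
gradient (relative step $10^{-5}$) and the inverse observed REML information
(numerical Hessian, relative step $10^{-4}$). The df are clamped to
$[1, NJ - p]$; at the independence boundary, or when the data are
interpolated so the restricted likelihood has no curvature to exploit, the
residual df $NJ - p$ are used, and a numerically singular information
matrix triggers a cluster-based fallback $N - p$ with a warning (fits
record whether the fallback fired). These numerical choices are this
package's own; they reproduce lmerTest's Satterthwaite df to within 2% on
the designs used here, which the test suite verifies.

**GEE.** `fit_gee()` implements identity-link Gaussian estimating equations
with an exchangeable working correlation. Starting from ordinary least
squares, coefficient updates (weighted estimating equations, again rank-one
structured) alternate with moment updates of the scale $\varphi$ (Pearson
residuals, denominator $\sum_i n_i - p$) and of the working correlation
$\hat\alpha$ (all within-cluster pairs, denominator
$\sum_i n_i(n_i-1)/2 - p$), until the coefficients move less than $10^{-8}$
in the max norm (at most 50 iterations; convergence is judged on the
coefficients, not the correlation, and $\hat\alpha$ is clipped into
$(-1/(\max n_i - 1), 1)$ with a warning if the moment estimate escapes its
valid range). Two empirical covariance estimators are returned: the
Liang–Zeger sandwich, and the Mancl–DeRouen (MD) bias-corrected sandwich in
which each cluster's residual vector is pre-multiplied by
$(I - H_i)^{-1}$, $H_i = D_i A^{-1} D_i' V_i^{-1}$, before the meat is
formed — implemented from the source formula, not as a scalar multiplier.
A fixed `working_corr` hook bypasses the moment updates (independence
reproduces OLS exactly; the true exchangeable value reproduces closed-form
GLS), which the oracle tests exploit.

### Reference distributions for GEE tests

A design question that mattered here: which reference distribution each GEE
variance flavour is tested against. The uncorrected sandwich is an
asymptotic estimator, and standard GEE software reports normal-reference
Wald tests for it; the MD correction was proposed *together with* t-tests on
$N - p$ degrees of freedom, and using the asymptotic normal with the
corrected variance would undo much of the correction's small-sample benefit.
`gee_test()` therefore defaults to the canonical pairing — sandwich tests on
the normal reference, MD tests on $t_{N-p}$ — and exposes `reference =
"n-p"` / `"normal"` to force either convention. Empirically the pairing
matters at $N = 30$: the sandwich/normal test shows the familiar roughly
two-fold type-I-error inflation at the Bonferroni-adjusted 0.025 level,
while the MD/$t_{26}$ test is at or just below nominal; forcing the t
reference onto the sandwich halves its inflation, and forcing the normal
onto MD re-inflates it. The simulation engine uses the canonical pairing.

## The Monte Carlo engine

`scenario_config()` fixes a design, sample size, ICC, generating effects,
analysis model, estimators and a master seed; `run_scenario()` executes the
replicates and aggregates. The conditions mirror the design's intended
application: $N \in \{30, 60, 120\}$ (single-site rare-disease trial,
multi-site trial, stability check), ICC $\in \{0.05, 0.10, 0.30\}$
(i.e. $\tau \in \{0.23, 0.33, 0.65\}$ at $\sigma = 1$), baseline mean 0,
period trend 1, and effect vectors $(\beta_A, \beta_B, \beta_C)$ of
$(0,0,0)$ (null), $(0.8, 0.8, 1.6)$ (additive) and $(0.8, 0.8, 2.0)$
(interaction $\beta_I = 0.4$). The effects are deliberately large so that
power differences between estimators are visible rather than uniformly
small.

Within a replicate the same simulated dataset is analysed by every
requested estimator (common random numbers), each coefficient in the
model's hypothesis set is tested at the Bonferroni-adjusted level (0.05/2
for Model 1, 0.05/3 for Models 2–3), and replicate $r$ is reproducible in
isolation: its seed is a fixed hash of the master seed and $r$, and
randomization, random intercepts and residuals are drawn in a documented
order. Non-converged fits exclude the replicate from that estimator's
denominator and are counted; exceeding 5% exclusions flags the result. Both
per-coefficient rejection rates and the disjunctive "at least one
hypothesis rejected" rate are reported: the former is what per-coefficient
summary tables print, the latter is the family-wise power definition, and
the two differ, so the package computes both and labels them.

`reproduce_table()` runs the full ICC × model × N × estimator grids behind
the four headline summaries (type I error, power without interaction, mean
estimates under interaction, power with interaction) at a requested
replicate count. The replicate count for published-quality grids defaults
to 5000, giving binomial Monte Carlo standard errors of 0.003–0.007 on
rates; the packaged acceptance checks run at 2000 replicates with
tolerances widened accordingly (three combined Monte Carlo standard
errors), and the quick examples in the documentation use far fewer, where
only the grid's shape matters.

## What the generator does and does not emulate

`simulate_trial()` draws exactly from the random-intercept model: one
Gaussian intercept per participant, independent Gaussian residuals, a
linear period trend, effects constant over the exposed periods, no
carryover, no dropout. Real multiple-baseline data can violate each of
these: serially correlated residuals (AR structure), random slopes,
non-Gaussian outcomes, missing measurements, order-dependent (sequence)
effects in the combined phase. Passing the packaged simulation checks
therefore demonstrates correctness of the estimators *under the
random-intercept conditions*, and the documented robustness ordering (GEE's
sandwich remains valid when the random-effect structure is misspecified;
the model-based LMM variance does not) is motivation, not something these
simulations test. The design deliberately confounds the combined effect
with delivery order: $\beta_C$ is an order-averaged estimand, and no model
here separates AB from BA effects.

## Degenerate inputs and numerical corner cases

Noise-free data (an interpolating fit) leave the restricted likelihood
without curvature; such fits are flagged and fall back to residual df.
$\hat\tau^2$ is truncated at zero rather than allowed negative. The GEE
working correlation is clipped into its valid range. Rank-deficient design
matrices are rejected with the offending columns named, rather than
silently dropped. Allocation requires at least one participant per
sequence; the remainder when the sample size is not a multiple of the
number of sequences goes to uniformly random sequences, under the same
seed discipline as everything else.

## Limitations

The estimators cover the random-intercept/exchangeable family only — no
random slopes, AR residuals, Kenward–Roger or Kauermann–Carroll
corrections, and no binary or count outcomes. Monte Carlo results carry
simulation error; at 5000 replicates, rates are accurate to roughly
±0.006–0.014 (two binomial SEs, depending on the rate), which is the
agreement level one should expect when comparing independently seeded
reproductions of the same grid.
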