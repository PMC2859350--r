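---
title: "The total deviation index by probability intervals, and tolerance-interval inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The total deviation index by probability intervals, and tolerance-interval inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdiagree)
```

## The agreement problem

Two devices (instruments, raters) measure the same continuous quantity on
$n$ subjects, $m$ times each. Whether the devices are interchangeable is a
question about the *paired differences* $D$ between their readings: if a
large proportion $p$ of $|D|$ falls below a clinically acceptable boundary,
the devices agree. The total deviation index (TDI), $\kappa_p$, is that
boundary: the value with $P(|D| < \kappa_p) = p$. Unlike correlation-type
indices (ICC, CCC) it does not depend on the between-subject spread, so it
is not inflated by heterogeneous populations, and it is expressed in the
measurement units themselves.

## Model

`tdiagree` fits the standard two-device mixed model

$$y_{ijl} = \mu + \mathbf{x}_{ijl}'\delta + \beta_j + \alpha_i +
\gamma_{ij} + e_{ijl},$$

with subject effects $\alpha_i \sim N(0,\sigma^2_\alpha)$, optional
subject-by-device interaction $\gamma_{ij} \sim N(0,\sigma^2_\gamma)$, and
errors $e_{ijl} \sim N(0,\sigma^2_e)$ (optionally device-specific
$\sigma^2_{e1},\sigma^2_{e2}$). Three difference distributions follow:

| kind  | difference                                   | mean    | variance |
|-------|----------------------------------------------|---------|----------|
| total | single readings across devices               | $\mu_D=\beta_2-\beta_1$ | $2\sigma^2_\gamma + 2\sigma^2_e$ |
| intra | replicates within one device                 | $0$     | $2\sigma^2_e$ |
| inter | replicate averages across devices            | $\mu_D$ | $2\sigma^2_\gamma + 2\sigma^2_e/m$ |

For balanced data `fit_balanced_vc()` uses the closed-form ANOVA moment
estimators, which coincide with REML whenever the raw solutions are
non-negative; negative solutions are truncated at zero and flagged (the
standard REML-consistent behaviour). With covariates or unbalanced data,
`fit_reml_general()` delegates the numerical REML fit to `lme4`. Because
the device contrast is a within-subject comparison, subject-level
covariates leave $\hat\beta_2-\hat\beta_1$ and $\hat\sigma^2_e$ — the only
ingredients of the TDI — unchanged in balanced designs; this is tested, and
it is why covariate adjustment matters for model comparison (AIC) but not
for the index itself.

## The estimate: a probability interval solved by binary search

An interval $[-\kappa_p, \kappa_p]$ symmetric about zero (not about
$\mu_D$, which distinguishes the TDI from Bland–Altman limits) with normal
content $p$ has

$$\kappa_p = |\mu_D| + \sigma_D z_{p_1}, \qquad
\Phi(z_{p_1}) - \Phi(-2|\mu_D|/\sigma_D - z_{p_1}) = p .$$

The upper-tail proportion $p_1 \in [p, 1]$ has no closed form; `solve_p1()`
finds it by a modified bisection on $[p, 1]$ whose bracket endpoints are
shifted by the tolerance at each step, terminating when the probability
equation holds to within `tol` (default $10^{-10}$; the Monte-Carlo
harness uses $10^{-4}$, trading precision for speed where thousands of
solves are needed). Convergence is logarithmic: at most
$\lceil\log_2(1/\mathrm{tol})\rceil + 5$ iterations. Two sanity anchors:
$p_1 = (1+p)/2$ exactly when $\mu_D = 0$, and $p_1 \downarrow p$ as
$|\mu_D|/\sigma_D \to \infty$ (one tail dominates).

The same $\kappa_p$ comes from the non-central chi-square representation
$\kappa_p = \sigma_D\sqrt{q_p}$, $q_p$ the $p$-quantile of
$\chi^2_1\!\left((\mu_D/\sigma_D)^2\right)$ (`tdi_ncx2_exact()`); the two
routes agree to $10^{-8}$ relative over the tested grid. The binary-search
route is kept as the primary one because the inference step needs $p_1$.
`tdi_msd_approx()` provides the historical approximation
$z_{(1+p)/2}\sqrt{\mu_D^2+\sigma_D^2}$, exact only at $\mu_D = 0$.

The sign of $\mu_D$ is a reporting convention (second device in
`device_order` minus the first); every estimator uses $|\hat\mu_D|$, since
the index is symmetric in the sign.

## Inference: an exact one-sided tolerance interval

Plugging estimates into the probability interval makes $\hat\kappa_p$ a
random quantity. The studentised statistic follows a non-central $t$
distribution with non-centrality $\sqrt{N} z_{p_1}$, which yields Hahn's
exact one-sided upper tolerance bound for a $p_1$ proportion of the
difference population:

$$UB = |\hat\mu_D| + \hat\sigma_D\,
t'_{1-\alpha;\,\nu;\,\sqrt{N}z_{p_1}} / \sqrt{N}.$$

Here $N$ counts the paired differences feeding the statistic. We use
$N = 2nm$ for total and intra, and $N = 2n$ for inter (only $2n$
replicate averages exist); the sources leave $N$ for the intra/inter
variants unstated, and this rule reproduces the published concordance
table within rounding.

The residual degrees of freedom $\nu$ are a *convention*, selectable and
always reported (`residual_df()`):

* `interaction`: $\nu = 2n(m-1)$ — all effects consume df (conservative);
* `no_interaction`: $\nu = 2nm - (n+m-1)$ — the additive-model residual
  (default when the fitted model lacks the interaction);
* `fixed_only`: $\nu = 2nm - 2$ — random effects consume nothing;
* `satterthwaite`: Welch combination of the device-specific error df, used
  automatically when the error variances differ by device.

At $n = 384$, $m = 2$ these give 768 / 1151 / 1534, and bounds
18.09 / 17.98 / 17.93 for the total TDI at $p = 0.90$ — a spread of under
1% that nevertheless straddles published roundings; the published
concordance table is itself internally most consistent with different
conventions in different rows, which is precisely why the convention is a
reported flag rather than a hidden constant. For $m = 2$ (the only
replicate count in the motivating data) the printed `no_interaction`
formula equals the exact additive-ANOVA residual df $2nm - n - 1$; for
$m > 2$ the model fit uses the exact df while `residual_df()` keeps the
conventional formula.

Non-central $t$ quantiles come from `stats::qt(..., ncp)`; for
non-centralities beyond 5000 (or wherever the routine fails) the
closed-form one-sided normal tolerance factor
$k = (z_{p_1} + \sqrt{z_{p_1}^2 - ab})/a$, $a = 1 - z_{1-\alpha}^2/(2\nu)$,
$b = z_{p_1}^2 - z_{1-\alpha}^2/N$, takes over; near the switch point the
two agree to about 0.3% at $\nu = 100$ and tighter as $\nu$ grows.

`tdi_hypothesis_test()` phrases agreement as $H_0: \kappa_p \ge \kappa_0$,
rejected (agreement concluded) when $UB < \kappa_0$ — the burden of proof
is on agreement.

### Inter-method modes

`tdi_inter()` has two modes. `strict` (default) solves $p_1$ from the
averaged-difference ratio $\mu_D/\sigma_{inter}$, so the interval captures
exactly $p$ of the averaged differences — the mathematically consistent
reading. `paper_compat` takes $p_1$ from the *total*-difference ratio and
only then applies the inter spread; published concordance tables have been
produced this way (the two differ by a few tenths of a unit: 12.48 vs
12.86 at $p = 0.90$ in the worked example). Both are labelled in results.

## Coverage probability

The dual question — what proportion $p_\kappa$ of $|D|$ lies inside a fixed
boundary $\kappa$ — is answered by two normal CDF evaluations
(`cp_estimate()`), and its one-sided lower confidence bound by inverting
the tolerance interval (`cp_lower_bound()`): a bisection on
$p_\kappa \in (0,1)$, recomputing the non-centrality through the $p_1$
link at each candidate, keeps the printed algorithm's structure rather than
root-finding on the non-centrality directly (equivalent, but the
proportion-scale bracket is the documented procedure). The bound satisfies
an exact duality used as a test oracle: evaluated at
$\kappa = UB_p$ it returns $p$, and the TDI and CP hypothesis tests reach
identical decisions at $(\kappa_0, p_0) = (\kappa, p)$.

## Comparator bounds

Two established methods are implemented for benchmarking, both as
log-scale normal-theory bounds
$\exp(\log\hat\kappa + z_{1-\alpha}\,se_{\log})$:

* `lin_tdi_ub()`: the MSD approximation with moment (working-independence
  GEE, identical for balanced data) estimates;
* `choudhary_tdi_ub()`: the non-central chi-square estimate at ML
  parameter estimates — its point estimate provably equals the
  probability-interval estimate at the same parameters, and the balanced
  ML has a closed form through the between/within likelihood
  factorisation.

The original closed-form delta-method variances are not reproduced here;
$se_{\log}$ uses numerically differentiated gradients with model-based
covariances (mean-square asymptotics for the moment fit, inverse observed
information for ML). Results carry an `approx_variance` flag. Consequently
the comparator *bounds* are structural stand-ins suitable for qualitative
comparison (e.g. the MSD bound's conservatism under large bias), while
their point estimates are exact.

## The synthetic-data generator and what the simulations show

`generate_dataset()` draws balanced two-device data from the
compound-symmetry model with no interaction term — the configuration of
the motivating blood-pressure study (384 subjects, two readings per
device; intercept 133.369 mmHg, subject variance 380.187, device effect
2.174, error variance 52.867, as estimated there). The harness's scenario
grid varies the device effect over $\{0, 2.174, 5\}$, the error variance
over $\{16, 52.867\}$ and $n$ over $\{20, 100\}$ with $m = 2$, 1000
replicates and search tolerance $10^{-4}$. True $\kappa_p$ values use the
exact $\sqrt{32}$ and $\sqrt{2 \times 52.867}$, not their rounded labels.
One master seed draws per-replicate seeds, so any scenario is reproducible
in isolation; estimates and bounds are summarised on the log scale (TDI
estimates are right-skewed), and the empirical confidence (EC) is the
percentage of replicates whose true $\log\kappa_p$ is at or below the log
upper bound (ties, a measure-zero event, count as covered).

What the generator does *not* emulate: discretised readings (mercury
sphygmomanometers round to 10 mmHg), heteroscedasticity over the
measurement range, non-normal tails, drop-out or unbalanced replication.
Passing simulations therefore certify the estimator and its bound under
the stated normal mixed model, not robustness to those features.

Two qualitative behaviours of the bound are reproduced and tested: under
$\mu_D = 0$ the symmetric-about-zero construction over-covers (EC above
the nominal 95%, the Westlake effect) with a slight upward bias of the
point estimate at small $n$; under large bias with small $n$ and small
$\sigma_D$, coverage dips slightly below nominal.

## Numerical choices and edge cases

* Search tolerances: $10^{-10}$ default, $10^{-4}$ in the harness; both
  validated against a `uniroot` oracle.
* Degenerate inputs: $\sigma_D = 0$ raises an error (degenerate difference
  distribution); missing values are rejected, never imputed; unbalanced
  data are accepted and flagged, but closed-form fitting and
  tolerance-interval bookkeeping refuse them (the general REML path
  handles the fit).
* A one-subject data set is accepted by the validator (it is well-formed
  data); every fitting routine requires $n \ge 2$.
* Replicate fit failures inside a scenario are logged and excluded; more
  than 1% aborts the scenario summary.
* Problem sizes in the test suite are chosen to keep the default run in
  tens of seconds: full 1000-replicate runs are reserved for the two
  headline scenarios and the comparator coverage check, the remaining
  properties use 25–500 replicates with assertions at 3 Monte-Carlo
  standard errors or better.

## Known limitations

Two devices only; no heteroscedasticity beyond device-specific error
variances; no nonparametric TDI; comparator variances approximate (above);
the tolerance-interval path requires balanced data. The `strict` vs
`paper_compat` inter-method ambiguity and the df-convention spread are
inherent to the published record and are surfaced as flags rather than
resolved silently.
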