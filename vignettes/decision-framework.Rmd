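---
title: "Multivariate Bayesian decision-making for trials with correlated binary endpoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate Bayesian decision-making for trials with correlated binary endpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(2026)
```

bmlr supports superiority and inferiority decision-making in two-arm
randomized trials that record $K$ correlated binary endpoints per subject and
where the treatment effect may vary with observed covariates. This vignette
is the package's account of the underlying model and of the design choices a
user should know about before trusting a green test suite.

## The model

Each subject's outcome vector $y_i \in \{0,1\}^K$ takes one of $Q = 2^K$
configurations, the rows of the configuration matrix $H$ (all-success first,
all-failure last, descending binary order in between; `config_matrix()`).
The joint configuration probabilities follow a multinomial logistic
regression,
$$
\phi_{iq}(x_i) \;=\;
\frac{\exp\{\psi_{iq}(x_i)\}}{\sum_{r<Q}\exp\{\psi_{ir}(x_i)\} + 1},
\qquad
\psi_{iq}(x_i) = \beta_{0q} + \beta_{1q} x_{i1} + \dots + \beta_{Pq} x_{iP},
$$
with the all-failure category as reference ($\beta_Q \equiv 0$ for
identifiability). The linear predictor contains an intercept, the treatment
indicator, covariates, and treatment-covariate interactions; the
interactions are what let endpoint-specific effects and endpoint
correlations vary freely over the covariate space, which stratified or
shared-coefficient multivariate models cannot do.

Because the model is saturated over configurations at each covariate value,
the correlation between endpoints is not a separate parameter: it is encoded
in $\phi$ and travels through every transformation below.

### Posterior sampling

`fit_bmlr()` samples the posterior with a Gibbs sampler based on the
Polya-Gamma expansion. Per sweep and per category $q$, it computes each
subject's competing-category offset
$C_{iq} = \log \sum_{r \neq q} \exp(\psi_{ir})$ (reference included as
$e^0$), draws $\omega_{iq} \sim \mathrm{PG}(1, \psi_{iq} - C_{iq})$, and
updates $\beta_q$ from the resulting conjugate multivariate normal with
precision $X^\top \Omega_q X + B_0^{-1}$ and working response
$\kappa_{iq} + \omega_{iq} C_{iq}$, $\kappa_{iq} = I(c_i = q) - 1/2$. The
PG(1, z) draws use the exact alternating-series rejection sampler
(`rpg()`); no truncated-sum approximation is involved, so no approximation
bias can leak into the error-rate checks. The sampler draws from R's RNG
stream and is bit-reproducible under `set.seed()`.

Defaults mirror a production analysis: 2 chains, 10,000 retained iterations,
1,000 burn-in, prior $\beta_q \sim N(0, 10 I)$ — diffuse on the log-odds
scale yet proper enough to keep separable data finite. Simulation studies
scale these down; the tests verify that the posterior mean agrees with a
direct numerical maximizer of the multinomial likelihood under the diffuse
prior, which is the arbiter wherever the update algebra could be doubted.

Chains are initialized at $\beta = 0$ (option: overdispersed draws from the
prior). Convergence is monitored with the Brooks-Gelman potential scale
reduction factors (`gelman_rubin()`): univariate per coefficient and the
multivariate statistic
$\sqrt{(L-1)/L + \tfrac{m+1}{m}\lambda_1(W^{-1}B/L)}$. We use the textbook
$(m+1)/m$ chain factor; on exact-copy chains the statistic equals its floor
$\sqrt{(L-1)/L}$, marginally below 1. The working tolerance is 1.10.

### From coefficients to decisions

Coefficients have no direct clinical reading, so every retained draw — never
a posterior summary — is pushed through three stations
(`treatment_effects()`):

1. counterfactual linear predictors with the treatment forced to 0 and 1
   map to joint probabilities $\phi_T(x)$ via the inverse multinomial logit
   (log-sum-exp stabilized);
2. endpoint success probabilities are selection sums
   $\theta_{Tk} = \sum_{q \in U_k} \phi_{Tq}$, $U_k$ the $2^{K-1}$
   configurations with success on endpoint $k$;
3. treatment differences $\delta_k = \theta_{1k} - \theta_{0k}$, optionally
   weighted into $\delta_w = \sum_k w_k \delta_k$.

Applying transforms per draw matters: on a skewed posterior the mean of the
transformed draws and the transform of the mean differ visibly (a test
quantifies this), and only the former is the posterior of the effect.

Populations are specified either by fixed covariate values (`pop_fixed()`) or
by empirical marginalization over the covariate rows observed in an interval
(`pop_interval()`, `pop_all()`): per draw, the per-subject $\phi$ of every
selected subject is computed for both counterfactual arms and averaged
within arm before steps 2-3. Both arms' covariate rows enter both
counterfactual profiles — randomization makes the covariate distribution
exchangeable across arms, and pooling uses twice the rows. The posterior
itself is always fit on all subjects; only covariate rows are subset, which
is exactly the advantage regression holds over stratified analysis when the
covariate is continuous (a test asserts the resulting precision ordering).
Fixed values outside the observed covariate range are allowed but are
extrapolation; interval endpoints are closed by default.

### Decision rules

Three rejection-region shapes for the $K$-variate difference are supported
(`decision_rule()`): *Any* (at least one $\delta_k$ on the favorable side of
zero; superiority and inferiority regions may overlap), *All* (every
$\delta_k$), and *Compensatory* (the weighted $\delta_w$, letting benefits
offset harms). Region boundaries are strict, so a draw exactly at zero
belongs to no region — measure-zero, but deterministic.

Thresholds are $p_{\text{cut}} = 1-\alpha$ for All/Compensatory and the
multiplicity-corrected $1-\alpha/K$ for Any; two-sided tests halve
$\alpha$. The Compensatory decision thresholds
$P(\delta_w > 0 \mid y)$ directly. The Any and All decisions threshold
*per-endpoint* posterior probabilities: with
$P_k = P(\delta_k > 0 \mid y)$, Any concludes superiority when
$\max_k P_k > 1-\alpha/K$ and All when $\min_k P_k > 1-\alpha$. This is a
deliberate calibration choice, not a shortcut. The posterior probability of
the union region itself satisfies
$P(\bigcup_k \{\delta_k > 0\} \mid y) \ge \max_k P_k$, so thresholding *it*
at $1-\alpha/K$ would conclude far too easily: under a two-endpoint
independent null the Type I error of the union-probability test at
$p_{\text{cut}} = 0.975$ is $c(1-\ln c) \approx 0.117$ with $c = 0.025$
(confirmed by simulation), more than twice the nominal 5%. The
per-endpoint form restores the nominal level ($\approx 0.049$ under
independence) and is the decision procedure that the $1-\alpha/K$
correction and the multivariate-normal sample-size approximations
presuppose. The union/intersection region probabilities remain available
as summaries via `region_prob()`, and per-draw region flags via
`region_membership()`.

For failure-coded outcomes (lower is better) use `side = "left"`, which
flips the favorable direction without recoding data. A two-sided Any test
can in principle exceed the threshold in both directions; the result is
then flagged as a double trigger rather than suppressed.

## Sample sizes, and where the approximations sit

`required_n()` computes a priori per-arm sample sizes. For Any/All the power
is a $K$-variate normal rectangle probability with the endpoint correlation
matrix and standardized shifts
$e_k = \delta_k \sqrt{n} / \sqrt{\theta_{1k}(1-\theta_{1k}) +
\theta_{0k}(1-\theta_{0k})}$: All-rule power
$\Psi_K(-z_{1-\alpha} + e)$, Any-rule power
$1 - \Psi_K(z_{1-\alpha/K} - e)$ (the rectangle with the Any shift is the
probability that *no* endpoint rejects, so power is its complement — the
$K=1$ collapse to the univariate two-proportion formula and the simulated
operating characteristics both confirm this orientation). The search uses
geometric bracketing plus binary search for the minimal integer $n$,
equivalent to gradually increasing $n$. The Compensatory rule has the closed
form
$n = \lceil [\theta_{1w}(1-\theta_{1w}) + \theta_{0w}(1-\theta_{0w})]
\{(z_{1-\alpha} + z_{1-\beta})/(\theta_{1w}-\theta_{0w})\}^2 \rceil$ on the
weighted success probabilities.

The rectangle probabilities are computed by deterministic adaptive
quadrature (bivariate single-integral reduction; trivariate conditioning on
the first coordinate), absolute accuracy well below $10^{-6}$, checked
against an external reference implementation at development time. $K \le 3$
is supported, matching the evaluated designs.

Two calibration facts, verified by simulation in the test suite, deserve
emphasis:

* the Any/All approximations are sharp for the per-endpoint decisions they
  model — simulated All-rule power at the computed $n$ lands on the target
  (0.800 at $n = 304$ in the shipped check);
* the Compensatory size is *conservative* whenever the weights spread over
  endpoints: the closed form treats the weighted endpoint as a Bernoulli
  with mean $\theta_{Tw}$, but the variance of $w^\top y$ involves
  $\sum_k w_k^2 < 1$ and the endpoint covariances, and is smaller for
  non-degenerate weights. The computed $n$ therefore overshoots the power
  target (simulated $\approx 0.88$ with $w = (0.75, 0.25)$ in the shipped
  world) while never undershooting it. Tests assert the tight band for All
  and the at-least-target bound for Compensatory.

Correlation effects go in the documented directions: negative correlation
reduces the required $n$ for Any/Compensatory, positive correlation helps
the All rule.

## The synthetic world

`dgm_spec()` states a trial mechanism by conditional success probabilities
and pairwise endpoint correlations at two anchor covariate values (0/1 for a
Bernoulli(0.5) covariate; -1/+1 for a standard normal one), per arm. The
margins-plus-correlation specification is converted to joint cells by the
bivariate Bernoulli identity
$\phi_{11} = \theta_1\theta_2 + \rho\sqrt{\theta_1(1-\theta_1)\,
\theta_2(1-\theta_2)}$ (for $K=3$, all pairwise cells are fixed this way
and the unidentified triple-success cell takes the midpoint of its
feasibility interval); infeasible combinations outside the Frechet-type
bounds error with the violated bound named. The four anchor cells are then
inverted exactly into coefficients of the interaction model (a $4\times4$
linear solve per category on the log-odds scale), so between the anchors the
mechanism interpolates linearly in log-odds — a consequence of the model
form, not an extra assumption. The inversion round-trips to $10^{-10}$.

Effect-size presets (`dgm_preset()`) state the heterogeneity patterns used
throughout the package's evaluation, with the control arm at
$\theta = (0.5, 0.5)$ everywhere: ES1 fully null; ES2 conditional effects
$\pm(0.2, 0.1)$ cancelling to a zero average effect; ES3 conditional
$(0.25, 0.15)$ / $(0.15, 0.05)$ at the low/high anchor (average
$(0.20, 0.10)$, conditional above average); ES4 the mirror (conditional
below average); ES5 a strong-heterogeneity variant $(0.30, 0.20)$ /
$(0.10, 0.00)$ whose low-anchor conditional effect needs fewer subjects
than stratification leaves available — the premise of the conditional-power
checks. Pairwise correlations $\rho \in \{-0.2, 0, 0.2\}$. These numeric
cells are this package's stated defaults for the qualitative patterns;
the evaluation's conclusions do not hinge on the exact values.

Every generated trial carries a ground-truth manifest: exact conditional
effects at the anchors, and average effects obtained by the exact half-half
mixture in $\phi$-space (binary covariate) or deterministic adaptive
quadrature over the normal covariate law — quadrature rather than
Monte-Carlo integration, being faster and reproducible at higher accuracy.
A generator test checks the manifest against empirical frequencies from
$10^6$ subjects.

What the generator emulates: the stated margins, their pairwise
correlations, heterogeneity linear in log-odds, randomized balanced arms.
What it does not: model misspecification (non-logistic covariate effects),
missingness, measurement error, covariate distributions beyond
Bernoulli(0.5)/standard normal, more than one covariate. A green
operating-characteristic suite therefore certifies calibration *under the
model*, not robustness to violations of it.

## Reference analyses

Two comparators reproduce the standard alternatives: `fit_mb()`, the
stratified multivariate Bernoulli-Dirichlet analysis (configuration counts
plus a near-Haldane Dirichlet(0.01) prior, sampled directly; subpopulations
by stratification, so conditional effects pay the full sample-size cost);
and `fit_ulr_suite()`, independent univariate logistic regressions per
endpoint whose draws are index-paired into joint difference draws — the
pairing encodes exactly the independence assumption the comparison is meant
to expose. The Dirichlet posterior mean matches its closed form to machine
precision in tests, and the saturated no-covariate regression agrees with it
on shared data.

## Numerical and scaling choices

* Simplex checks tolerate $10^{-8}$ and error beyond it rather than
  silently renormalizing; silent renormalization hides upstream bugs.
* Posterior summaries are means and central quantile intervals
  (deterministic, unlike HPD intervals).
* Repetition studies derive per-repetition seeds as
  `rep_seed(master, scenario, rep)` (a fixed affine-mod map), so any single
  repetition is reproducible in isolation; individual repetition failures
  are counted and tolerated up to 1%.
* The shipped tests run the operating-characteristic checks desk-scaled:
  the Dirichlet route at 1,000-2,000 repetitions, the regression route at
  100-500 repetitions with 400-1,200 retained iterations, and convergence
  over 12-20 datasets. Tolerances account for the Monte-Carlo error at
  those settings; thresholds themselves (5% error, 80% power, PSRF 1.10)
  are never adjusted.

## Limitations

The model grows $Q - 1 = 2^K - 1$ coefficient vectors; it is intended for a
handful of endpoints ($K \le 3$ evaluated here) and few covariates. Small
samples inherit the familiar logistic small-sample bias in coefficients,
which the probability-scale transforms largely — not entirely — absorb.
Non-inferiority margins, Bayes factors, splines, latent-class heterogeneity
and interim monitoring are out of scope.

## A worked run

```{r, eval = FALSE}
library(bmlr)
spec <- dgm_preset("ES3", "normal", rho = 0.2, weights = c(0.75, 0.25))
trial <- generate_trial(spec, n_per_arm = 1000, seed = 7)
ana <- analyze_trial(
  trial, c("y1", "y2"), "treat", covariates = "z",
  populations = list(ATE = pop_all(), low = pop_interval("z", -Inf, -1)),
  rules = list(decision_rule("any"),
               decision_rule("compensatory", weights = c(0.75, 0.25))),
  weights = c(0.75, 0.25), chains = 2, iter = 2000, burnin = 500, seed = 8)
ana$decisions
```
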